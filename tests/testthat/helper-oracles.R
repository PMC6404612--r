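# Independent oracles used across the suite. These deliberately take the
# brute-force / closed-form route, never the package's own code paths.

# Random small inbred {0,1} marker set with all markers polymorphic.
toy_marker_set <- function(n, m, seed, subgenomes = NULL, coding = "01") {
  set.seed(seed)
  size <- if (coding == "012") 2 else 1
  M <- matrix(rbinom(n * m, size, runif(m, 0.2, 0.8)[rep(1:m, each = n)]), n, m)
  # repair monomorphic columns so every marker is polymorphic
  for (j in which(apply(M, 2, function(v) length(unique(v)) == 1))) {
    i <- sample(n, 1)
    M[i, j] <- if (M[i, j] == 0) size else 0
  }
  storage.mode(M) <- "double"
  rownames(M) <- sprintf("L%03d", seq_len(n))
  colnames(M) <- sprintf("mk%03d", seq_len(m))
  sub <- if (!is.null(subgenomes)) rep_len(subgenomes, m)
  chrom <- if (!is.null(sub)) paste0(rep_len(1:7, m), sub)
  marker_set(M, chrom = chrom, subgenome = sub, coding = coding)
}

# Centered scores and scaling constant, recomputed independently of the
# package (inbred analogue for {0,1}, 2p centering for {0,1,2}).
oracle_center <- function(ms) {
  M <- ms$scores
  if (ms$coding == "012") {
    p <- colMeans(M) / 2
    list(W = sweep(M, 2, 2 * p, "-"), c = 2 * sum(p * (1 - p)))
  } else {
    p <- colMeans(M)
    list(W = sweep(M, 2, p, "-"), c = sum(p * (1 - p)))
  }
}

# Exact epistatic kernel by explicit pairwise interaction design matrix:
# H = 2 c^-2 E E', E's columns are w_j * w_k over all pairs j < k.
oracle_pairwise_H <- function(W, cc) {
  m <- ncol(W)
  pairs <- utils::combn(m, 2)
  E <- W[, pairs[1, ], drop = FALSE] * W[, pairs[2, ], drop = FALSE]
  2 * tcrossprod(E) / cc^2
}

# Cross-subgenome interaction kernel by explicit design matrix:
# K_X (.) K_Y = (c_X c_Y)^-1 F F', F's columns are all cross products.
oracle_cross_kernel <- function(WX, WY, cX, cY) {
  F_ <- matrix(0, nrow(WX), ncol(WX) * ncol(WY))
  k <- 0
  for (a in seq_len(ncol(WX))) {
    for (b in seq_len(ncol(WY))) {
      k <- k + 1
      F_[, k] <- WX[, a] * WY[, b]
    }
  }
  tcrossprod(F_) / (cX * cY)
}

# Direct evaluation of the restricted log-likelihood at given variances,
# using plain determinant()/solve() rather than the solver's Cholesky route.
oracle_restricted_loglik <- function(y, X, Vlist, theta) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (l in seq_along(Vlist)) V <- V + theta[l] * Vlist[[l]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- as.numeric(t(r) %*% Vi %*% r)
  ldV <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  ldX <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
  -0.5 * (ldV + ldX + quad + (n - ncol(X)) * log(2 * pi))
}

# Closed-form REML for the balanced one-way random-effects model with K = I:
# sigma2_e = MSE, sigma2_g = (MSB - MSE) / r.
oracle_balanced_oneway <- function(ymat) {  # lines in rows, reps in columns
  q <- nrow(ymat)
  r <- ncol(ymat)
  gm <- mean(ymat)
  lm_ <- rowMeans(ymat)
  msb <- r * sum((lm_ - gm)^2) / (q - 1)
  mse <- sum((ymat - lm_)^2) / (q * (r - 1))
  c(g = (msb - mse) / r, e = mse)
}

# Expand a kernel to record level for the direct likelihood oracle.
oracle_expand <- function(K, idx) unclass(K)[idx, idx, drop = FALSE]

# Column-subset a marker set without touching package internals.
subset_markers_for_test <- function(ms, keep) {
  marker_set(ms$scores[, keep, drop = FALSE], coding = ms$coding)
}
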