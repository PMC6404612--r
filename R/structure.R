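#' Extract population structure from the marker matrix by SVD
#'
#' Population structure is removed from all subgenomes at once: the
#' column-centered score matrix is decomposed as \eqn{M_c = U D V^T}, the first
#' `k` principal-component scores are kept as \eqn{Q = U_k D_k}, and the marker
#' matrix is rebuilt with those `k` singular values set to zero. Column means
#' are restored to the deflated matrix \eqn{\tilde M} so that downstream kernel
#' construction re-centers consistently with its own frequency estimates. Each
#' singular vector's sign is fixed so that its largest-magnitude score element
#' is positive, making the decomposition reproducible across platforms.
#'
#' @param marker_set A complete (imputed) [marker_set()].
#' @param k Number of leading principal components to remove; `0 <= k < rank`.
#' @return A `structure_basis`: list with `Q` (n-by-k PC score matrix),
#'   `singular_values` (the k removed singular values), `d` (all singular
#'   values), `k`, `M_tilde` (deflated score matrix with column means
#'   restored), `col_means`, and `line_ids`.
#' @seealso [deflate_markers()] to turn the basis back into a marker set,
#'   [variance_explained()], [subgenome_collinearity()].
#' @export
decompose_structure <- function(marker_set, k) {
  x <- marker_set
  if (anyNA(x$scores)) stop("Impute missing scores first.", call. = FALSE)
  M <- x$scores
  mu <- colMeans(M)
  Mc <- sweep(M, 2, mu, "-")
  sv <- svd(Mc)
  tol <- max(dim(Mc)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol)
  if (k < 0 || k != round(k)) stop("`k` must be a non-negative integer.", call. = FALSE)
  if (k >= r) stop("`k` must be smaller than the rank of the centered matrix (",
                   r, ").", call. = FALSE)
  if (k > 0) {
    # deterministic sign convention on the score vectors
    for (j in seq_len(k)) {
      i_max <- which.max(abs(sv$u[, j]))
      if (sv$u[i_max, j] < 0) {
        sv$u[, j] <- -sv$u[, j]
        sv$v[, j] <- -sv$v[, j]
      }
    }
    Q <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
    Mt <- Mc - Q %*% t(sv$v[, seq_len(k), drop = FALSE])
  } else {
    Q <- matrix(0, nrow(M), 0)
    Mt <- Mc
  }
  Mt <- sweep(Mt, 2, mu, "+")
  dimnames(Mt) <- dimnames(M)
  rownames(Q) <- rownames(M)
  if (k > 0) colnames(Q) <- paste0("Q", seq_len(k))
  structure(
    list(Q = Q, singular_values = sv$d[seq_len(k)], d = sv$d, k = k,
         M_tilde = Mt, col_means = mu, line_ids = rownames(M),
         chrom = x$chrom, subgenome = x$subgenome),
    class = "structure_basis"
  )
}

#' @export
print.structure_basis <- function(x, ...) {
  cat("<structure_basis> k = ", x$k, ", n = ", length(x$line_ids),
      ", markers = ", ncol(x$M_tilde), "\n", sep = "")
  if (x$k > 0) {
    cat("  removed variance fraction: ",
        format(sum(x$singular_values^2) / sum(x$d^2), digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Marker set with population structure removed
#'
#' Converts a [decompose_structure()] result back into a [marker_set()] whose
#' scores are the deflated, real-valued matrix \eqn{\tilde M}; kernels built
#' from it are free of the removed principal components.
#'
#' @param basis A `structure_basis`.
#' @return A `marker_set` with coding `"real"`.
#' @export
deflate_markers <- function(basis) {
  marker_set(basis$M_tilde, chrom = basis$chrom, subgenome = basis$subgenome,
             coding = "real")
}

#' Fraction of marker-matrix variance explained by the leading PCs
#'
#' @inheritParams decompose_structure
#' @param k Number of leading components, `k >= 1`.
#' @return Fraction in (0, 1\]: the sum of the first `k` squared singular
#'   values of the column-centered score matrix over the total.
#' @export
variance_explained <- function(marker_set, k) {
  if (k < 1 || k != round(k)) stop("`k` must be a positive integer.", call. = FALSE)
  x <- marker_set
  if (anyNA(x$scores)) stop("Impute missing scores first.", call. = FALSE)
  Mc <- sweep(x$scores, 2, colMeans(x$scores), "-")
  d2 <- svd(Mc, nu = 0, nv = 0)$d^2
  k <- min(k, length(d2))
  sum(d2[seq_len(k)]) / sum(d2)
}

#' Collinearity between subgenome kernels
#'
#' Pearson correlation of the strictly-lower-triangle (off-diagonal) entries
#' for every pair of subgenome kernels. Under Hardy-Weinberg equilibrium
#' subgenomes segregate independently and these correlations are near zero;
#' population structure inflates them, and removing leading PCs with
#' [decompose_structure()] brings them back down.
#'
#' @param kernels Named list of `genetic_kernel`s sharing line ordering.
#' @return Tibble with columns `kernel_1`, `kernel_2`, `correlation`.
#' @export
subgenome_collinearity <- function(kernels) {
  if (length(kernels) < 2) stop("Need at least two kernels.", call. = FALSE)
  n <- nrow(kernels[[1]])
  if (n < 3) stop("Need at least 3 lines for off-diagonal correlations.",
                  call. = FALSE)
  ids <- lapply(kernels, rownames)
  for (i in seq_along(kernels)[-1]) {
    if (!identical(ids[[1]], ids[[i]])) {
      stop("Kernels have mismatched line orderings.", call. = FALSE)
    }
  }
  low <- lower.tri(kernels[[1]])
  nm <- names(kernels)
  if (is.null(nm)) nm <- vapply(kernels, kernel_label, character(1))
  prs <- utils::combn(seq_along(kernels), 2)
  tibble::tibble(
    kernel_1 = nm[prs[1, ]],
    kernel_2 = nm[prs[2, ]],
    correlation = apply(prs, 2, function(ij) {
      stats::cor(unclass(kernels[[ij[1]]])[low], unclass(kernels[[ij[2]]])[low])
    })
  )
}

#' Subgenome-kernel collinearity as a function of removed PCs
#'
#' Diagnostic for choosing `k`: rebuilds the subgenome kernels after removing
#' `k = 0, 1, ...` principal components and reports every pairwise kernel
#' correlation. The curve typically levels off at the `k` beyond which little
#' further decorrelation is gained.
#'
#' @inheritParams decompose_structure
#' @param ks Integer vector of structure dimensions to evaluate.
#' @return Tibble with columns `k`, `kernel_1`, `kernel_2`, `correlation`.
#' @export
collinearity_profile <- function(marker_set, ks = 0:5) {
  purrr::map_dfr(ks, function(k) {
    ms_k <- if (k == 0) marker_set else
      deflate_markers(decompose_structure(marker_set, k))
    kl <- subgenome_kernels(ms_k, nugget = 0)
    dplyr::mutate(subgenome_collinearity(kl), k = k, .before = 1)
  })
}

#' Structure covariates for the fixed-effect design
#'
#' Returns the PC scores scaled to unit standard deviation per column (the fit
#' is invariant to column scaling of fixed covariates; scaling just conditions
#' the solve).
#'
#' @param basis A `structure_basis`.
#' @return Tibble with `line_id` and one column per retained component.
#' @export
structure_covariates <- function(basis) {
  Q <- basis$Q
  if (ncol(Q) > 0) {
    s <- apply(Q, 2, stats::sd)
    s[s == 0] <- 1
    Q <- sweep(Q, 2, s, "/")
  }
  dplyr::bind_cols(tibble::tibble(line_id = basis$line_ids),
                   tibble::as_tibble(Q))
}
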