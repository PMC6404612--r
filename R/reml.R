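#' Specify a multi-kernel linear mixed model
#'
#' Assembles the pieces of the model
#' \deqn{y = 1\mu + X\beta + ZQ\gamma + \sum_l Z g_l + \varepsilon}
#' for one trait: the record vector over non-missing phenotypes, the
#' fixed-effect design (intercept, trial dummies with the first level as
#' reference, and optionally the structure covariates Q), the record-to-line
#' incidence, and the ordered list of genetic relationship kernels, each term
#' with its own variance \eqn{\sigma^2_l} and \eqn{g_l \sim N(0, \sigma^2_l
#' K_l)}. Kernels carrying no nugget receive a `ridge` on the diagonal so the
#' phenotypic covariance is guaranteed invertible.
#'
#' Lines present in the kernels but without records are retained: their BLUPs
#' are predicted through the kernel relationships, which is how masked lines
#' are predicted in cross-validation.
#'
#' @param pheno Phenotype tibble (`line_id`, `trial_id`, trait columns).
#' @param trait Name of the trait column to model.
#' @param kernels Named list of `genetic_kernel`s over a common line set and
#'   ordering; the names become the term labels.
#' @param structure Optional [decompose_structure()] result (or a tibble from
#'   [structure_covariates()]); its scaled PC scores enter the fixed design.
#' @param ridge Nugget added to any kernel whose recorded nugget is zero.
#' @return A `model_spec` object consumed by [fit_reml()].
#' @export
model_spec <- function(pheno, trait, kernels, structure = NULL, ridge = 0.01) {
  if (!trait %in% names(pheno)) stop("Trait '", trait, "' not in `pheno`.",
                                     call. = FALSE)
  if (is.null(names(kernels)) || any(names(kernels) == "")) {
    stop("`kernels` must be a named list.", call. = FALSE)
  }
  lines <- rownames(kernels[[1]])
  for (i in seq_along(kernels)[-1]) {
    if (!identical(rownames(kernels[[i]]), lines)) {
      stop("All kernels must share the same line IDs in the same order.",
           call. = FALSE)
    }
  }
  kernels <- lapply(kernels, function(k) {
    if (kernel_nugget(k) == 0 && ridge > 0) add_nugget(k, ridge) else k
  })

  rec <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  if (!nrow(rec)) stop("No non-missing records for trait '", trait, "'.",
                       call. = FALSE)
  miss_ln <- setdiff(unique(rec$line_id), lines)
  if (length(miss_ln)) {
    stop("Phenotyped line(s) absent from the kernels: ",
         paste(utils::head(miss_ln, 5), collapse = ", "), call. = FALSE)
  }
  y <- as.numeric(rec[[trait]])
  z_idx <- match(rec$line_id, lines)

  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  trials <- sort(unique(rec$trial_id))
  if (length(trials) > 1) {
    f <- factor(rec$trial_id, levels = trials)
    Xt <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(Xt) <- paste0("trial_", trials[-1])
    X <- cbind(X, Xt)
  }
  q_cols <- character(0)
  Q_line <- NULL
  if (!is.null(structure)) {
    qc <- if (inherits(structure, "structure_basis")) {
      structure_covariates(structure)
    } else {
      structure
    }
    if (ncol(qc) > 1) {
      qm <- as.matrix(qc[, -1, drop = FALSE])
      rownames(qm) <- qc$line_id
      if (!all(lines %in% rownames(qm))) {
        stop("Structure covariates missing for some kernel lines.", call. = FALSE)
      }
      Q_line <- qm[lines, , drop = FALSE]
      q_cols <- colnames(Q_line)
      X <- cbind(X, Q_line[z_idx, , drop = FALSE])
    }
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("Fixed-effect design is singular; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (length(y) <= ncol(X)) {
    stop("Fewer records than fixed-effect parameters.", call. = FALSE)
  }
  structure(
    list(y = y, X = X, z_idx = z_idx, kernels = kernels, lines = lines,
         trait = trait, record_lines = rec$line_id, record_trials = rec$trial_id,
         q_cols = q_cols, Q_line = Q_line),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> trait '", x$trait, "': ", length(x$y), " records, ",
      length(x$lines), " lines\n  fixed: ", ncol(x$X), " columns (",
      paste(utils::head(colnames(x$X), 6), collapse = ", "),
      if (ncol(x$X) > 6) ", ..." else "", ")\n  random terms: ",
      paste(names(x$kernels), collapse = ", "), " + residual\n", sep = "")
  invisible(x)
}

#' Fit a multi-kernel mixed model by average-information REML
#'
#' Maximizes the restricted likelihood over the variance components of every
#' genetic term and the residual using average-information (AI) updates with
#' step halving; when an AI step fails to improve the likelihood, a scaled
#' gradient (EM-type) step is used instead. Components are bounded below at
#' `1e-8` times the phenotypic variance; a component that finishes on that
#' bound is reported as zero and flagged `boundary`. Convergence is declared
#' when the restricted log-likelihood changes by less than `tol` between
#' accepted iterations.
#'
#' @param spec A [model_spec()].
#' @param max_iter Maximum number of iterations before a non-convergence error
#'   (the error condition carries the likelihood trajectory in
#'   `$trajectory`).
#' @param tol Absolute convergence tolerance on the restricted log-likelihood.
#' @param start Optional starting values for the variance components
#'   (terms..., residual); defaults to an equal split of the phenotypic
#'   variance.
#' @param verbose Print the likelihood path.
#' @return A `reml_fit` with elements `sigma2` (named; boundary components
#'   reported 0), `se` (from the inverse AI matrix), `ai_matrix`, `loglik`,
#'   `aic`, `blups` (lines-by-terms matrix), `beta`, `gamma`, `boundary`,
#'   `converged`, `iterations`, plus the data pieces needed by downstream
#'   methods.
#' @seealso [tidy.reml_fit()], [glance.reml_fit()], [blup_effects()],
#'   [model_aic()], [likelihood_ratio_test()], [sampling_correlations()]
#' @export
fit_reml <- function(spec, max_iter = 200, tol = 1e-6, start = NULL,
                     verbose = FALSE) {
  y <- spec$y
  X <- spec$X
  n <- length(y)
  L <- length(spec$kernels)
  labs <- names(spec$kernels)
  Vl <- lapply(spec$kernels, function(k) {
    unclass(k)[spec$z_idx, spec$z_idx, drop = FALSE]
  })
  vp <- stats::var(y)
  lb <- 1e-8 * vp
  theta <- if (is.null(start)) rep(vp / (L + 1), L + 1) else as.numeric(start)
  if (length(theta) != L + 1 || any(theta <= 0)) {
    stop("`start` must give ", L + 1, " positive variances.", call. = FALSE)
  }

  eval_ll <- function(th) {
    V <- diag(rep(th[L + 1], n))
    for (l in seq_len(L)) V <- V + th[l] * Vl[[l]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Viy <- backsolve(ch, forwardsolve(t(ch), y))
    ViX <- backsolve(ch, forwardsolve(t(ch), X))
    XtViX <- crossprod(X, ViX)
    chx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    beta <- backsolve(chx, forwardsolve(t(chx), crossprod(X, Viy)))
    Py <- as.numeric(Viy - ViX %*% beta)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py) + (n - ncol(X)) * log(2 * pi))
    list(ll = as.numeric(ll), Py = Py, beta = as.numeric(beta), ch = ch,
         chx = chx, ViX = ViX)
  }

  cur <- eval_ll(theta)
  if (is.null(cur)) stop("Initial covariance matrix not positive definite.",
                         call. = FALSE)
  trajectory <- cur$ll
  converged <- FALSE
  iter <- 0
  score <- rep(NA_real_, L + 1)
  AI <- NULL

  while (iter < max_iter) {
    iter <- iter + 1
    # full pieces: projection matrix for traces
    Vi <- chol2inv(cur$ch)
    Bx <- backsolve(cur$chx, forwardsolve(t(cur$chx), t(cur$ViX)))
    P <- Vi - cur$ViX %*% Bx
    Py <- cur$Py
    tmat <- matrix(0, n, L + 1)
    tr <- numeric(L + 1)
    for (l in seq_len(L)) {
      tr[l] <- sum(P * Vl[[l]])
      tmat[, l] <- Vl[[l]] %*% Py
    }
    tr[L + 1] <- sum(diag(P))
    tmat[, L + 1] <- Py
    ypvpy <- as.numeric(crossprod(tmat, Py))
    score <- -0.5 * (tr - ypvpy)
    PT <- P %*% tmat
    AI <- 0.5 * crossprod(tmat, PT)

    # active set: hold components clamped at the bound with downhill gradient
    at_lb <- theta <= lb * (1 + 1e-8)
    free <- !(at_lb & score < 0)
    delta <- rep(0, L + 1)
    ok <- FALSE
    if (any(free)) {
      sol <- tryCatch(solve(AI[free, free, drop = FALSE], score[free]),
                      error = function(e) NULL)
      if (!is.null(sol)) {
        delta[free] <- sol
        ok <- TRUE
      }
    }
    if (!ok) delta <- 2 * theta^2 * score / n  # EM-type scaled gradient

    accepted <- FALSE
    for (attempt in 1:2) {
      step <- 1
      for (h in 1:20) {
        cand <- pmax(theta + step * delta, lb)
        ev <- eval_ll(cand)
        if (!is.null(ev) && ev$ll >= cur$ll - 1e-10) {
          theta <- cand
          cur <- ev
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (accepted || attempt == 2) break
      delta <- 2 * theta^2 * score / n  # AI step failed entirely: EM fallback
    }
    trajectory <- c(trajectory, cur$ll)
    if (verbose) {
      cat(sprintf("iter %3d  logLik %.8f\n", iter, cur$ll))
    }
    if (!accepted) {
      converged <- TRUE  # no direction improves the likelihood
      break
    }
    dl <- trajectory[length(trajectory)] - trajectory[length(trajectory) - 1]
    if (abs(dl) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    cond <- structure(
      class = c("sgblup_nonconvergence", "error", "condition"),
      list(message = paste0("REML did not converge in ", max_iter,
                            " iterations (last change ",
                            format(diff(utils::tail(trajectory, 2))), ")."),
           call = sys.call(-1), trajectory = trajectory)
    )
    stop(cond)
  }

  at_lb <- theta <= lb * (1 + 1e-6)
  sigma2 <- theta
  sigma2[seq_len(L)][at_lb[seq_len(L)]] <- 0
  names(sigma2) <- c(labs, "residual")
  se <- rep(NA_real_, L + 1)
  ai_inv <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(ai_inv)) se <- sqrt(pmax(diag(ai_inv), 0))
  names(se) <- names(sigma2)

  # BLUPs: g_l = sigma2_l K_l Z' P y (zero exactly for boundary terms)
  u <- rep(0, length(spec$lines))
  agg <- rowsum(cur$Py, group = spec$z_idx)
  u[as.integer(rownames(agg))] <- agg[, 1]
  blups <- matrix(0, length(spec$lines), L,
                  dimnames = list(spec$lines, labs))
  for (l in seq_len(L)) {
    if (sigma2[l] > 0) {
      blups[, l] <- sigma2[l] * (unclass(spec$kernels[[l]]) %*% u)
    }
  }
  beta_all <- cur$beta
  names(beta_all) <- colnames(X)
  is_gamma <- names(beta_all) %in% spec$q_cols
  fitted <- as.numeric(X %*% beta_all) +
    unname(rowSums(blups[spec$z_idx, , drop = FALSE]))
  ll <- cur$ll
  fit <- structure(
    list(sigma2 = sigma2, se = se, ai_matrix = AI, loglik = ll,
         aic = -2 * ll + 2 * (L + 1), n_vc = L + 1,
         blups = blups, beta = beta_all[!is_gamma], gamma = beta_all[is_gamma],
         boundary = stats::setNames(at_lb, names(sigma2)),
         converged = converged, iterations = iter, trajectory = trajectory,
         fitted = fitted, residuals = y - fitted, spec = spec),
    class = "reml_fit"
  )
  fit
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit> trait '", x$spec$trait, "': ", length(x$spec$y), " records, ",
      x$iterations, " iterations\n", sep = "")
  cat("  logLik ", format(x$loglik, digits = 8), ", AIC ",
      format(x$aic, digits = 8), "\n", sep = "")
  df <- data.frame(term = names(x$sigma2), sigma2 = unname(x$sigma2),
                   se = unname(x$se),
                   boundary = ifelse(unname(x$boundary), "*", ""))
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}
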