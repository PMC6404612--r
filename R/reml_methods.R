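#' Tidy the variance components of a REML fit
#'
#' @param x A [fit_reml()] result.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`, `boundary`.
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble::tibble(term = names(x$sigma2),
                 estimate = unname(x$sigma2),
                 std.error = unname(x$se),
                 boundary = unname(x$boundary))
}

#' One-row summary of a REML fit
#'
#' @param x A [fit_reml()] result.
#' @param ... Unused.
#' @return Tibble with `logLik`, `AIC`, `nobs`, `n_lines`, `n_terms`,
#'   `converged`, `iterations`.
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, nobs = length(x$spec$y),
                 n_lines = length(x$spec$lines),
                 n_terms = length(x$spec$kernels),
                 converged = x$converged, iterations = x$iterations)
}

#' Per-term BLUP effect vectors
#'
#' Mixed-model-equation solutions \eqn{\hat g_l = \sigma^2_l K_l Z^T P y} for
#' every random genetic term, evaluated at the converged variance estimates.
#' Terms whose variance was estimated on the zero boundary return exact zero
#' vectors. Lines without records receive predictions through the kernel.
#'
#' @param fit A converged [fit_reml()] result.
#' @return Tibble with `line_id` and one column per genetic term.
#' @export
blup_effects <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  dplyr::bind_cols(tibble::tibble(line_id = rownames(fit$blups)),
                   tibble::as_tibble(fit$blups))
}

#' Akaike's information criterion for a REML fit
#'
#' \eqn{AIC = -2 \ell_R + 2t} with \eqn{t} the number of variance parameters
#' (all genetic terms plus the residual; components clamped on the boundary
#' are still counted). Because the likelihood is restricted, AIC values are
#' only comparable between fits sharing the same fixed-effect design —
#' use [compare_models()] to get a warning when they do not.
#'
#' @param fit A converged [fit_reml()] result.
#' @return The AIC (scalar).
#' @export
model_aic <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  fit$aic
}

#' Compare several REML fits by AIC
#'
#' @param ... Named `reml_fit` objects.
#' @return Tibble with one row per model (`model`, `n_terms`, `logLik`,
#'   `AIC`), sorted by AIC. A warning is attached when the fits do not share
#'   the same fixed-effect design (their REML likelihoods are then not
#'   comparable).
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "reml_fit")) {
    fits <- fits[[1]]
  }
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model_", seq_along(fits))
  designs <- lapply(fits, function(f) f$spec$X)
  same <- all(vapply(designs[-1], function(d) isTRUE(all.equal(d, designs[[1]])),
                     logical(1)))
  if (!same) {
    warning("Fits have different fixed-effect designs; REML AIC values are ",
            "not comparable across them.", call. = FALSE)
  }
  out <- tibble::tibble(
    model = nm,
    n_terms = vapply(fits, function(f) length(f$spec$kernels), integer(1)),
    logLik = vapply(fits, function(f) f$loglik, double(1)),
    AIC = vapply(fits, function(f) f$aic, double(1))
  )
  dplyr::arrange(out, .data$AIC)
}

#' Likelihood-ratio test between nested REML fits
#'
#' Tests whether the extra variance components of the full model improve the
#' restricted likelihood. Because a variance component lies on the boundary of
#' its parameter space under the null, the default reference distribution is
#' the equal mixture \eqn{0.5\,\chi^2_0 + 0.5\,\chi^2_d} for `d` added
#' components; set `boundary_mixture = FALSE` for the plain \eqn{\chi^2_d}.
#' Both fits must share data and fixed-effect design and the reduced model's
#' random terms must be a subset of the full model's.
#'
#' @param full,reduced Converged [fit_reml()] results.
#' @param boundary_mixture Use the 50:50 boundary mixture null (default).
#' @return Tibble with `statistic`, `df`, `p.value`, `method`.
#' @export
likelihood_ratio_test <- function(full, reduced, boundary_mixture = TRUE) {
  stopifnot(inherits(full, "reml_fit"), inherits(reduced, "reml_fit"))
  if (!all(names(reduced$spec$kernels) %in% names(full$spec$kernels))) {
    stop("Models are not nested: reduced terms must be a subset of full terms.",
         call. = FALSE)
  }
  d <- length(full$spec$kernels) - length(reduced$spec$kernels)
  if (d < 0) stop("`full` has fewer random terms than `reduced`.", call. = FALSE)
  if (!isTRUE(all.equal(full$spec$y, reduced$spec$y)) ||
      !isTRUE(all.equal(full$spec$X, reduced$spec$X))) {
    stop("Fits must share the same records and fixed-effect design.",
         call. = FALSE)
  }
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  if (d == 0) {
    p <- 1
  } else if (boundary_mixture) {
    p <- if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, df = d, lower.tail = FALSE)
  } else {
    p <- stats::pchisq(stat, df = d, lower.tail = FALSE)
  }
  tibble::tibble(statistic = stat, df = d, p.value = p,
                 method = if (boundary_mixture) "0.5*chisq(0) + 0.5*chisq(d)"
                 else "chisq(d)")
}

#' Sampling correlations of variance-component estimates
#'
#' Asymptotic correlations of the REML variance estimates, derived from the
#' inverse of the average-information matrix at convergence (whose inverse
#' approximates the sampling covariance of the estimates).
#'
#' @param fit A converged [fit_reml()] result.
#' @param include_residual Also include the residual variance (default keeps
#'   only the genetic terms).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sampling_correlations <- function(fit, include_residual = FALSE) {
  stopifnot(inherits(fit, "reml_fit"))
  Ci <- tryCatch(solve(fit$ai_matrix), error = function(e) NULL)
  if (is.null(Ci)) {
    stop("Average-information matrix is singular; consider dropping boundary ",
         "terms or simplifying the model.", call. = FALSE)
  }
  rownames(Ci) <- colnames(Ci) <- names(fit$sigma2)
  if (!include_residual) {
    keep <- setdiff(names(fit$sigma2), "residual")
    Ci <- Ci[keep, keep, drop = FALSE]
  }
  stats::cov2cor(Ci)
}
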