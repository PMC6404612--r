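#' Assemble whole-genome and subgenome effect predictions
#'
#' Collects the per-term BLUPs of a fit into an effect table: the subgenome
#' estimated breeding values (SGEBVs: columns `A`, `B`, `D`), any interaction
#' effects (`AB`, `AD`, `BD`, `ABD`), the centered population-structure
#' contribution \eqn{Q\gamma} when structure covariates were fitted, and the
#' whole-genome value — the sum of the centered structure contribution and all
#' genetic term effects.
#'
#' @param fit A converged [fit_reml()] result.
#' @return An `effect_table`: tibble with `line_id`, one column per genetic
#'   term, `structure`, and `whole_genome`. The additivity
#'   `whole_genome = structure + sum(terms)` holds exactly.
#' @export
assemble_effects <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  eff <- blup_effects(fit)
  sc <- rep(0, nrow(eff))
  if (length(fit$gamma)) {
    if (is.null(fit$spec$Q_line)) {
      stop("Structure slopes were fitted but the covariates are unavailable.",
           call. = FALSE)
    }
    qg <- as.numeric(fit$spec$Q_line[, names(fit$gamma), drop = FALSE] %*%
                       fit$gamma)
    sc <- qg - mean(qg)
  }
  terms <- setdiff(names(eff), "line_id")
  eff$structure <- sc
  eff$whole_genome <- rowSums(as.matrix(eff[terms])) + sc
  out <- tibble::new_tibble(eff, class = "effect_table")
  attr(out, "terms") <- terms
  out
}

#' Quantile flags and ranks for effect columns
#'
#' For each effect column, flags the lines at or above the `q`-quantile (the
#' parental-candidate rule: the upper 95% quantile by default) and assigns a
#' dense rank with 1 the highest value.
#'
#' @param effects An [assemble_effects()] table (or any tibble with `line_id`
#'   and numeric effect columns).
#' @param q Quantile threshold in (0, 1); default 0.95.
#' @return Long tibble with columns `line_id`, `term`, `value`, `rank`,
#'   `top_quantile`.
#' @export
quantile_report <- function(effects, q = 0.95) {
  if (nrow(effects) < 2) stop("Need at least 2 lines.", call. = FALSE)
  cols <- names(effects)[vapply(effects, is.numeric, logical(1))]
  long <- tidyr::pivot_longer(effects[c("line_id", cols)], -"line_id",
                              names_to = "term", values_to = "value")
  dplyr::mutate(
    dplyr::group_by(long, .data$term),
    rank = dplyr::min_rank(dplyr::desc(.data$value)),
    top_quantile = .data$value >= stats::quantile(.data$value, q),
    .keep = "all"
  ) |> dplyr::ungroup()
}
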