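#' "True" genetic values from an identity-covariance fit
#'
#' The reference values that cross-validation predictions are correlated
#' against: line BLUPs from the same trial-adjusted mixed model but with the
#' genetic covariance replaced by the identity, so every line's value is
#' informed only by its own records (replicated checks pool information across
#' all of theirs). Lines with no records get no value.
#'
#' @param pheno Phenotype tibble (`line_id`, `trial_id`, trait columns).
#' @param trait Trait column name.
#' @return Tibble with `line_id` and `true_value` for every phenotyped line.
#' @export
true_genetic_values <- function(pheno, trait) {
  rec <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  lines <- sort(unique(rec$line_id))
  Im <- diag(length(lines))
  dimnames(Im) <- list(lines, lines)
  K <- new_genetic_kernel(Im, label = "G", c = 1, nugget = 0)
  spec <- model_spec(rec, trait, kernels = list(G = K), ridge = 0)
  fit <- fit_reml(spec)
  tibble::tibble(line_id = lines, true_value = as.numeric(fit$blups[, "G"]))
}

#' Fold sizes for k-fold cross-validation
#'
#' `n` lines are split into `folds` groups of `floor(n/folds)` lines, with the
#' remainder pooled into the final group (so 1,447 lines in 5 folds gives four
#' groups of 289 and one of 291).
#'
#' @param n Number of lines.
#' @param folds Number of folds.
#' @return Integer vector of group sizes summing to `n`.
#' @export
cv_fold_sizes <- function(n, folds = 5) {
  base <- n %/% folds
  if (base < 1) stop("More folds than lines.", call. = FALSE)
  sizes <- rep(base, folds)
  sizes[folds] <- sizes[folds] + n - base * folds
  sizes
}

#' Replicated k-fold cross-validation of genomic prediction
#'
#' For each replicate the genotyped lines are randomly partitioned into
#' `folds` groups; for each fold, *all* records of its lines are masked, the
#' model is refit on the remaining records, and the masked lines' whole-genome
#' values are predicted through the kernel relationships (kernels and allele
#' frequencies are computed once from all genotypes and never re-estimated per
#' fold). The pooled predictions of a replicate are correlated once with the
#' identity-covariance "true" values, giving one accuracy per replicate.
#'
#' @param pheno Phenotype tibble (`line_id`, `trial_id`, trait columns); every
#'   phenotyped line must be genotyped.
#' @param marker_set A complete [marker_set()] with subgenomes assigned.
#' @param trait Trait column name.
#' @param model Model family passed to [build_kernels()]: `"G"`, `"ABD"`,
#'   `"GxG"` or `"ABDxABD"`.
#' @param k Number of principal components removed as population structure
#'   (0 = no correction); with `k > 0` the kernels are built from the deflated
#'   matrix and the scaled PC scores enter the fixed design.
#' @param folds,reps Cross-validation layout (defaults 5 and 10).
#' @param seed Integer seed; the whole result is reproducible given
#'   `(seed, model, data)`.
#' @param include_structure Include the centered fixed structure contribution
#'   \eqn{Q\gamma} in the predicted whole-genome value (default `TRUE`).
#' @param true_values Optional precomputed [true_genetic_values()] table.
#' @param nugget,exact_h,three_way Passed to [build_kernels()].
#' @return A `cv_result`: list with `folds` (tibble rep/line_id/fold),
#'   `accuracies` (tibble rep/accuracy), `mean`, `sd`, `seed`, `model`, `k`.
#' @export
cross_validate <- function(pheno, marker_set, trait,
                           model = c("ABD", "G", "GxG", "ABDxABD"),
                           k = 0, folds = 5, reps = 10, seed,
                           include_structure = TRUE, true_values = NULL,
                           nugget = 0.01, exact_h = TRUE, three_way = FALSE) {
  model <- match.arg(model)
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  set.seed(seed)
  basis <- NULL
  ms_work <- marker_set
  if (k > 0) {
    basis <- decompose_structure(marker_set, k)
    ms_work <- deflate_markers(basis)
  }
  kernels <- build_kernels(ms_work, model = model, nugget = nugget,
                           exact_h = exact_h, three_way = three_way)
  lines <- rownames(kernels[[1]])
  rec <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  if (!all(rec$line_id %in% lines)) {
    stop("Every phenotyped line must be genotyped.", call. = FALSE)
  }
  if (is.null(true_values)) true_values <- true_genetic_values(pheno, trait)

  ph_lines <- intersect(lines, unique(rec$line_id))
  n <- length(ph_lines)
  sizes <- cv_fold_sizes(n, folds)
  fold_tbl <- list()
  acc <- numeric(reps)
  for (r in seq_len(reps)) {
    perm <- sample(ph_lines)
    fold_of <- stats::setNames(rep(seq_len(folds), times = sizes), perm)
    preds <- stats::setNames(rep(NA_real_, n), ph_lines)
    for (f in seq_len(folds)) {
      test_lines <- names(fold_of)[fold_of == f]
      train <- rec[!rec$line_id %in% test_lines, , drop = FALSE]
      stopifnot(!any(train$line_id %in% test_lines))  # masking is total
      lost <- setdiff(unique(rec$trial_id), unique(train$trial_id))
      if (length(lost)) {
        stop("Training fold lost all records of trial(s) ",
             paste(lost, collapse = ", "),
             "; the trial fixed effect is inestimable. Use fewer folds.",
             call. = FALSE)
      }
      spec <- model_spec(train, trait, kernels = kernels, structure = basis,
                         ridge = nugget)
      fit <- fit_reml(spec)
      eff <- assemble_effects(fit)
      val <- if (include_structure) eff$whole_genome else
        eff$whole_genome - eff$structure
      names(val) <- eff$line_id
      preds[test_lines] <- val[test_lines]
    }
    tv <- true_values$true_value[match(ph_lines, true_values$line_id)]
    ok <- !is.na(tv) & !is.na(preds)
    # constant predictions (all genetic terms on the boundary) carry no
    # discriminating information: the accuracy is reported as 0
    acc[r] <- if (stats::sd(preds[ok]) == 0 || stats::sd(tv[ok]) == 0) 0 else
      stats::cor(preds[ok], tv[ok])
    fold_tbl[[r]] <- tibble::tibble(rep = r, line_id = names(fold_of),
                                    fold = unname(fold_of))
  }
  structure(
    list(folds = dplyr::bind_rows(fold_tbl),
         accuracies = tibble::tibble(rep = seq_len(reps), accuracy = acc),
         mean = mean(acc), sd = stats::sd(acc),
         seed = seed, model = model, k = k, trait = trait),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> model ", x$model, ", trait '", x$trait, "', k = ", x$k,
      "\n  ", nrow(x$accuracies), " replicates: mean accuracy ",
      format(x$mean, digits = 4), " (SD ", format(x$sd, digits = 3), ")\n",
      sep = "")
  invisible(x)
}

#' Tidy / summarize a cross-validation result
#'
#' @param x A [cross_validate()] result.
#' @param ... Unused.
#' @return `tidy()`: per-replicate accuracies; `glance()`: one-row summary.
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::mutate(x$accuracies, model = x$model, trait = x$trait, k = x$k)
}

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(model = x$model, trait = x$trait, k = x$k,
                 reps = nrow(x$accuracies), mean_accuracy = x$mean,
                 sd_accuracy = x$sd, seed = x$seed)
}
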