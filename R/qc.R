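#' Assign markers to subgenomes from chromosome labels
#'
#' Hexaploid wheat chromosomes follow the `1A`...`7D` convention, where the
#' trailing letter names the ancestral subgenome. Any chromosome label matching
#' `digit(1-7) + letter(A|B|D)` is parsed directly; other labels must be
#' covered by an explicit `override` table.
#'
#' @param marker_set A [marker_set()].
#' @param map Optional marker map tibble (`marker_id`, `chrom`); required when
#'   the marker set carries no chromosome labels. A marker present in the score
#'   matrix but absent from the map is an error naming the marker.
#' @param override Optional tibble/data frame with columns `chrom` and
#'   `subgenome` mapping non-standard chromosome names to a subgenome.
#' @return The marker set with its `subgenome` field populated; the assignment
#'   is a disjoint cover of all markers.
#' @export
assign_subgenomes <- function(marker_set, map = NULL, override = NULL) {
  x <- marker_set
  chrom <- x$chrom
  if (!is.null(map)) {
    idx <- match(marker_ids(x), as.character(map$marker_id))
    if (anyNA(idx)) {
      missing_mk <- marker_ids(x)[is.na(idx)]
      stop("Markers absent from the map: ",
           paste(utils::head(missing_mk, 5), collapse = ", "),
           if (length(missing_mk) > 5) ", ..." else "", call. = FALSE)
    }
    chrom <- as.character(map$chrom)[idx]
  }
  if (is.null(chrom)) {
    stop("No chromosome labels available; supply `map`.", call. = FALSE)
  }
  sub <- ifelse(grepl("^[1-7][ABD]$", chrom), substr(chrom, 2, 2), NA_character_)
  if (!is.null(override)) {
    oidx <- match(chrom, as.character(override$chrom))
    sub[!is.na(oidx)] <- as.character(override$subgenome)[oidx[!is.na(oidx)]]
  }
  if (anyNA(sub)) {
    bad <- unique(chrom[is.na(sub)])
    stop("Cannot assign subgenome for chromosome label(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         ". Supply an `override` table.", call. = FALSE)
  }
  marker_set(x$scores, chrom = chrom, subgenome = sub, coding = x$coding)
}

#' Quality-filter markers
#'
#' Removes markers failing any of three rules, evaluated on the input matrix
#' (so the surviving set does not depend on the order the rules are applied):
#' minor-allele frequency below `maf_min`, missing-call fraction above
#' `max_missing`, or heterozygous-call fraction above `max_het` (only possible
#' under \{0,1,2\} coding). MAF is computed from non-missing calls, counting a
#' heterozygote as one copy of each allele.
#'
#' @param marker_set A [marker_set()].
#' @param maf_min,max_missing,max_het Thresholds in \[0, 1\]. Defaults 0.01,
#'   0.30 and 0.10.
#' @return The filtered marker set, with a `filter_report` attribute: a tibble
#'   of per-rule failure counts (a marker can fail several rules).
#' @export
filter_markers <- function(marker_set, maf_min = 0.01, max_missing = 0.30,
                           max_het = 0.10) {
  x <- marker_set
  thr <- c(maf_min, max_missing, max_het)
  if (any(thr < 0 | thr > 1)) stop("Thresholds must lie in [0, 1].", call. = FALSE)
  if (x$coding == "real") {
    stop("Cannot quality-filter real-valued (deflated) scores.", call. = FALSE)
  }
  maf <- marker_maf(x)
  miss <- colMeans(is.na(x$scores))
  het <- if (x$coding == "012") colMeans(x$scores == 1, na.rm = TRUE) else
    rep(0, n_markers(x))
  het[is.nan(het)] <- 0
  fail_maf <- is.na(maf) | maf < maf_min
  fail_miss <- miss > max_missing
  fail_het <- het > max_het
  keep <- !(fail_maf | fail_miss | fail_het)
  if (!any(keep)) stop("All markers removed by quality filters.", call. = FALSE)
  report <- tibble::tibble(
    rule = c("maf", "missing", "het"),
    threshold = thr,
    n_failed = c(sum(fail_maf), sum(fail_miss), sum(fail_het))
  )
  out <- subset_markers(x, keep)
  attr(out, "filter_report") <- report
  out
}

#' Impute missing scores (and heterozygous calls) with the population mode
#'
#' Each marker's missing scores are replaced with that marker's most frequent
#' call; with `het_policy = "to_mode"` (the default) heterozygous calls under
#' \{0,1,2\} coding are also replaced, with the mode taken over the homozygous
#' calls (the major-allele homozygote). A tie in the mode is broken
#' deterministically toward the lower score value and reported in a warning.
#'
#' A custom imputation routine can be plugged in through `imputer`: a function
#' `marker_set -> marker_set` that removes all missingness; it bypasses the
#' mode rule entirely.
#'
#' @param marker_set A filtered [marker_set()].
#' @param het_policy `"to_mode"` to replace heterozygous calls, `"keep"` to
#'   leave them.
#' @param imputer Optional user-supplied imputation function.
#' @return A marker set with no missing entries.
#' @export
impute_mode <- function(marker_set, het_policy = c("to_mode", "keep"),
                        imputer = NULL) {
  x <- marker_set
  het_policy <- match.arg(het_policy)
  if (!is.null(imputer)) {
    out <- imputer(x)
    if (anyNA(out$scores)) stop("Supplied imputer left missing scores.", call. = FALSE)
    return(out)
  }
  s <- x$scores
  ties <- character(0)
  replace_het <- het_policy == "to_mode" && x$coding == "012"
  for (j in seq_len(ncol(s))) {
    v <- s[, j]
    na <- is.na(v)
    het <- if (replace_het) (!na & v == 1) else rep(FALSE, length(v))
    if (!any(na) && !any(het)) next
    pool <- v[!na]
    if (replace_het) {
      hompool <- pool[pool != 1]
      if (length(hompool)) pool <- hompool
    }
    if (!length(pool)) {
      stop("Marker ", colnames(s)[j], " has no usable calls for imputation.",
           call. = FALSE)
    }
    cnt <- table(pool)
    best <- as.numeric(names(cnt)[cnt == max(cnt)])
    if (length(best) > 1) ties <- c(ties, colnames(s)[j])
    mode_val <- min(best)  # tie-break toward the lower (major/reference) score
    v[na | het] <- mode_val
    s[, j] <- v
  }
  if (length(ties)) {
    warning("Mode tie broken toward the lower score for marker(s): ",
            paste(utils::head(ties, 5), collapse = ", "),
            if (length(ties) > 5) ", ..." else "", call. = FALSE)
  }
  marker_set(s, chrom = x$chrom, subgenome = x$subgenome, coding = x$coding)
}

#' Standardize phenotypes to zero mean and unit variance
#'
#' Each trait is centered and scaled using its global (not per-environment)
#' mean and standard deviation over non-missing records, so relationships
#' between environments are preserved. The scale used is stored in the
#' `scale_info` attribute for back-transformation with
#' [destandardize_phenotypes()].
#'
#' @param pheno Phenotype tibble (`line_id`, `trial_id`, trait columns).
#' @param traits Character vector of trait columns to standardize; defaults to
#'   every column other than `line_id`/`trial_id`.
#' @return The phenotype tibble with standardized traits and a `scale_info`
#'   attribute (tibble of trait, mean, sd).
#' @export
standardize_phenotypes <- function(pheno, traits = NULL) {
  if (is.null(traits)) traits <- setdiff(names(pheno), c("line_id", "trial_id"))
  info <- attr(pheno, "scale_info")
  if (is.null(info)) info <- tibble::tibble(trait = character(), mean = double(),
                                            sd = double())
  for (tr in traits) {
    v <- pheno[[tr]]
    mu <- mean(v, na.rm = TRUE)
    sd_v <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(sd_v) || sd_v == 0) {
      stop("Trait '", tr, "' is constant; cannot standardize.", call. = FALSE)
    }
    pheno[[tr]] <- (v - mu) / sd_v
    info <- dplyr::bind_rows(dplyr::filter(info, .data$trait != tr),
                             tibble::tibble(trait = tr, mean = mu, sd = sd_v))
  }
  attr(pheno, "scale_info") <- info
  pheno
}

#' @rdname standardize_phenotypes
#' @param scale_info Scale table as stored by [standardize_phenotypes()];
#'   defaults to the attribute on `pheno`.
#' @export
destandardize_phenotypes <- function(pheno, scale_info = attr(pheno, "scale_info")) {
  if (is.null(scale_info) || !nrow(scale_info)) {
    stop("No scale information available.", call. = FALSE)
  }
  for (i in seq_len(nrow(scale_info))) {
    tr <- scale_info$trait[i]
    pheno[[tr]] <- pheno[[tr]] * scale_info$sd[i] + scale_info$mean[i]
  }
  attr(pheno, "scale_info") <- NULL
  pheno
}
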