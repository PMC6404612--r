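#' Construct a marker set
#'
#' A `marker_set` holds a line-by-marker matrix of allele scores together with
#' the chromosome and subgenome assignment of every marker. Scores are coded
#' either as diploid minor-allele counts in \{0, 1, 2\} or, for fully inbred
#' material, as boolean minor-allele indicators in \{0, 1\}. Missing scores are
#' allowed until [impute_mode()] has been applied. After population structure
#' has been removed with [decompose_structure()], the scores become real-valued
#' and the coding is recorded as `"real"`.
#'
#' @param scores Numeric matrix, lines in rows and markers in columns.
#'   Row names are line identifiers, column names marker identifiers; both are
#'   required and must be unique.
#' @param chrom Optional character vector of chromosome labels, one per marker
#'   (e.g. `"1A"` ... `"7D"`).
#' @param subgenome Optional character vector of subgenome labels, one per
#'   marker. Usually filled by [assign_subgenomes()].
#' @param coding Score alphabet: `"012"`, `"01"` or `"real"`. Auto-detected
#'   when `NULL`: `"012"` if any score equals 2, otherwise `"01"`; any
#'   non-integer score gives `"real"`.
#'
#' @return An object of class `marker_set`.
#' @examples
#' m <- matrix(c(0, 1, 2, 0), 2, 2,
#'             dimnames = list(c("L1", "L2"), c("mk1", "mk2")))
#' marker_set(m, chrom = c("1A", "3D"))
#' @export
marker_set <- function(scores, chrom = NULL, subgenome = NULL, coding = NULL) {
  if (!is.matrix(scores) || !is.numeric(scores)) {
    stop("`scores` must be a numeric matrix (lines x markers).", call. = FALSE)
  }
  ln <- rownames(scores)
  mk <- colnames(scores)
  if (is.null(ln) || is.null(mk)) {
    stop("`scores` must carry line IDs as row names and marker IDs as column names.",
         call. = FALSE)
  }
  if (anyDuplicated(ln)) {
    stop("Duplicate line IDs: ", paste(unique(ln[duplicated(ln)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(mk)) {
    stop("Duplicate marker IDs: ", paste(unique(mk[duplicated(mk)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(coding)) {
    obs <- scores[!is.na(scores)]
    coding <- if (any(obs != round(obs))) "real" else if (any(obs == 2)) "012" else "01"
  }
  coding <- match.arg(coding, c("012", "01", "real"))
  if (coding != "real") {
    obs <- scores[!is.na(scores)]
    allowed <- if (coding == "012") c(0, 1, 2) else c(0, 1)
    if (length(obs) && !all(obs %in% allowed)) {
      stop("Scores outside the declared coding set {", paste(allowed, collapse = ","),
           "}.", call. = FALSE)
    }
  }
  if (!is.null(chrom) && length(chrom) != ncol(scores)) {
    stop("`chrom` must have one entry per marker.", call. = FALSE)
  }
  if (!is.null(subgenome) && length(subgenome) != ncol(scores)) {
    stop("`subgenome` must have one entry per marker.", call. = FALSE)
  }
  structure(
    list(scores = scores, chrom = chrom, subgenome = subgenome, coding = coding),
    class = "marker_set"
  )
}

#' @export
print.marker_set <- function(x, ...) {
  cat("<marker_set> ", nrow(x$scores), " lines x ", ncol(x$scores), " markers, coding {",
      paste(strsplit(x$coding, "")[[1]], collapse = ","), "}\n", sep = "")
  nmiss <- sum(is.na(x$scores))
  if (nmiss) cat("  missing scores: ", nmiss, "\n", sep = "")
  if (!is.null(x$subgenome)) {
    tb <- table(x$subgenome)
    cat("  subgenomes: ",
        paste(sprintf("%s (%d)", names(tb), as.integer(tb)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @rdname marker_set
#' @param x A `marker_set`.
#' @export
line_ids <- function(x) rownames(x$scores)

#' @rdname marker_set
#' @export
marker_ids <- function(x) colnames(x$scores)

#' @rdname marker_set
#' @export
n_lines <- function(x) nrow(x$scores)

#' @rdname marker_set
#' @export
n_markers <- function(x) ncol(x$scores)

# Subset markers by logical/integer index, keeping labels aligned.
subset_markers <- function(x, j) {
  marker_set(x$scores[, j, drop = FALSE],
             chrom = if (!is.null(x$chrom)) x$chrom[j],
             subgenome = if (!is.null(x$subgenome)) x$subgenome[j],
             coding = x$coding)
}

# Minor-allele frequency per marker from non-missing calls. Heterozygotes count
# one copy of each allele under {0,1,2}; under {0,1} MAF = min(mean, 1 - mean).
marker_maf <- function(x) {
  f <- colMeans(x$scores, na.rm = TRUE)
  if (x$coding == "012") f <- f / 2
  pmin(f, 1 - f)
}
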