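#' Read a line-by-marker score table or a VCF file
#'
#' The tab-delimited dialect has lines as rows and markers as columns: a header
#' row of marker IDs and a first column of line IDs. Empty cells and `NA` are
#' treated as missing and preserved. VCF genotypes are collapsed per sample to
#' reference-allele counts and then recoded to minor-allele counts, so the
#' resulting scores are minor-allele dosages in \{0, 1, 2\}; positions are kept
#' for bookkeeping only and never enter any computation.
#'
#' @param path Path to the marker table (or VCF when `format = "vcf"`).
#' @param format `"table"` (default) or `"vcf"`.
#' @param map Optional marker map (see [read_marker_map()]); when supplied,
#'   subgenomes are assigned immediately via [assign_subgenomes()] and a marker
#'   present in the matrix but absent from the map is an error.
#' @return A [marker_set()] with missing entries preserved; coding is
#'   auto-detected (`"01"` when no score of 2 is observed).
#' @export
load_marker_table <- function(path, format = c("table", "vcf"), map = NULL) {
  format <- match.arg(format)
  ms <- if (format == "table") read_marker_matrix(path) else read_marker_vcf(path)
  if (!is.null(map)) ms <- assign_subgenomes(ms, map = map)
  ms
}

read_marker_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (ncol(tab) < 2) stop("Marker table needs a line-ID column plus markers.", call. = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  marker_set(m)
}

read_marker_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("Reading VCF requires the vcfR package.", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  chrom <- vcfR::getCHROM(v)
  ids <- rownames(gt)
  if (is.null(ids)) ids <- paste0("mk", seq_len(nrow(gt)))
  # collapse GT strings to ALT-allele counts, then to reference counts
  alt <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    al <- al[al != "."]
    if (!length(al)) return(NA_real_)
    sum(al != "0") * 2 / length(al)  # scale haploid calls up to diploid dosage
  })
  ref <- 2 - alt
  # recode to minor-allele counts: flip markers whose scored allele is major
  freq <- rowMeans(ref, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  ref[flip, ] <- 2 - ref[flip, , drop = FALSE]
  m <- t(ref)
  colnames(m) <- ids
  marker_set(m, chrom = chrom, coding = "012")
}

#' Read a marker map (marker, chromosome, position)
#'
#' @param path Tab-delimited file whose first three columns are marker ID,
#'   chromosome and (optional) position; a header row is expected.
#' @return A tibble with columns `marker_id`, `chrom` and, when present, `pos`.
#' @export
read_marker_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  out <- tibble::tibble(marker_id = as.character(tab[[1]]),
                        chrom = as.character(tab[[2]]))
  if (ncol(tab) >= 3) out$pos <- tab[[3]]
  out
}

#' Read a phenotype table
#'
#' Expects a tab-delimited table whose first column is the line ID and second
#' the trial (environment) ID; every remaining column is a trait. Missing trait
#' values are preserved as `NA`.
#'
#' @param path File path.
#' @return A tibble with columns `line_id`, `trial_id` and one column per trait.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("NA", ""))
  if (ncol(tab) < 3) stop("Phenotype table needs line, trial and >=1 trait column.",
                          call. = FALSE)
  out <- tibble::as_tibble(tab)
  names(out)[1:2] <- c("line_id", "trial_id")
  out$line_id <- as.character(out$line_id)
  out$trial_id <- as.character(out$trial_id)
  out
}

#' Write marker data and phenotypes in the package's table dialects
#'
#' `write_marker_table()` emits the lines-as-rows score matrix,
#' `write_marker_map()` the marker/chromosome map, and `write_phenotypes()` the
#' phenotype records; all round-trip losslessly through the matching readers.
#'
#' @param x A `marker_set` (or, for `write_phenotypes()`, a phenotype tibble).
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_marker_table <- function(x, path) {
  df <- data.frame(line_id = line_ids(x), x$scores, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname write_marker_table
#' @export
write_marker_map <- function(x, path) {
  if (is.null(x$chrom)) stop("Marker set has no chromosome labels.", call. = FALSE)
  df <- data.frame(marker_id = marker_ids(x), chrom = x$chrom)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname write_marker_table
#' @export
write_phenotypes <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
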