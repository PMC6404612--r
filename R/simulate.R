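#' Configure a synthetic allohexaploid population
#'
#' The generator emulates the structure of an inbred allohexaploid breeding
#' population: three subgenomes with unequal marker counts and diversity (the
#' D genome carrying both fewer markers and narrower allele-frequency spread,
#' as in bread wheat), subpopulation structure from non-random mating,
#' per-subgenome additive effects, sampled inter-genomic pairwise (and
#' optionally three-way) epistatic effects, and an unbalanced multi-trial
#' phenotype layout with replicated check lines.
#'
#' Subpopulation allele frequencies drift around ancestral frequencies with a
#' Balding-Nichols-style variance `divergence * p * (1 - p)`; lines are drawn
#' as inbred \{0,1\} genotypes within their subpopulation.
#'
#' @param n_lines Number of inbred lines (default 500).
#' @param m Named marker counts per subgenome (defaults A = 600, B = 600,
#'   D = 300).
#' @param diversity Per-subgenome width of the ancestral minor-allele
#'   frequency distribution, on (0, 1\]; frequencies are drawn uniformly on
#'   `(maf_floor, 0.1 + 0.4 * diversity)`. Default gives the D genome half the
#'   spread of A and B.
#' @param n_subpop Number of subpopulations (default 3).
#' @param divergence Drift parameter of subpopulation frequencies (an
#'   Fst-like quantity; default 0.1, enough that the first PCs separate
#'   subpopulations).
#' @param maf_floor Minimum realized minor-allele frequency; markers below it
#'   are redrawn. Must be < 0.5.
#' @param sigma2 Named genetic variance components on the standardized-trait
#'   scale: `A`, `B`, `D`, `AB`, `AD`, `BD`, `ABD`. Defaults
#'   `c(A = 0.3, B = 0.4, D = 0.1, AB = 0.2, AD = 0, BD = 0, ABD = 0)`.
#' @param sigma2_e Residual variance (default 1).
#' @param n_pairs Number of causal cross-subgenome marker pairs sampled per
#'   pairwise interaction term (default 200); `n_triples` likewise for the
#'   three-way term.
#' @param n_trials Number of trials (environments; default 4) and `trial_sd`
#'   the SD of their fixed effects.
#' @param records_per_line Trials in which each non-check line is observed
#'   (default 2).
#' @param n_checks Number of check lines replicated in every trial (default 5).
#' @param missing_rate Fraction of phenotype records set missing (default 0).
#' @param seed Integer seed; mandatory.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_lines = 500,
                       m = c(A = 600, B = 600, D = 300),
                       diversity = c(A = 1, B = 1, D = 0.5),
                       n_subpop = 3, divergence = 0.1, maf_floor = 0.05,
                       sigma2 = c(A = 0.3, B = 0.4, D = 0.1,
                                  AB = 0.2, AD = 0, BD = 0, ABD = 0),
                       sigma2_e = 1, n_pairs = 200, n_triples = 100,
                       n_trials = 4, trial_sd = 0.5, records_per_line = 2,
                       n_checks = 5, missing_rate = 0, seed) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  s2 <- c(A = 0, B = 0, D = 0, AB = 0, AD = 0, BD = 0, ABD = 0)
  s2[names(sigma2)] <- sigma2
  if (any(s2 < 0) || sigma2_e < 0) stop("Variances must be >= 0.", call. = FALSE)
  if (any(m < 1)) stop("Each subgenome needs at least one marker.", call. = FALSE)
  if (maf_floor >= 0.5) stop("`maf_floor` must be < 0.5.", call. = FALSE)
  if (records_per_line > n_trials) stop("`records_per_line` cannot exceed `n_trials`.",
                                        call. = FALSE)
  structure(
    list(n_lines = n_lines, m = m, diversity = diversity, n_subpop = n_subpop,
         divergence = divergence, maf_floor = maf_floor, sigma2 = s2,
         sigma2_e = sigma2_e, n_pairs = n_pairs, n_triples = n_triples,
         n_trials = n_trials, trial_sd = trial_sd,
         records_per_line = records_per_line, n_checks = n_checks,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate inbred allohexaploid genotypes
#'
#' @param config A [sim_config()].
#' @return List with `markers` (a complete \{0,1\}-coded [marker_set()] with
#'   chromosome labels `1A`...`7D` and subgenomes assigned) and `subpop`
#'   (tibble `line_id`, `subpop`). Bit-identical across runs for a fixed seed.
#' @export
simulate_genotypes <- function(config) {
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_lines
  subpop <- rep_len(seq_len(cf$n_subpop), n)
  line_id <- sprintf("L%04d", seq_len(n))
  blocks <- list()
  chrom <- character(0)
  subg <- character(0)
  for (g in names(cf$m)) {
    mg <- cf$m[[g]]
    hi <- 0.1 + 0.4 * cf$diversity[[g]]
    draw_marker <- function() {
      p_anc <- stats::runif(1, cf$maf_floor, hi)
      if (stats::runif(1) < 0.5) p_anc <- 1 - p_anc
      ps <- if (cf$divergence > 0) {
        a <- p_anc * (1 - cf$divergence) / cf$divergence
        b <- (1 - p_anc) * (1 - cf$divergence) / cf$divergence
        stats::rbeta(cf$n_subpop, a, b)
      } else {
        rep(p_anc, cf$n_subpop)
      }
      stats::rbinom(n, 1, ps[subpop])
    }
    S <- matrix(0L, n, mg)
    for (j in seq_len(mg)) {
      v <- draw_marker()
      tries <- 0
      while (min(mean(v), 1 - mean(v)) < cf$maf_floor) {
        tries <- tries + 1
        if (tries > 200) {
          stop("Could not satisfy the MAF floor; lower `maf_floor`.",
               call. = FALSE)
        }
        v <- draw_marker()
      }
      S[, j] <- v
    }
    blocks[[g]] <- S
    chrom <- c(chrom, paste0(rep_len(1:7, mg), g))
    subg <- c(subg, rep(g, mg))
  }
  M <- do.call(cbind, blocks)
  storage.mode(M) <- "double"
  rownames(M) <- line_id
  colnames(M) <- sprintf("mk_%s_%04d", subg, stats::ave(seq_along(subg), subg,
                                                        FUN = seq_along))
  list(markers = marker_set(M, chrom = chrom, subgenome = subg, coding = "01"),
       subpop = tibble::tibble(line_id = line_id, subpop = subpop))
}

#' Simulate phenotypes with known subgenome architecture
#'
#' Builds the total genetic value of each line as the sum of per-subgenome
#' additive effects (centered marker scores times normal effect sizes) and
#' sampled cross-subgenome epistatic effects (element-wise products of
#' centered marker pairs times normal effect sizes), each term rescaled so its
#' realized variance equals the configured component exactly. Records follow
#' the configured unbalanced trial layout (check lines in every trial, other
#' lines in a random subset) with fixed trial effects and i.i.d. residual
#' noise. The RNG stream is derived from `config$seed + 1` so genotypes and
#' phenotypes are independently reproducible.
#'
#' @param marker_set A complete [marker_set()] with subgenomes assigned.
#' @param config The [sim_config()] used for [simulate_genotypes()].
#' @return List with `pheno` (tibble `line_id`, `trial_id`, `y`) and `truth`
#'   (a `sim_truth`: per-term effect tibble, realized variance components,
#'   causal pair lists, seed).
#' @export
simulate_phenotypes <- function(marker_set, config) {
  cf <- config
  x <- marker_set
  set.seed(cf$seed + 1L)
  n <- n_lines(x)
  W <- sweep(x$scores, 2, colMeans(x$scores), "-")
  subg <- x$subgenome
  cols <- split(seq_len(ncol(W)), subg)
  rescale <- function(u, s2) {
    u <- as.numeric(u)
    if (s2 == 0) return(rep(0, n))
    v <- stats::var(u)
    if (v == 0) stop("Cannot realize positive variance from a constant term.",
                     call. = FALSE)
    u * sqrt(s2 / v)
  }
  eff <- matrix(0, n, 7,
                dimnames = list(line_ids(x),
                                c("A", "B", "D", "AB", "AD", "BD", "ABD")))
  causal <- list()
  for (g in c("A", "B", "D")) {
    if (cf$sigma2[[g]] > 0) {
      if (is.null(cols[[g]])) stop("No markers for subgenome ", g, ".", call. = FALSE)
      a <- stats::rnorm(length(cols[[g]]))
      eff[, g] <- rescale(W[, cols[[g]], drop = FALSE] %*% a, cf$sigma2[[g]])
    }
  }
  for (pr in list(c("A", "B"), c("A", "D"), c("B", "D"))) {
    term <- paste0(pr, collapse = "")
    if (cf$sigma2[[term]] > 0) {
      if (is.null(cols[[pr[1]]]) || is.null(cols[[pr[2]]])) {
        stop("Interaction ", term, " requested but a subgenome has no markers.",
             call. = FALSE)
      }
      j1 <- sample(cols[[pr[1]]], cf$n_pairs, replace = TRUE)
      j2 <- sample(cols[[pr[2]]], cf$n_pairs, replace = TRUE)
      E <- W[, j1, drop = FALSE] * W[, j2, drop = FALSE]
      eff[, term] <- rescale(E %*% stats::rnorm(cf$n_pairs), cf$sigma2[[term]])
      causal[[term]] <- tibble::tibble(marker_1 = colnames(W)[j1],
                                       marker_2 = colnames(W)[j2])
    }
  }
  if (cf$sigma2[["ABD"]] > 0) {
    if (any(vapply(c("A", "B", "D"), function(g) is.null(cols[[g]]), logical(1)))) {
      stop("Three-way interaction requested but a subgenome has no markers.",
           call. = FALSE)
    }
    j1 <- sample(cols[["A"]], cf$n_triples, replace = TRUE)
    j2 <- sample(cols[["B"]], cf$n_triples, replace = TRUE)
    j3 <- sample(cols[["D"]], cf$n_triples, replace = TRUE)
    E <- W[, j1, drop = FALSE] * W[, j2, drop = FALSE] * W[, j3, drop = FALSE]
    eff[, "ABD"] <- rescale(E %*% stats::rnorm(cf$n_triples), cf$sigma2[["ABD"]])
    causal[["ABD"]] <- tibble::tibble(marker_1 = colnames(W)[j1],
                                      marker_2 = colnames(W)[j2],
                                      marker_3 = colnames(W)[j3])
  }
  total <- unname(rowSums(eff))

  # unbalanced trial layout: checks everywhere, others in a random subset
  trials <- sprintf("T%02d", seq_len(cf$n_trials))
  trial_eff <- stats::setNames(stats::rnorm(cf$n_trials, 0, cf$trial_sd), trials)
  ids <- line_ids(x)
  n_checks <- min(cf$n_checks, n)
  rec <- list()
  for (i in seq_len(n)) {
    tr <- if (i <= n_checks) trials else
      sample(trials, cf$records_per_line)
    rec[[i]] <- tibble::tibble(line_id = ids[i], trial_id = tr)
  }
  pheno <- dplyr::bind_rows(rec)
  pheno$y <- unname(trial_eff[pheno$trial_id]) +
    unname(total[match(pheno$line_id, ids)]) +
    stats::rnorm(nrow(pheno), 0, sqrt(cf$sigma2_e))
  if (cf$missing_rate > 0) {
    drop <- stats::runif(nrow(pheno)) < cf$missing_rate
    pheno$y[drop] <- NA_real_
  }
  truth <- structure(
    list(effects = dplyr::bind_cols(tibble::tibble(line_id = ids),
                                    tibble::as_tibble(eff),
                                    tibble::tibble(total = total)),
         realized_sigma2 = apply(eff, 2, stats::var),
         causal = causal, seed = cf$seed),
    class = "sim_truth"
  )
  list(pheno = pheno, truth = truth)
}

#' Simulate a full population in one call
#'
#' @param config A [sim_config()].
#' @return List with `markers`, `subpop`, `pheno`, `truth`.
#' @export
simulate_population <- function(config) {
  g <- simulate_genotypes(config)
  p <- simulate_phenotypes(g$markers, config)
  c(g, p)
}
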