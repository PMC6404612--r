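# Build a minimal spec directly from simulated pieces.
make_identity_spec <- function(y_by_line, reps = 1, seed = 1) {
  q <- length(y_by_line)
  lines <- sprintf("L%03d", seq_len(q))
  Im <- diag(q)
  dimnames(Im) <- list(lines, lines)
  K <- sgblup:::new_genetic_kernel(Im, label = "G", c = 1, nugget = 0)
  ph <- tibble::tibble(line_id = rep(lines, each = reps),
                       trial_id = "T1",
                       y = as.numeric(y_by_line))
  model_spec(ph, "y", kernels = list(G = K), ridge = 0)
}

test_that("REML matches the closed-form balanced one-way solution", {
  set.seed(42)
  q <- 100
  r <- 3
  g <- rnorm(q, 0, 1)
  ymat <- matrix(g, q, r) + matrix(rnorm(q * r), q, r)
  oracle <- oracle_balanced_oneway(ymat)

  lines <- sprintf("L%03d", seq_len(q))
  Im <- diag(q)
  dimnames(Im) <- list(lines, lines)
  K <- sgblup:::new_genetic_kernel(Im, label = "G", c = 1, nugget = 0)
  ph <- tibble::tibble(line_id = rep(lines, r), trial_id = "T1",
                       y = as.numeric(ymat))
  fit <- fit_reml(model_spec(ph, "y", kernels = list(G = K), ridge = 0),
                  tol = 1e-10)
  expect_equal(unname(fit$sigma2[["G"]]), unname(oracle[["g"]]), tolerance = 1e-6)
  expect_equal(unname(fit$sigma2[["residual"]]), unname(oracle[["e"]]),
               tolerance = 1e-6)
})

test_that("the solver's likelihood agrees with a direct evaluation", {
  cf <- sim_config(n_lines = 60, m = c(A = 40, B = 40, D = 20), seed = 11,
                   n_pairs = 30, records_per_line = 2, n_checks = 3)
  pop <- simulate_population(cf)
  ph <- standardize_phenotypes(pop$pheno, "y")
  ks <- build_kernels(pop$markers, "ABD")
  spec <- model_spec(ph, "y", kernels = ks)
  fit <- fit_reml(spec)
  theta <- fit$sigma2
  theta[theta == 0] <- 1e-8 * var(spec$y)
  Vlist <- lapply(spec$kernels, oracle_expand, idx = spec$z_idx)
  ll_direct <- oracle_restricted_loglik(spec$y, spec$X, Vlist, theta)
  expect_equal(fit$loglik, ll_direct, tolerance = 1e-8)
  # and at an arbitrary non-optimal point the evaluator and a one-iteration
  # restart from it agree on the starting likelihood
  th0 <- rep(var(spec$y) / 4, 4)
  fit0 <- fit_reml(spec, start = th0, max_iter = 200)
  expect_gte(fit0$loglik, oracle_restricted_loglik(spec$y, spec$X, Vlist, th0) - 1e-8)
  expect_equal(fit0$loglik, fit$loglik, tolerance = 1e-4)
})

test_that("the likelihood trajectory is nondecreasing and convergence is flagged", {
  cf <- sim_config(n_lines = 80, m = c(A = 30, B = 30, D = 15), seed = 13,
                   n_pairs = 20)
  pop <- simulate_population(cf)
  ph <- standardize_phenotypes(pop$pheno, "y")
  fit <- fit_reml(model_spec(ph, "y", build_kernels(pop$markers, "ABD")))
  expect_true(fit$converged)
  expect_true(all(diff(fit$trajectory) >= -1e-9))
  expect_error(fit_reml(model_spec(ph, "y", build_kernels(pop$markers, "ABD")),
                        max_iter = 1, tol = 1e-12),
               "did not converge")
})

test_that("pure-noise phenotypes put the genetic variance on the boundary", {
  q <- 300
  lines <- sprintf("L%03d", seq_len(q))
  ms <- toy_marker_set(q, 80, seed = 5)
  K <- vanraden_kernel(ms)
  small <- 0
  at_zero <- 0
  n_rep <- 40
  set.seed(500)
  for (i in seq_len(n_rep)) {
    ph <- tibble::tibble(line_id = rownames(K), trial_id = "T1", y = rnorm(q))
    fit <- fit_reml(model_spec(ph, "y", kernels = list(G = K)))
    at_zero <- at_zero + fit$boundary[["G"]]
    small <- small + (fit$boundary[["G"]] || fit$sigma2[["G"]] < 0.1)
  }
  # the REML null distribution puts about half its mass exactly at zero and
  # the remainder near it: estimates are zero-or-tiny in nearly all replicates
  expect_gte(small / n_rep, 0.95)
  expect_gte(at_zero / n_rep, 0.25)
})

test_that("boundary terms yield exactly zero BLUPs and zero-variance reports", {
  q <- 100
  ms <- toy_marker_set(q, 50, seed = 6, subgenomes = c("A", "B", "D"))
  ks <- build_kernels(ms, "ABD")
  set.seed(61)
  ph <- tibble::tibble(line_id = line_ids(ms), trial_id = "T1", y = rnorm(q))
  fit <- fit_reml(model_spec(ph, "y", kernels = ks))
  if (any(fit$boundary[c("A", "B", "D")])) {
    bl <- names(which(fit$boundary[c("A", "B", "D")]))[1]
    expect_identical(unname(fit$sigma2[[bl]]), 0)
    expect_true(all(fit$blups[, bl] == 0))
  }
  # y reconstructs from fixed fit + BLUP contributions + residuals exactly
  spec <- fit$spec
  recon <- fit$fitted + fit$residuals
  expect_equal(recon, spec$y, tolerance = 1e-12)
})

test_that("single-kernel identity BLUPs equal heritability-shrunk centered records", {
  set.seed(77)
  q <- 150
  y <- rnorm(q, 0, sqrt(2))
  spec <- make_identity_spec(y)
  fit <- fit_reml(spec, tol = 1e-10)
  h2 <- fit$sigma2[["G"]] / (fit$sigma2[["G"]] + fit$sigma2[["residual"]])
  # GLS mean with K = I and one record per line is the plain mean
  expect_equal(as.numeric(fit$blups[, "G"]), h2 * (y - mean(y)),
               tolerance = 1e-6)
})

test_that("model-7-style variance components are recovered across replicates", {
  cf <- sim_config(n_lines = 250, m = c(A = 120, B = 120, D = 60),
                   divergence = 0, n_subpop = 1, seed = 900,
                   sigma2 = c(A = 0.3, B = 0.4, D = 0.1, AB = 0.2),
                   records_per_line = 2, n_checks = 4, n_pairs = 100)
  pop <- simulate_genotypes(cf)
  ks <- build_kernels(pop$markers, "ABDxABD")
  ks <- ks[c("A", "B", "D", "AB")]  # terms actually simulated
  n_rep <- 12
  est <- matrix(NA_real_, n_rep, 5,
                dimnames = list(NULL, c("A", "B", "D", "AB", "residual")))
  for (i in seq_len(n_rep)) {
    cf_i <- sim_config(n_lines = 250, m = c(A = 120, B = 120, D = 60),
                       divergence = 0, n_subpop = 1, seed = 900 + i,
                       sigma2 = c(A = 0.3, B = 0.4, D = 0.1, AB = 0.2),
                       records_per_line = 2, n_checks = 4, n_pairs = 100)
    sim <- simulate_phenotypes(pop$markers, cf_i)
    fit <- fit_reml(model_spec(sim$pheno, "y", kernels = ks))
    est[i, ] <- fit$sigma2[colnames(est)]
  }
  truth <- c(A = 0.3, B = 0.4, D = 0.1, AB = 0.2, residual = 1)
  for (term in colnames(est)) {
    mc_se <- sd(est[, term]) / sqrt(n_rep)
    expect_lt(abs(mean(est[, term]) - truth[[term]]), 2.5 * mc_se + 0.02)
  }
})

test_that("AIC is deterministic and counts every variance parameter", {
  cf <- sim_config(n_lines = 70, m = c(A = 30, B = 30, D = 15), seed = 15,
                   n_pairs = 20)
  pop <- simulate_population(cf)
  ph <- standardize_phenotypes(pop$pheno, "y")
  ks <- build_kernels(pop$markers, "ABD")
  f1 <- fit_reml(model_spec(ph, "y", ks))
  f2 <- fit_reml(model_spec(ph, "y", ks))
  expect_equal(model_aic(f1), model_aic(f2), tolerance = 1e-8)
  expect_equal(model_aic(f1), -2 * f1$loglik + 2 * 4)
  fg <- fit_reml(model_spec(ph, "y", build_kernels(pop$markers, "G")))
  cmp <- compare_models(G = fg, ABD = f1)
  expect_s3_class(cmp, "tbl_df")
  expect_equal(nrow(cmp), 2L)
})

test_that("AIC prefers parsimony without epistasis and power with it", {
  # a related (structured) population with replicated records: with unrelated
  # lines and single records the epistatic kernel is near-identity and the
  # term is confounded with the residual, so no criterion would have power
  q <- 150
  cf <- sim_config(n_lines = q, m = c(A = 40, B = 40, D = 20),
                   divergence = 0.2, n_subpop = 3, seed = 77)
  ms <- simulate_genotypes(cf)$markers
  kG <- build_kernels(ms, "G")
  kGG <- build_kernels(ms, "GxG")
  n_rep <- 20
  wins_null <- 0
  wins_alt <- 0
  set.seed(160)
  Kv <- unclass(kG$G)
  Hv <- unclass(kGG$I)
  cK <- chol(Kv + 1e-8 * diag(q))
  cH <- chol(Hv + 1e-8 * diag(q))
  ph0 <- tibble::tibble(line_id = rep(rownames(Kv), 2),
                        trial_id = rep(c("T1", "T2"), each = q))
  for (i in seq_len(n_rep)) {
    g <- as.numeric(t(cK) %*% rnorm(q))
    g <- g * sqrt(0.5) / sd(g)
    e <- rnorm(2 * q)
    ph <- ph0
    ph$y <- rep(g, 2) + e
    a_g <- model_aic(fit_reml(model_spec(ph, "y", kG)))
    a_gg <- model_aic(fit_reml(model_spec(ph, "y", kGG)))
    wins_null <- wins_null + (a_g <= a_gg)
    gi <- as.numeric(t(cH) %*% rnorm(q))
    gi <- gi * sqrt(0.5) / sd(gi)  # epistatic variance = 0.5 * residual
    ph$y <- rep(g + gi, 2) + e
    b_g <- model_aic(fit_reml(model_spec(ph, "y", kG)))
    b_gg <- model_aic(fit_reml(model_spec(ph, "y", kGG)))
    wins_alt <- wins_alt + (b_gg < b_g)
  }
  expect_gt(wins_null / n_rep, 0.5)
  expect_gt(wins_alt / n_rep, 0.5)
})

test_that("likelihood-ratio tests honour nesting, boundaries and invariances", {
  cf <- sim_config(n_lines = 90, m = c(A = 40, B = 40, D = 20), seed = 17,
                   n_pairs = 30)
  pop <- simulate_population(cf)
  ph <- standardize_phenotypes(pop$pheno, "y")
  ks <- build_kernels(pop$markers, "ABD")
  full <- fit_reml(model_spec(ph, "y", ks))
  # identical fits: statistic 0, p = 1
  lrt0 <- likelihood_ratio_test(full, full)
  expect_equal(lrt0$statistic, 0)
  expect_equal(lrt0$p.value, 1)
  # reordering random terms leaves the statistic invariant
  full_perm <- fit_reml(model_spec(ph, "y", ks[c("D", "A", "B")]))
  red <- fit_reml(model_spec(ph, "y", ks["A"]))
  l1 <- likelihood_ratio_test(full, red)
  l2 <- likelihood_ratio_test(full_perm, red)
  expect_equal(l1$statistic, l2$statistic, tolerance = 1e-4)
  # non-nested comparisons are refused
  expect_error(likelihood_ratio_test(red, fit_reml(model_spec(ph, "y", ks["B"]))),
               "not nested")
})

test_that("sampling correlations have correlation-matrix structure", {
  cf <- sim_config(n_lines = 100, m = c(A = 40, B = 40, D = 20), seed = 19,
                   n_pairs = 30)
  pop <- simulate_population(cf)
  ph <- standardize_phenotypes(pop$pheno, "y")
  fit <- fit_reml(model_spec(ph, "y", build_kernels(pop$markers, "ABD")))
  R <- sampling_correlations(fit)
  expect_equal(diag(R), setNames(rep(1, 3), c("A", "B", "D")))
  expect_equal(R, t(R), tolerance = 1e-12)
  expect_true(all(abs(R) <= 1 + 1e-12))
  # single genetic term: 1x1 unit matrix
  fitG <- fit_reml(model_spec(ph, "y", build_kernels(pop$markers, "G")))
  expect_equal(unname(sampling_correlations(fitG)), matrix(1), tolerance = 1e-12)
  # including the residual extends the matrix
  expect_equal(dim(sampling_correlations(fit, include_residual = TRUE)), c(4L, 4L))
})

test_that("block-diagonal kernels over disjoint line sets decorrelate estimates", {
  q <- 120
  half <- q / 2
  lines <- sprintf("L%03d", seq_len(q))
  ms1 <- toy_marker_set(half, 60, seed = 23)
  ms2 <- toy_marker_set(half, 60, seed = 24)
  K1v <- matrix(0, q, q, dimnames = list(lines, lines))
  K2v <- K1v
  K1v[1:half, 1:half] <- unclass(vanraden_kernel(ms1))
  K2v[(half + 1):q, (half + 1):q] <- unclass(vanraden_kernel(ms2))
  diag(K1v)[(half + 1):q] <- 1e-6
  diag(K2v)[1:half] <- 1e-6
  K1 <- sgblup:::new_genetic_kernel(K1v, label = "K1", c = 1, nugget = 0.01)
  K2 <- sgblup:::new_genetic_kernel(K2v, label = "K2", c = 1, nugget = 0.01)
  set.seed(25)
  g1 <- as.numeric(t(chol(K1v + 1e-6 * diag(q))) %*% rnorm(q))
  g2 <- as.numeric(t(chol(K2v + 1e-6 * diag(q))) %*% rnorm(q))
  ph <- tibble::tibble(line_id = rep(lines, 2), trial_id = rep(c("T1", "T2"), each = q),
                       y = rep(g1 + g2, 2) + rnorm(2 * q))
  fit <- fit_reml(model_spec(ph, "y", kernels = list(K1 = K1, K2 = K2)))
  R <- sampling_correlations(fit)
  expect_lt(abs(R["K1", "K2"]), 0.15)
})

test_that("aliased fixed designs are rejected with the offending column named", {
  q <- 30
  ms <- toy_marker_set(q, 20, seed = 29)
  K <- vanraden_kernel(ms)
  ph <- tibble::tibble(line_id = line_ids(ms), trial_id = "T1", y = rnorm(q))
  qc <- tibble::tibble(line_id = line_ids(ms), Q1 = 1)  # constant covariate
  expect_error(model_spec(ph, "y", list(G = K), structure = qc), "aliased|Q1")
})
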