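test_that("rate estimators implement their three definitions", {
  # protein of length 100 with 5 motifs: per-protein rate 0.05
  s1 <- paste0(paste(rep(c("SQ", strrep("A", 18)), 5), collapse = ""))
  p1 <- synth_proteome_from_strings(c(A = s1))
  expect_equal(p1$length, 100L)
  expect_equal(estimate_rates(p1)$lambda, 0.05)

  # (m=2, L=100) and (m=4, L=200)
  sA <- paste0("SQTQ", strrep("A", 96))
  sB <- paste0("SQTQSQTQ", strrep("A", 192))
  p2 <- synth_proteome_from_strings(c(A = sA, B = sB))
  expect_equal(estimate_rates(p2, mode = "per_protein")$lambda,
               c(2 / 100, 4 / 200))
  expect_equal(estimate_rates(p2, mode = "global_mean_per_protein")$lambda,
               c(3 / 100, 3 / 200))
  expect_equal(estimate_rates(p2, mode = "global_per_residue")$lambda,
               c(0.02, 0.02))
})

test_that("degenerate inputs give degenerate probabilities", {
  expect_equal(scd_probability(100, 0, method = "exact_dp")$p, 0)
  expect_equal(scd_probability(5, 0.3, k = 3, method = "exact_dp")$p, 0)
  expect_error(scd_probability(100, 1.5), "lambda")
  # window covering the whole protein: binomial upper tail at k
  for (lam in c(0.05, 0.2)) {
    got <- scd_probability(12, lam, k = 3, W = 13,
                           method = "exact_small")$p
    expect_equal(got, pbinom(2, 12, lam, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("exact dynamic program equals exhaustive enumeration", {
  for (prm in list(c(20, 0.10, 3, 10), c(20, 0.05, 2, 5),
                   c(15, 0.20, 4, 12), c(18, 0.08, 3, 18),
                   c(12, 0.30, 2, 12))) {
    e <- scd_probability(prm[1], prm[2], prm[3], prm[4],
                         method = "exact_small")$p
    d <- scd_probability(prm[1], prm[2], prm[3], prm[4],
                         method = "exact_dp")$p
    expect_equal(d, e, tolerance = 1e-12)
  }
})

test_that("Monte Carlo agrees with enumeration within 3 true SEs", {
  for (prm in list(c(20, 0.1, 3, 10), c(16, 0.05, 2, 8))) {
    e <- scd_probability(prm[1], prm[2], prm[3], prm[4],
                         method = "exact_small")$p
    m <- scd_probability(prm[1], prm[2], prm[3], prm[4],
                         method = "monte_carlo", n_sims = 1e5, seed = 99)
    se <- sqrt(e * (1 - e) / 1e5)
    expect_lt(abs(m$p - e), 3 * se)
    expect_gt(m$se, 0)
  }
})

test_that("closed-form approximation tracks the exact value", {
  # the product-form approximation runs high by design; exact methods are
  # authoritative and the approximation must stay within 25% relative
  prof <- scd_prob_profile_bernoulli(2000, 0.006, 3, 50)
  for (L in c(200, 500, 2000)) {
    a <- scd_probability(L, 0.006, method = "approximation")$p
    expect_lt(abs(a - prof[L]) / prof[L], 0.25)
  }
})

test_that("event probability is monotone in lambda, L, W and k", {
  lams <- c(0.02, 0.05, 0.1)
  Ls <- c(12, 16, 20)
  Ws <- c(6, 10, 14)
  ks <- c(2, 3)
  p_of <- function(L, lam, k, W)
    scd_probability(L, lam, k, W, method = "exact_dp")$p
  for (L in Ls) for (k in ks) for (W in Ws) {
    expect_true(all(diff(vapply(lams, function(l)
      p_of(L, l, k, W), numeric(1))) >= 0))
  }
  for (lam in lams) for (k in ks) for (W in Ws) {
    expect_true(all(diff(vapply(Ls, function(L)
      p_of(L, lam, k, W), numeric(1))) >= 0))
  }
  for (lam in lams) for (k in ks) for (L in Ls) {
    expect_true(all(diff(vapply(Ws, function(W)
      p_of(L, lam, k, W), numeric(1))) >= 0))
  }
  for (lam in lams) for (W in Ws) for (L in Ls) {
    expect_true(all(diff(vapply(ks, function(k)
      p_of(L, lam, k, W), numeric(1))) <= 0))
  }
})

test_that("composition null equals the 3^L residue-class oracle", {
  for (prm in list(list(8, 0.3, 0.2, 2, 4), list(9, 0.2, 0.15, 3, 8),
                   list(9, 0.3, 0.3, 4, 10))) {
    o <- oracle_composition_prob(prm[[1]], prm[[2]], prm[[3]],
                                 prm[[4]], prm[[5]])
    d <- scd_probability_composition(prm[[1]], prm[[2]], prm[[3]],
                                     prm[[4]], prm[[5]])[prm[[1]]]
    expect_lt(abs(d - o), 1e-12)
  }
})

test_that("expected census is the sum of the probabilities", {
  expect_equal(expected_census(numeric(0))$expected_census, 0)
  expect_equal(expected_census(rep(0.25, 10))$expected_census, 2.5)
})

test_that("Poisson-binomial pmf and tails are exact", {
  set.seed(77)
  p <- runif(12, 0.01, 0.9)
  f <- poisson_binomial_pmf(p)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_equal(poisson_binomial_tail(p, 0), 1)
  for (x in c(1, 3, 6, 9, 12)) {
    expect_equal(poisson_binomial_tail(p, x), oracle_poisbin_tail(p, x),
                 tolerance = 1e-12)
  }
  # all p = 0.5, n = 4, observed 0
  expect_equal(poisson_binomial_tail(rep(0.5, 4), 0), 1)
  # normal refinement is close for moderate n
  expect_equal(poisson_binomial_tail(p, 6, "normal_refined"),
               poisson_binomial_tail(p, 6, "exact_dp"), tolerance = 0.05)
})

test_that("census significance near the expectation is unremarkable", {
  gen <- generate_proteome(synth_config(n_proteins = 250, seed = 21))
  f <- gen$ground_truth
  prof <- scd_probability_composition(max(gen$proteome$length),
                                      f$p_st, f$p_q, 3, 50)
  p <- prof[gen$proteome$length]
  sig <- census_significance(p, round(sum(p)), "both")
  expect_gte(sig$p_value[["exact_dp"]], 0.3)
  expect_lte(sig$p_value[["exact_dp"]], 0.7)
  expect_error(census_significance(p, length(p) + 1L), "exceeds")
})

test_that("null_model wraps rates, probabilities and significance", {
  gen <- generate_proteome(synth_config(n_proteins = 80, seed = 22))
  nm <- null_model(gen$proteome, method = "exact_dp",
                   lambda_mode = "global_per_residue")
  expect_equal(nrow(nm$table), 80L)
  expect_true(all(nm$table$p >= 0 & nm$table$p <= 1))
  expect_equal(nm$expected_census, sum(nm$table$p))
  expect_equal(nm$observed_census,
               scan_census(gen$proteome)$census_size)
})
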