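test_that("a single site yields one-hot columns at each offset", {
  p <- synth_proteome_from_strings(c(P1 = "AAAAASQAAAAA"))
  s <- data.frame(protein_id = "P1", position = 6L, residue = "S")
  prof <- build_profile(s, p)
  expect_equal(prof$n_sites, 1L)
  expect_equal(prof$freqs["-1", "A"], 1)
  expect_equal(prof$freqs["0", "S"], 1)
  expect_equal(prof$freqs["1", "Q"], 1)
  expect_equal(unname(prof$per_offset_totals), rep(1L, 11))
})

test_that("offsets beyond the termini drop out of the denominators", {
  p <- synth_proteome_from_strings(c(P1 = "ASQAAAAA"))  # length 8
  s <- data.frame(protein_id = "P1", position = 2L, residue = "S")
  prof <- build_profile(s, p)
  tot <- prof$per_offset_totals
  expect_equal(unname(tot[as.character(-5:-2)]), rep(0L, 4))
  expect_equal(unname(tot[as.character(-1:5)]), rep(1L, 7))
  # zero-total offsets carry zero frequency rows, not NaN
  expect_true(all(is.finite(prof$freqs)))
})

test_that("sites not matching the pS/T-Q definition are excluded", {
  p <- synth_proteome_from_strings(c(P1 = "ASQATAAAAA"))
  s <- data.frame(protein_id = "P1", position = c(2L, 5L),
                  residue = c("S", "T"))
  prof <- build_profile(s, p)          # position 5 is T but followed by A
  expect_equal(prof$n_sites, 1L)
  expect_equal(prof$n_excluded_not_q, 1L)
  prof2 <- build_profile(s, p, require_q = FALSE)
  expect_equal(prof2$n_sites, 2L)
})

test_that("structural zeros hold on generated data", {
  gen <- generate_proteome(synth_config(n_proteins = 150, seed = 61))
  ph <- generate_phosphosites(gen$proteome, 300, seed = 61)
  prof <- build_profile(ph$sites, ph$proteome)
  expect_equal(sum(prof$freqs["0", c("S", "T")]), 1)
  expect_equal(prof$freqs["1", "Q"], 1)
  expect_true(all(prof$freqs["0", setdiff(colnames(prof$freqs),
                                          c("S", "T"))] == 0))
  # populated offsets are column-stochastic
  pop <- prof$per_offset_totals > 0
  expect_equal(unname(rowSums(prof$freqs)[pop]),
               rep(1, sum(pop)), tolerance = 1e-12)
})

test_that("profiles add over disjoint site sets", {
  gen <- generate_proteome(synth_config(n_proteins = 100, seed = 62))
  ph <- generate_phosphosites(gen$proteome, 200, seed = 62)
  a <- ph$sites[1:100, ]
  b <- ph$sites[101:200, ]
  pa <- build_profile(a, ph$proteome)
  pb <- build_profile(b, ph$proteome)
  pab <- build_profile(ph$sites, ph$proteome)
  expect_equal(pab$counts, pa$counts + pb$counts)
})

test_that("within/outside SCD restriction partitions the sites", {
  cfg <- synth_config(n_proteins = 200, seed = 63,
                      planted_scds = list(list(k = 3, W = 50, count = 40)))
  gen <- generate_proteome(cfg)
  cen <- scan_census(gen$proteome)
  ph <- generate_phosphosites(gen$proteome, 300, seed = 63)
  all_p <- build_profile(ph$sites, gen$proteome)
  inp <- build_profile(ph$sites, gen$proteome, restrict_to = "within_scd",
                       regions = cen$regions)
  outp <- build_profile(ph$sites, gen$proteome,
                        restrict_to = "outside_scd", regions = cen$regions)
  expect_equal(inp$counts + outp$counts, all_p$counts)
  expect_error(build_profile(ph$sites, gen$proteome,
                             restrict_to = "within_scd"), "regions")
})

test_that("sampling preference can force all sites into planted regions", {
  cfg <- synth_config(n_proteins = 200, seed = 64,
                      aa_frequencies = motif_free_frequencies(),
                      planted_scds = list(list(k = 3, W = 50, count = 50)))
  gen <- generate_proteome(cfg)
  ph <- generate_phosphosites(gen$proteome, 100, within_pref = 1,
                              ground_truth = gen$ground_truth, seed = 64)
  gt <- gen$ground_truth$planted
  for (i in seq_len(nrow(ph$sites))) {
    g <- gt[gt$protein_id == ph$sites$protein_id[i], ]
    expect_true(any(ph$sites$position[i] >= g$start &
                    ph$sites$position[i] <= g$end))
  }
})

test_that("comparison to background is zero for identical profiles", {
  gen <- generate_proteome(synth_config(n_proteins = 80, seed = 65))
  ph <- generate_phosphosites(gen$proteome, 150, seed = 65)
  prof <- build_profile(ph$sites, ph$proteome)
  cmp <- compare_to_background(prof, prof)
  expect_true(all(cmp$log2_ratio == 0, na.rm = TRUE))
  # zero-total offsets come back missing
  p <- synth_proteome_from_strings(c(P1 = "ASQAAAAA"))
  s <- data.frame(protein_id = "P1", position = 2L, residue = "S")
  edge <- build_profile(s, p)
  cmp2 <- compare_to_background(edge, edge)
  expect_true(all(is.na(cmp2$log2_ratio["-5", ])))
})

test_that("a planted flanking bias is recovered at the right frequency", {
  gen <- generate_proteome(synth_config(n_proteins = 300, seed = 66))
  ph <- generate_phosphosites(
    gen$proteome, 600,
    flank_bias = list(list(offset = -2L, residue = "S", prob = 0.4)),
    seed = 66)
  prof <- build_profile(ph$sites, ph$proteome)
  n <- prof$per_offset_totals[["-2"]]
  expect_lt(abs(prof$freqs["-2", "S"] - 0.4), 3 * sqrt(0.4 * 0.6 / n))
})
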