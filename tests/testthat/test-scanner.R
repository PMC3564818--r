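test_that("definition parameters are validated", {
  d <- scd_definition()
  expect_equal(d$min_motifs, 3L)
  expect_equal(d$max_span, 50L)
  expect_equal(d$motif_length, 2L)
  expect_error(scd_definition(min_motifs = 1), ">= 2")
  expect_error(scd_definition(min_motifs = 3, max_span = 5), "max_span")
})

test_that("motif occurrences are enumerated exhaustively", {
  p <- synth_proteome_from_strings(c(P1 = "SQ", P2 = "AAASQATQGG",
                                     P3 = "AAAA", P4 = "XQSXTQ"))
  hits <- find_motifs(p)
  expect_equal(hits$position[hits$protein_id == "P1"], 1L)
  expect_equal(hits$position[hits$protein_id == "P2"], c(4L, 7L))
  expect_equal(hits$dipeptide[hits$protein_id == "P2"], c("SQ", "TQ"))
  # ambiguity characters never match the class
  expect_equal(hits$position[hits$protein_id == "P4"], 5L)
  expect_false("P3" %in% hits$protein_id)
})

test_that("span boundary cases follow the inclusive span rule", {
  d <- scd_definition(3, 50)
  r <- find_scd_regions(c(10L, 30L, 58L), d)      # span 50: in
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 10L)
  expect_equal(r$end, 59L)
  expect_equal(r$end - r$start + 1L, 50L)
  expect_equal(nrow(find_scd_regions(c(10L, 30L, 59L), d)), 0L)  # span 51
})

test_that("chained qualifying tuples merge into one maximal region", {
  r <- find_scd_regions(c(5L, 20L, 40L, 60L), scd_definition(3, 50))
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 5L)
  expect_equal(r$end, 61L)
  expect_equal(r$n_motifs, 4L)
  expect_equal(r$motif_positions[[1]], c(5L, 20L, 40L, 60L))
})

test_that("fewer than k hits yield no region", {
  expect_equal(nrow(find_scd_regions(c(3L, 10L), scd_definition(3, 50))), 0L)
  expect_equal(nrow(find_scd_regions(integer(0), scd_definition())), 0L)
})

test_that("scanner matches the brute-force oracles on random sequences", {
  set.seed(401)
  d <- scd_definition(3, 50)
  for (i in 1:120) {
    len <- sample(10:800, 1)
    s <- random_protein(len)
    p <- synth_proteome_from_strings(c(X = s))
    hits <- find_motifs(p)
    expect_identical(hits$position, oracle_motif_positions(s))
    got <- find_scd_regions(hits, d)
    want <- oracle_regions(hits$position, 3L, 50L)
    expect_identical(got$start, as.integer(want$start))
    expect_identical(got$end, as.integer(want$end))
  }
})

test_that("region detection is idempotent on its own member hits", {
  set.seed(402)
  d <- scd_definition(3, 50)
  for (i in 1:40) {
    s <- random_protein(sample(200:1500, 1))
    p <- synth_proteome_from_strings(c(X = s))
    r1 <- find_scd_regions(find_motifs(p), d)
    if (nrow(r1) == 0L) next
    member_hits <- sort(unlist(r1$motif_positions))
    r2 <- find_scd_regions(member_hits, d, protein_id = "X")
    expect_equal(r2$start, r1$start)
    expect_equal(r2$end, r1$end)
    expect_equal(r2$n_motifs, r1$n_motifs)
  }
})

test_that("census counts proteins and the degenerate-span limit holds", {
  cfg <- synth_config(n_proteins = 10, min_len = 120, max_len = 400,
                      aa_frequencies = motif_free_frequencies(),
                      planted_scds = list(list(k = 3, W = 50, count = 4)),
                      seed = 9)
  gen <- generate_proteome(cfg)
  cen <- scan_census(gen$proteome)
  expect_equal(cen$census_size, 4L)
  expect_setequal(cen$census_ids, gen$ground_truth$planted$protein_id)

  # no span constraint beyond length: census = proteins with >= 3 motifs
  gen2 <- generate_proteome(synth_config(n_proteins = 60, seed = 10))
  Lmax <- max(gen2$proteome$length)
  cen2 <- scan_census(gen2$proteome, scd_definition(3, Lmax + 1L))
  hits <- find_motifs(gen2$proteome)
  with3 <- names(which(table(hits$protein_id) >= 3))
  expect_setequal(cen2$census_ids, with3)
})

test_that("sweep census sizes are monotone in W and k", {
  # single protein with hits at 1, 25, 52: span 53
  p <- synth_proteome_from_strings(
    c(A = paste0("SQ", strrep("A", 22), "SQ", strrep("A", 25), "SQ")))
  expect_equal(find_motifs(p)$position, c(1L, 25L, 52L))
  sw <- sweep_definitions(p, k_values = 3, span_values = c(50, 55))
  expect_equal(sw$census_size[sw$W == 50], 0L)
  expect_equal(sw$census_size[sw$W == 55], 1L)

  gen <- generate_proteome(synth_config(n_proteins = 150, seed = 11))
  sw2 <- sweep_definitions(gen$proteome, k_values = 3:5,
                           span_values = seq(50, 100, by = 10))
  for (k in 3:5) {
    cs <- sw2$census_size[sw2$k == k][order(sw2$W[sw2$k == k])]
    expect_true(all(diff(cs) >= 0L))
  }
  for (W in unique(sw2$W)) {
    cs <- sw2$census_size[sw2$W == W][order(sw2$k[sw2$W == W])]
    expect_true(all(diff(cs) <= 0L))
  }
})

test_that("minimal qualifying spans match brute force", {
  p <- synth_proteome_from_strings(c(
    A = paste0("SQ", strrep("A", 7), "SQ", strrep("A", 8), "SQ")))
  ms <- min_span_statistic(p, k = 3)
  expect_equal(ms$per_protein$min_span, 21L)   # hits 1, 10, 20

  p2 <- synth_proteome_from_strings(c(
    B = paste0("SQ", strrep("A", 7), "TQ", strrep("A", 8), "SQTQ")))
  # hits 1, 10, 20, 22: best tuple (10, 20, 22) -> 23 - 10 + 1 = 14
  ms2 <- min_span_statistic(p2, k = 3)
  expect_equal(ms2$per_protein$min_span, 14L)

  set.seed(403)
  for (i in 1:30) {
    s <- random_protein(sample(100:1000, 1))
    pos <- oracle_motif_positions(s)
    if (length(pos) < 3) next
    want <- min(vapply(seq_len(length(pos) - 2L), function(j)
      pos[j + 2L] + 1L - pos[j] + 1L, integer(1)))
    got <- min_span_statistic(synth_proteome_from_strings(c(Z = s)),
                              k = 3)$per_protein$min_span
    expect_equal(got, want)
  }

  # proteins with < k hits are flagged and excluded from the set maximum
  p3 <- synth_proteome_from_strings(c(C = "SQAA", D = "SQAAASQAAASQ"))
  ms3 <- min_span_statistic(p3, k = 3, ids = c("C", "D"))
  expect_equal(attr(ms3, "insufficient"), "C")
  expect_equal(ms3$max_min_span, 12L)
})

test_that("planted clusters are always recovered (recall 1)", {
  cfg <- synth_config(n_proteins = 300, seed = 12,
                      planted_scds = list(list(k = 3, W = 50, count = 30),
                                          list(k = 4, W = 60, count = 10)))
  gen <- generate_proteome(cfg)
  gt <- gen$ground_truth$planted
  for (def in list(c(3L, 50L), c(4L, 60L))) {
    cen <- scan_census(gen$proteome, scd_definition(def[1], def[2]))
    sub <- gt[gt$k == def[1], , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      reg <- cen$regions[cen$regions$protein_id == sub$protein_id[r], ]
      expect_true(any(reg$start <= sub$start[r] & reg$end >= sub$end[r]))
    }
  }
})
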