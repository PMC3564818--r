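# End-to-end census pipeline: scan -> null model -> optional overlap,
# enrichment, goodness of fit, sweep and flank profile, with a JSON run
# manifest. The pipeline has no hidden state: every output equals the
# composition of the individually exported operations on the same inputs.

#' Run the SCD census pipeline
#'
#' Orchestrates the full workflow on a FASTA file: motif scan and census,
#' null-model expectation and census significance, and (when the
#' corresponding inputs are given) overlap test, term enrichment,
#' length-distribution goodness of fit, definition sweep and phosphosite
#' flank profile. All outputs are TSV files in `out_dir`, plus
#' `manifest.json` recording inputs, parameters and seed.
#'
#' @param fasta Path to the input FASTA.
#' @param out_dir Output directory (created if missing).
#' @param min_motifs,max_span,motif Cluster definition parameters (see
#'   [scd_definition()]).
#' @param lambda_mode Rate estimator for the null model.
#' @param null_method Probability method for [scd_probability()].
#' @param n_sims,seed Monte Carlo controls.
#' @param sites Optional phosphosite TSV path (enables the flank profile).
#' @param annotations Optional annotation file path (enables enrichment).
#' @param external_list Optional protein-id list path (enables the
#'   overlap test).
#' @param universe Optional universe id list path; defaults to the scanned
#'   proteome's ids.
#' @param sweep If `TRUE`, also run the default (k, W) definition sweep.
#' @param gof If `TRUE` (default), test the census length distribution
#'   against a log-normal.
#' @param bed If `TRUE`, also write a BED6 census export.
#' @return Invisibly, a list with the in-memory results (`census`,
#'   `null`, and whichever optional analyses ran) and `files` (paths
#'   written).
#' @export
run_census_pipeline <- function(fasta, out_dir,
                                min_motifs = 3L, max_span = 50L,
                                motif = "[ST]Q",
                                lambda_mode = "per_protein",
                                null_method = "monte_carlo",
                                n_sims = 1e5, seed = 17L,
                                sites = NULL, annotations = NULL,
                                external_list = NULL, universe = NULL,
                                sweep = FALSE, gof = TRUE, bed = FALSE) {
  if (!file.exists(fasta)) {
    stop("[stage: input] FASTA not found: ", fasta)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  definition <- scd_definition(min_motifs, max_span, motif)
  files <- character(0)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }

  proteome <- read_fasta(fasta)
  log_stage("read", nrow(proteome), " protein records")

  census <- scan_census(proteome, definition)
  log_stage("scan", census$census_size, " census proteins, ",
            nrow(census$regions), " regions")
  census_path <- file.path(out_dir, "census.tsv")
  write_census(census$regions, census_path,
               bed = if (bed) file.path(out_dir, "census.bed") else NULL)
  files <- c(files, census_path)

  null <- tryCatch(
    null_model(proteome, definition, lambda_mode = lambda_mode,
               method = null_method, n_sims = n_sims, seed = seed,
               observed = census$census_size),
    error = function(e) stop("[stage: null] ", conditionMessage(e)))
  log_stage("null", sprintf("expected %.2f vs observed %d",
                            null$expected_census, null$observed_census))
  null_path <- file.path(out_dir, "null.tsv")
  utils::write.table(null$table, null_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, null_path)
  summary_path <- file.path(out_dir, "null_summary.tsv")
  pv <- null$significance$p_value
  utils::write.table(
    data.frame(expected_census = null$expected_census,
               observed_census = null$observed_census,
               p_value_exact = format_pvalue(pv[["exact_dp"]]),
               p_value_normal = format_pvalue(pv[["normal_refined"]])),
    summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, summary_path)

  universe_ids <- if (is.null(universe)) proteome$id
                  else read_id_list(universe)
  results <- list(census = census, null = null)

  if (!is.null(external_list)) {
    ids <- read_id_list(external_list)
    ov <- overlap_test(census$census_ids, ids, universe_ids)
    log_stage("overlap", sprintf("x=%d expected=%.3f p=%s", ov$x,
                                 ov$expected, format_pvalue(ov$p_value)))
    ov_path <- file.path(out_dir, "overlap.tsv")
    utils::write.table(
      data.frame(N = ov$N, K = ov$K, n = ov$n, x = ov$x,
                 expected = ov$expected, p_value = ov$p_value),
      ov_path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, ov_path)
    results$overlap <- ov
  }

  if (!is.null(annotations)) {
    ann <- read_annotations(annotations)
    enr <- term_enrichment(census$census_ids, ann, universe_ids)
    log_stage("enrich", nrow(enr), " terms tested, ",
              sum(enr$significant), " significant")
    enr_path <- file.path(out_dir, "enrichment.tsv")
    utils::write.table(enr, enr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, enr_path)
    results$enrichment <- enr
  }

  if (gof && census$census_size >= 30L) {
    lens <- proteome$length[proteome$id %in% census$census_ids]
    g <- lognormal_gof(lens)
    log_stage("goffit", sprintf("chi2=%.2f df=%d p=%.4g", g$chi2, g$df,
                                g$p_value))
    gof_path <- file.path(out_dir, "gof.tsv")
    utils::write.table(
      data.frame(mu_hat = g$mu_hat, sigma_hat = g$sigma_hat,
                 n_bins = g$n_bins, chi2 = g$chi2, df = g$df,
                 p_value = g$p_value),
      gof_path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, gof_path)
    results$gof <- g
  } else if (gof) {
    log_stage("goffit", "skipped: census smaller than 30")
  }

  if (sweep) {
    sw <- sweep_definitions(proteome)
    sweep_path <- file.path(out_dir, "sweep.tsv")
    utils::write.table(sw, sweep_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, sweep_path)
    results$sweep <- sw
  }

  if (!is.null(sites)) {
    st <- read_phosphosites(sites, proteome)
    prof <- build_profile(st, proteome)
    prof_path <- file.path(out_dir, "flank_profile.tsv")
    write_profile(prof, prof_path,
                  counts_path = file.path(out_dir, "flank_counts.tsv"))
    files <- c(files, prof_path)
    results$flank <- prof
    log_stage("flank", prof$n_sites, " profiled sites")
  }

  manifest <- list(
    tool = "scdscan",
    version = as.character(utils::packageVersion("scdscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = manifest_inputs(c(fasta = fasta, sites = sites,
                               annotations = annotations,
                               external_list = external_list,
                               universe = universe)),
    parameters = list(min_motifs = min_motifs, max_span = max_span,
                      motif = motif, lambda_mode = lambda_mode,
                      null_method = null_method, n_sims = n_sims,
                      seed = seed),
    outputs = basename(files))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  results$files <- c(files, manifest_path)
  invisible(results)
}

manifest_inputs <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  lapply(paths, function(p)
    list(path = p, md5 = unname(tools::md5sum(p))))
}

format_pvalue <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-15) "< 1e-15" else format(p, digits = 6)
}
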