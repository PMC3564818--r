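# Synthetic proteomes, phosphosites and annotation maps with recorded
# ground truth. Everything is a pure function of the configuration
# including its seed; per-component seeds are derived from the global seed
# by fixed offsets so components can be regenerated independently.
#
# Sequences are i.i.d. residues from a configurable composition, so the
# true per-residue S/T-Q motif start rate is P(S or T) * P(Q). Lengths
# follow a log-normal truncated to [min_len, max_len]. Planted SCDs
# overwrite k S/T-Q dipeptides (pairwise gaps >= 2) within a span <= W,
# keeping the length model exact.

#' Yeast-like amino-acid composition preset
#'
#' S 9.0%, T 5.9%, Q 3.9% (so the S/T-Q start rate is about 0.0058 per
#' residue), remaining mass uniform over the other 17 amino acids.
#'
#' @return Named numeric 20-vector summing to 1.
#' @export
yeast_like_frequencies <- function() {
  f <- stats::setNames(rep((1 - 0.090 - 0.059 - 0.039) / 17, 20),
                       AA_STANDARD)
  f["S"] <- 0.090
  f["T"] <- 0.059
  f["Q"] <- 0.039
  f
}

#' Configuration for the synthetic-proteome generator
#'
#' @param n_proteins Number of proteins.
#' @param length_meanlog,length_sdlog Log-normal length parameters
#'   (defaults 6.0 and 0.55: median ~400 residues, yeast-like).
#' @param min_len,max_len Truncation bounds (defaults 50 and 4000).
#' @param aa_frequencies Named 20-vector of residue frequencies summing to
#'   1 (default [yeast_like_frequencies()]).
#' @param planted_scds List of directives `list(k=, W=, count=)`; each
#'   plants `count` clusters of exactly `k` S/T-Q motifs within span
#'   `<= W`, one per protein.
#' @param seed Integer seed; fully determines all outputs.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_proteins = 1000L, length_meanlog = 6.0,
                         length_sdlog = 0.55, min_len = 50L,
                         max_len = 4000L,
                         aa_frequencies = yeast_like_frequencies(),
                         planted_scds = list(), seed = 1L) {
  if (abs(sum(aa_frequencies) - 1) > 1e-9) {
    stop("aa_frequencies must sum to 1")
  }
  if (!all(AA_STANDARD %in% names(aa_frequencies))) {
    stop("aa_frequencies must be named by the 20 standard amino acids")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 aa_frequencies = aa_frequencies[AA_STANDARD],
                 planted_scds = planted_scds,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic proteome with known ground truth
#'
#' Draws lengths from the truncated log-normal, fills sequences with
#' i.i.d. residues from the configured composition, then plants the
#' requested SCDs by overwriting dipeptides. Each planted cluster is `k`
#' S/T-Q motifs with pairwise position gaps >= 2 and total span <= W,
#' placed in a protein of sufficient length (at most one plant per
#' protein). After planting, the affected proteins are rescanned so the
#' ground truth also records plants whose surroundings happened to gain
#' extra motifs.
#'
#' @param config A [synth_config()].
#' @return A list with `proteome`, and `ground_truth`: a list holding
#'   `planted` (data.frame `protein_id`, `start`, `end`, `k`, `W`),
#'   `lambda` (true motif start rate `P(S or T) * P(Q)`), `p_st`, `p_q`
#'   and `aa_frequencies`.
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_preserved_seed(config$seed, {
    n <- config$n_proteins
    f <- config$aa_frequencies
    lo <- stats::plnorm(config$min_len - 0.5, config$length_meanlog,
                        config$length_sdlog)
    hi <- stats::plnorm(config$max_len + 0.5, config$length_meanlog,
                        config$length_sdlog)
    u <- stats::runif(n, lo, hi)
    lens <- pmin(pmax(as.integer(round(stats::qlnorm(
      u, config$length_meanlog, config$length_sdlog))),
      config$min_len), config$max_len)
    residues <- sample(names(f), sum(lens), replace = TRUE, prob = f)
    seqs <- vapply(split(residues, rep.int(seq_len(n), lens)),
                   paste, character(1), collapse = "")
    ids <- sprintf("SYN%05d", seq_len(n))

    total_plants <- sum(vapply(config$planted_scds,
                               function(d) d$count, numeric(1)))
    planted <- data.frame(protein_id = character(0), start = integer(0),
                          end = integer(0), k = integer(0),
                          W = integer(0), stringsAsFactors = FALSE)
    if (total_plants > 0) {
      used <- logical(n)
      for (d in config$planted_scds) {
        k <- as.integer(d$k); W <- as.integer(d$W)
        cnt <- as.integer(d$count)
        eligible <- which(!used & lens >= W + 2L)
        if (length(eligible) < cnt) {
          stop("not enough proteins of length >= ", W + 2L,
               " to plant ", cnt, " SCD(s)")
        }
        targets <- if (length(eligible) == 1L) eligible
                   else sample(eligible, cnt)
        used[targets] <- TRUE
        for (i in targets) {
          s <- sample.int(lens[i] - W, 1L)
          # k offsets in 0..W-2 with pairwise gaps >= 2
          base <- sort(sample.int(W - 2L - 2L * (k - 1L) + 1L, k)) - 1L
          off <- base + 2L * (seq_len(k) - 1L)
          st <- sample(c("S", "T"), k, replace = TRUE)
          ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
          ch[s + off] <- st
          ch[s + off + 1L] <- "Q"
          seqs[i] <- paste(ch, collapse = "")
          planted <- rbind(planted, data.frame(
            protein_id = ids[i], start = s + off[1L],
            end = s + off[k] + 1L, k = k, W = W,
            stringsAsFactors = FALSE))
        }
      }
    }
    proteome <- new_proteome(ids, "", seqs, "synthetic")
    lam <- (f[["S"]] + f[["T"]]) * f[["Q"]]
    list(proteome = proteome,
         ground_truth = list(planted = planted,
                             lambda = lam,
                             p_st = f[["S"]] + f[["T"]],
                             p_q = f[["Q"]],
                             aa_frequencies = f))
  })
}

#' Sample phosphosites from motif positions, with flank biases
#'
#' Sites are drawn without replacement from the S/T-Q motif start
#' positions of the proteome. Optionally sites are drawn preferentially
#' from within planted SCD intervals, flanking residues are rewritten
#' under offset-specific biases, and a chosen number of rows is corrupted
#' (the stated residue flipped so validation rejects them).
#'
#' Each bias directive `list(offset=, residue=, prob=)` sets the residue
#' at `position + offset` to `residue` with probability `prob` and
#' otherwise draws it from the composition renormalized to exclude that
#' residue, so the realized frequency at the offset equals `prob`
#' exactly. Offsets 0 and +1 are structural (S/T and Q) and cannot be
#' biased. Rewrites are skipped where the offset falls outside the
#' sequence.
#'
#' @param proteome A proteome (it is returned modified when biases
#'   rewrite flanks).
#' @param n_sites Number of sites to draw; an error names the shortfall
#'   if fewer motif positions exist.
#' @param flank_bias List of bias directives, see Details.
#' @param within_pref Probability that a site is drawn from within a
#'   planted region (requires `ground_truth`); `NULL` for uniform
#'   sampling.
#' @param ground_truth Ground truth from [generate_proteome()] (needed for
#'   `within_pref`).
#' @param n_corrupt Number of rows whose stated residue is flipped
#'   (S <-> T) to simulate annotation errors.
#' @param aa_frequencies Composition used for unbiased redraws (default
#'   [yeast_like_frequencies()]).
#' @param seed Integer seed.
#' @return A list with `sites` (data.frame `protein_id`, `position`,
#'   `residue`), `proteome` (possibly rewritten) and `n_corrupt`.
#' @export
generate_phosphosites <- function(proteome, n_sites, flank_bias = list(),
                                  within_pref = NULL, ground_truth = NULL,
                                  n_corrupt = 0L,
                                  aa_frequencies = yeast_like_frequencies(),
                                  seed = 1L) {
  with_preserved_seed(seed + 1L, {
    hits <- find_motifs(proteome)
    if (nrow(hits) < n_sites) {
      stop("requested ", n_sites, " sites but only ", nrow(hits),
           " S/T-Q positions exist (short by ", n_sites - nrow(hits), ")")
    }
    if (!is.null(within_pref)) {
      if (is.null(ground_truth)) {
        stop("within_pref requires ground_truth")
      }
      gt <- ground_truth$planted
      inside <- logical(nrow(hits))
      for (r in seq_len(nrow(gt))) {
        inside <- inside |
          (hits$protein_id == gt$protein_id[r] &
           hits$position >= gt$start[r] & hits$position <= gt$end[r])
      }
      n_in <- stats::rbinom(1L, n_sites, within_pref)
      n_in <- min(n_in, sum(inside))
      n_out <- n_sites - n_in
      if (n_out > sum(!inside)) stop("not enough sites outside regions")
      pick <- c(sample(which(inside), n_in),
                sample(which(!inside), n_out))
    } else {
      pick <- sample.int(nrow(hits), n_sites)
    }
    sites <- hits[sort(pick), c("protein_id", "position")]
    sites$residue <- substring(
      proteome$sequence[match(sites$protein_id, proteome$id)],
      sites$position, sites$position)

    # rewrite flanks under the bias model
    if (length(flank_bias) > 0L && nrow(sites) > 0L) {
      seqs <- stats::setNames(proteome$sequence, proteome$id)
      for (b in flank_bias) {
        if (b$offset %in% c(0L, 1L)) {
          stop("offsets 0 and +1 are structural and cannot be biased")
        }
        others <- setdiff(AA_STANDARD, b$residue)
        pr <- aa_frequencies[others] / sum(aa_frequencies[others])
        at <- sites$position + b$offset
        lens <- nchar(seqs[sites$protein_id])
        ok <- which(at >= 1L & at <= lens)
        if (length(ok) == 0L) next
        take <- stats::runif(length(ok)) < b$prob
        newres <- ifelse(take, b$residue,
                         sample(others, length(ok), replace = TRUE,
                                prob = pr))
        for (j in seq_along(ok)) {
          i <- ok[j]
          id <- sites$protein_id[i]
          substr(seqs[[id]], at[i], at[i]) <- newres[j]
        }
      }
      proteome$sequence <- unname(seqs[proteome$id])
      proteome$length <- nchar(proteome$sequence)
    }

    n_corrupt <- as.integer(n_corrupt)
    if (n_corrupt > 0L) {
      if (n_corrupt > nrow(sites)) stop("n_corrupt exceeds site count")
      bad <- sample.int(nrow(sites), n_corrupt)
      sites$residue[bad] <- ifelse(sites$residue[bad] == "S", "T", "S")
    }
    rownames(sites) <- NULL
    list(sites = sites, proteome = proteome, n_corrupt = n_corrupt)
  })
}

#' Generate a synthetic annotation map with an optional planted term
#'
#' Background terms are assigned to proteins independently of census
#' membership (per-term membership rates drawn uniformly from
#' `background_rate_range`). An optional planted term is assigned with
#' `inside_rate` to census members and `outside_rate` to the rest, giving
#' a known enrichment signal (or a known null when the two rates are
#' equal).
#'
#' @param universe_ids Protein ids forming the universe.
#' @param census_ids Census member ids (subset of the universe).
#' @param n_terms Number of background terms.
#' @param background_rate_range Range for per-term background membership
#'   rates (default `c(0.02, 0.2)`).
#' @param planted `NULL` or `list(term_id=, inside_rate=, outside_rate=)`.
#' @param seed Integer seed.
#' @return An `annotation_map`; the planted term id (if any) is stored in
#'   the `planted_term` attribute.
#' @export
generate_annotations <- function(universe_ids, census_ids = character(0),
                                 n_terms = 50L,
                                 background_rate_range = c(0.02, 0.2),
                                 planted = NULL, seed = 1L) {
  with_preserved_seed(seed + 2L, {
    universe_ids <- unique(universe_ids)
    terms <- list()
    if (n_terms > 0L) {
      rates <- stats::runif(n_terms, background_rate_range[1L],
                            background_rate_range[2L])
      for (t in seq_len(n_terms)) {
        members <- universe_ids[stats::runif(length(universe_ids)) <
                                rates[t]]
        if (length(members) > 0L) {
          terms[[sprintf("BG%04d", t)]] <- members
        }
      }
    }
    if (!is.null(planted)) {
      if (planted$inside_rate < 0 || planted$inside_rate > 1 ||
          planted$outside_rate < 0 || planted$outside_rate > 1) {
        stop("planted rates must lie in [0, 1]")
      }
      inside <- universe_ids %in% census_ids
      pr <- ifelse(inside, planted$inside_rate, planted$outside_rate)
      members <- universe_ids[stats::runif(length(universe_ids)) < pr]
      terms[[planted$term_id]] <- members
    }
    terms <- lapply(terms, function(v) sort(unique(v)))
    terms <- terms[lengths(terms) > 0L]
    out <- new_annotation_map(terms,
                              stats::setNames(names(terms), names(terms)))
    attr(out, "planted_term") <- if (is.null(planted)) NULL
                                 else planted$term_id
    out
  })
}
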