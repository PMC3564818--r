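# Position-specific amino-acid frequency profiles around phosphorylated
# S/T-Q sites (the phosphosite S/T sits at offset 0, its Q at offset +1).
# Counts are pooled per offset over all sites; offsets that fall outside a
# sequence (sites near a terminus) simply contribute nothing at that
# offset, so per-offset denominators can differ.

#' Build a flanking-residue frequency profile
#'
#' @param sites A phosphosite table (`protein_id`, `position`, `residue`)
#'   as returned by [read_phosphosites()] or [generate_phosphosites()].
#' @param proteome The proteome the sites refer to.
#' @param flank Number of flanking offsets on each side (default 5, i.e.
#'   offsets -5..+5).
#' @param restrict_to `"any"` (default), `"within_scd"` or
#'   `"outside_scd"`; for the latter two, `regions` is required and a site
#'   is within an SCD when its position lies in `[start, end]` of some
#'   region of its protein.
#' @param regions Region table (from [scan_census()]) used by
#'   `restrict_to`.
#' @param require_q If `TRUE` (default) only sites whose following residue
#'   is Q are profiled (the pS/T-Q definition); others are excluded and
#'   counted. Set `FALSE` to admit any pS/T site.
#' @return A `flank_profile`: list with `counts` and `freqs`
#'   (offset x 20 amino-acid matrices), `per_offset_totals`, `n_sites`,
#'   `n_excluded_not_q`, `n_excluded_not_st` (sites whose own residue is
#'   not S/T are never profiled), `flank`.
#' @examples
#' p <- synth_proteome_from_strings(c(P1 = "AAAAASQAAAAA"))
#' s <- data.frame(protein_id = "P1", position = 6L, residue = "S")
#' build_profile(s, p)
#' @export
build_profile <- function(sites, proteome, flank = 5L,
                          restrict_to = c("any", "within_scd",
                                          "outside_scd"),
                          regions = NULL, require_q = TRUE) {
  restrict_to <- match.arg(restrict_to)
  flank <- as.integer(flank)
  offsets <- seq.int(-flank, flank)

  idx <- match(sites$protein_id, proteome$id)
  if (anyNA(idx)) stop("site refers to unknown protein id")
  seqs <- proteome$sequence[idx]
  lens <- proteome$length[idx]
  pos <- as.integer(sites$position)

  # a profiled site must itself be S or T (the pS/T definition) ...
  own <- substring(seqs, pos, pos)
  keep <- own %in% c("S", "T")
  n_excluded_not_st <- sum(!keep)
  # ... and, unless the permissive flag is set, be followed by Q
  n_excluded <- 0L
  if (require_q && length(pos) > 0L) {
    nxt <- substring(seqs, pos + 1L, pos + 1L)
    n_excluded <- sum(keep & nxt != "Q")
    keep <- keep & nxt == "Q"
  }
  seqs <- seqs[keep]; lens <- lens[keep]; pos <- pos[keep]
  ids <- sites$protein_id[keep]

  if (restrict_to != "any") {
    if (is.null(regions)) {
      stop("restrict_to = \"", restrict_to, "\" requires regions")
    }
    inside <- logical(length(pos))
    if (length(pos) > 0L && nrow(regions) > 0L) {
      for (i in seq_along(pos)) {
        r <- regions[regions$protein_id == ids[i], , drop = FALSE]
        inside[i] <- any(pos[i] >= r$start & pos[i] <= r$end)
      }
    }
    keep <- if (restrict_to == "within_scd") inside else !inside
    seqs <- seqs[keep]; lens <- lens[keep]; pos <- pos[keep]
  }

  counts <- matrix(0L, nrow = length(offsets), ncol = length(AA_STANDARD),
                   dimnames = list(offset = offsets, aa = AA_STANDARD))
  for (o in seq_along(offsets)) {
    at <- pos + offsets[o]
    ok <- at >= 1L & at <= lens
    if (!any(ok)) next
    res <- substring(seqs[ok], at[ok], at[ok])
    tab <- table(factor(res, levels = AA_STANDARD))
    counts[o, ] <- as.integer(tab)
  }
  totals <- rowSums(counts)
  freqs <- counts / ifelse(totals > 0L, totals, 1L)
  structure(list(counts = counts, freqs = freqs,
                 per_offset_totals = totals,
                 n_sites = length(pos),
                 n_excluded_not_q = n_excluded,
                 n_excluded_not_st = n_excluded_not_st,
                 flank = flank),
            class = "flank_profile")
}

#' @export
print.flank_profile <- function(x, ...) {
  cat(sprintf("flank profile over %d site(s), offsets %+d..%+d\n",
              x$n_sites, -x$flank, x$flank))
  if (x$n_excluded_not_q > 0L) {
    cat(sprintf("  %d site(s) excluded (following residue not Q)\n",
                x$n_excluded_not_q))
  }
  invisible(x)
}

#' Log2 enrichment of a profile over a background profile
#'
#' Per-cell `log2((f + eps) / (g + eps))` with
#' `eps = 1 / (2 * max(per-offset totals))`, plus delta-method binomial
#' standard errors on the log2 scale. Offsets with zero total in either
#' profile are reported as missing.
#'
#' @param profile,background `flank_profile` objects sharing offsets.
#' @return A list with matrices `log2_ratio` and `se` (NA where either
#'   offset total is zero) and the smoothing constant `eps`.
#' @export
compare_to_background <- function(profile, background) {
  if (!identical(rownames(profile$freqs), rownames(background$freqs))) {
    stop("profiles must share offsets")
  }
  n_f <- profile$per_offset_totals
  n_g <- background$per_offset_totals
  eps <- 1 / (2 * max(c(n_f, n_g, 1)))
  f <- profile$freqs
  g <- background$freqs
  ratio <- log2((f + eps) / (g + eps))
  # delta method on smoothed frequencies, var(log2 f) ~ (1-f)/(f n ln2^2)
  vf <- sweep((1 - f) / pmax(f + eps, eps), 1, pmax(n_f, 1), "/")
  vg <- sweep((1 - g) / pmax(g + eps, eps), 1, pmax(n_g, 1), "/")
  se <- sqrt(vf + vg) / log(2)
  miss <- n_f == 0L | n_g == 0L
  ratio[miss, ] <- NA_real_
  se[miss, ] <- NA_real_
  list(log2_ratio = ratio, se = se, eps = eps)
}

#' Write a flank profile as frequency and count TSVs
#'
#' Rows are offsets (-flank..+flank), columns the 20 amino acids; the
#' frequency matrix is consumable by standard logo-drawing tools.
#'
#' @param profile A `flank_profile`.
#' @param path Output TSV path for frequencies.
#' @param counts_path Optional TSV path for raw counts.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, counts_path = NULL) {
  utils::write.table(
    data.frame(offset = rownames(profile$freqs), profile$freqs,
               check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(counts_path)) {
    utils::write.table(
      data.frame(offset = rownames(profile$counts), profile$counts,
                 check.names = FALSE),
      counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
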