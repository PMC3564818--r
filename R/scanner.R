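# Motif enumeration and SCD cluster detection.
#
# The motif is a fixed-length residue-class pattern (default "[ST]Q", the
# PIKK kinase consensus). A cluster (SCD) under definition (k, W) is at
# least k motif occurrences whose span — from the S/T of the first motif
# through the Q of the last, inclusive — is at most W residues.
# Occurrence enumeration is exhaustive (every start position tested), and
# cluster detection windows over consecutive k-tuples of occurrences:
# if any k-subset of occurrences fits in a span, the k consecutive
# occurrences inside that span do too, so consecutive windowing is
# sufficient. Qualifying windows that share occurrences are merged
# transitively into maximal regions.

#' Construct an SCD definition
#'
#' @param min_motifs Minimum number of motif occurrences `k` (>= 2);
#'   default 3.
#' @param max_span Maximum region span `W` in residues (from the first
#'   motif's S/T through the last motif's Q, inclusive); default 50.
#'   Must satisfy `W >= 2 * k` so that a span can hold `k` non-overlapping
#'   dipeptides.
#' @param motif Fixed-length residue-class pattern; each element is either
#'   a single residue or a bracketed class like `[ST]`. Default `"[ST]Q"`.
#' @return An object of class `scd_definition`.
#' @examples
#' scd_definition()                    # the default: >= 3 S/T-Q within 50
#' scd_definition(min_motifs = 5, max_span = 100)
#' @export
scd_definition <- function(min_motifs = 3L, max_span = 50L,
                           motif = "[ST]Q") {
  k <- as.integer(min_motifs)
  W <- as.integer(max_span)
  if (is.na(k) || k < 2L) stop("min_motifs must be an integer >= 2")
  tokens <- parse_motif_pattern(motif)
  ml <- length(tokens)
  if (is.na(W) || W < ml * k) {
    stop("max_span must be >= ", ml * k,
         " (k non-overlapping motifs of length ", ml, ")")
  }
  structure(list(min_motifs = k, max_span = W, motif = motif,
                 motif_length = ml, tokens = tokens),
            class = "scd_definition")
}

#' @export
print.scd_definition <- function(x, ...) {
  cat(sprintf("SCD definition: >= %d x %s within a span of <= %d residues\n",
              x$min_motifs, x$motif, x$max_span))
  invisible(x)
}

# Split a class pattern like "[ST]Q" into per-position tokens.
parse_motif_pattern <- function(motif) {
  m <- gregexpr("\\[[A-Z]+\\]|[A-Z]", motif)[[1L]]
  if (m[1L] == -1L) stop("cannot parse motif pattern: ", motif)
  tokens <- regmatches(motif, gregexpr("\\[[A-Z]+\\]|[A-Z]", motif))[[1L]]
  if (sum(nchar(gsub("[^A-Z]", "", tokens))) !=
      nchar(gsub("[^A-Z]", "", motif))) {
    stop("cannot parse motif pattern: ", motif)
  }
  tokens
}

#' Find all motif occurrences in a proteome
#'
#' Exhaustive scan: every start position is tested, so overlapping
#' pattern instances are all reported (for the default S/T-Q motif,
#' occurrences can never overlap because Q is not S/T, and consecutive
#' hits therefore differ by at least 2). Ambiguity characters
#' (B, Z, X, U, O, *) never match a residue class.
#'
#' @param proteome A proteome (or any data.frame with `id` and `sequence`
#'   columns); a single record (one row) is fine.
#' @param motif Residue-class pattern, default `"[ST]Q"`.
#' @return A `data.frame` with columns `protein_id`, `position` (1-based
#'   index of the first pattern position) and `dipeptide` (the matched
#'   residues), ordered by protein then position.
#' @examples
#' p <- synth_proteome_from_strings(c(P1 = "AAASQATQGG"))
#' find_motifs(p)   # positions 4 and 7
#' @export
find_motifs <- function(proteome, motif = "[ST]Q") {
  tokens <- parse_motif_pattern(motif)
  ml <- length(tokens)
  rx <- paste0("(?=", paste(tokens, collapse = ""), ")")
  hits <- lapply(seq_len(nrow(proteome)), function(i) {
    s <- proteome$sequence[i]
    m <- gregexpr(rx, s, perl = TRUE)[[1L]]
    pos <- as.integer(m)
    pos <- pos[pos > 0L]
    if (length(pos) == 0L) return(NULL)
    data.frame(protein_id = proteome$id[i],
               position = pos,
               dipeptide = substring(s, pos, pos + ml - 1L),
               stringsAsFactors = FALSE)
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (length(hits) == 0L) {
    return(data.frame(protein_id = character(0), position = integer(0),
                      dipeptide = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

# Core region detection on sorted positions of one protein.
# Returns a data.frame(start, end, n_motifs, motif_positions).
scd_regions_from_positions <- function(positions, k, W, motif_length = 2L) {
  n <- length(positions)
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_motifs = integer(0))
  empty$motif_positions <- list()
  if (n < k) return(empty)
  p <- as.integer(positions)
  # consecutive k-window spans: first S/T through last motif's final residue
  span <- p[k:n] + (motif_length - 1L) - p[seq_len(n - k + 1L)] + 1L
  q <- which(span <= W)           # indices j of qualifying windows [j, j+k-1]
  if (length(q) == 0L) return(empty)
  # windows share a hit iff their start indices differ by <= k-1
  grp <- cumsum(c(1L, diff(q) > (k - 1L)))
  starts <- tapply(q, grp, min)
  ends <- tapply(q, grp, max) + (k - 1L)
  out <- data.frame(start = p[starts],
                    end = p[ends] + (motif_length - 1L),
                    n_motifs = ends - starts + 1L)
  out$motif_positions <- lapply(seq_along(starts), function(i)
    p[starts[i]:ends[i]])
  rownames(out) <- NULL
  out
}

#' Detect maximal SCD regions from motif hits
#'
#' A consecutive k-tuple of hits qualifies when its span (first S/T
#' through last Q, inclusive) is at most `W`; qualifying tuples that share
#' hits are merged transitively into maximal regions.
#'
#' @param hits Hit table from [find_motifs()] (may cover several
#'   proteins), or an integer vector of positions for a single protein.
#' @param definition An [scd_definition()].
#' @param protein_id Id used when `hits` is a bare position vector.
#' @return A `data.frame` with columns `protein_id`, `start`, `end`,
#'   `n_motifs` and list-column `motif_positions`, in position order
#'   within each protein.
#' @examples
#' find_scd_regions(c(10L, 30L, 58L), scd_definition())   # span 50: one region
#' find_scd_regions(c(10L, 30L, 59L), scd_definition())   # span 51: none
#' @export
find_scd_regions <- function(hits, definition = scd_definition(),
                             protein_id = "protein") {
  if (is.numeric(hits)) {
    hits <- data.frame(protein_id = rep(protein_id, length(hits)),
                       position = as.integer(hits),
                       stringsAsFactors = FALSE)
  }
  k <- definition$min_motifs
  W <- definition$max_span
  ml <- definition$motif_length
  pieces <- lapply(split(hits$position, hits$protein_id), function(p)
    scd_regions_from_positions(sort(p), k, W, ml))
  keep <- vapply(pieces, nrow, integer(1)) > 0L
  if (!any(keep)) {
    out <- data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), n_motifs = integer(0),
                      stringsAsFactors = FALSE)
    out$motif_positions <- list()
    return(out)
  }
  pieces <- pieces[keep]
  out <- do.call(rbind, pieces)
  out <- data.frame(protein_id = rep(names(pieces),
                                     vapply(pieces, nrow, integer(1))),
                    out, stringsAsFactors = FALSE)
  # keep input protein order if hits came from find_motifs
  ord <- order(match(out$protein_id, unique(hits$protein_id)), out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Census of SCD-containing proteins
#'
#' Scans every protein of a proteome for motif occurrences, detects
#' maximal SCD regions under the given definition, and reports the census:
#' the set of proteins with at least one region.
#'
#' @param proteome A proteome from [read_fasta()] or [generate_proteome()].
#' @param definition An [scd_definition()].
#' @return An object of class `scd_census`: a list with `regions` (region
#'   table as in [find_scd_regions()]), `census_ids`, `census_size`,
#'   `n_proteins`, `hits` (the motif hit table) and `definition`.
#' @export
scan_census <- function(proteome, definition = scd_definition()) {
  hits <- find_motifs(proteome, definition$motif)
  regions <- find_scd_regions(hits, definition)
  ids <- unique(regions$protein_id)
  ids <- ids[order(match(ids, proteome$id))]
  structure(list(regions = regions,
                 census_ids = ids,
                 census_size = length(ids),
                 n_proteins = nrow(proteome),
                 hits = hits,
                 definition = definition),
            class = "scd_census")
}

#' @export
print.scd_census <- function(x, ...) {
  print(x$definition)
  cat(sprintf("census: %d of %d proteins carry >= 1 SCD region (%d regions)\n",
              x$census_size, x$n_proteins, nrow(x$regions)))
  invisible(x)
}

#' Sweep cluster definitions over a (k, W) grid
#'
#' Recomputes the census size for every combination of minimum motif count
#' and maximum span. Census size is non-decreasing in `W` at fixed `k` and
#' non-increasing in `k` at fixed `W`.
#'
#' @param proteome A proteome.
#' @param k_values Integer vector of minimum motif counts (default `3:5`).
#' @param span_values Integer vector of maximum spans (default
#'   `seq(50, 100, by = 5)`).
#' @param motif Residue-class pattern, default `"[ST]Q"`.
#' @return A `data.frame` with columns `k`, `W`, `census_size`,
#'   `n_regions`, one row per grid point.
#' @export
sweep_definitions <- function(proteome, k_values = 3:5,
                              span_values = seq(50L, 100L, by = 5L),
                              motif = "[ST]Q") {
  if (length(k_values) == 0L || length(span_values) == 0L) {
    stop("k_values and span_values must be non-empty")
  }
  hits <- find_motifs(proteome, motif)
  ml <- length(parse_motif_pattern(motif))
  by_prot <- split(hits$position, hits$protein_id)
  grid <- expand.grid(k = as.integer(k_values),
                      W = as.integer(span_values))
  res <- t(vapply(seq_len(nrow(grid)), function(i) {
    k <- grid$k[i]; W <- grid$W[i]
    counts <- vapply(by_prot, function(p) {
      nrow(scd_regions_from_positions(sort(p), k, W, ml))
    }, integer(1))
    c(census_size = sum(counts > 0L), n_regions = sum(counts))
  }, c(census_size = 0L, n_regions = 0L)))
  cbind(grid, as.data.frame(res))
}

#' Minimal qualifying span per protein
#'
#' For each protein with at least `k` motif occurrences, the minimum over
#' consecutive k-tuples of the span (first S/T through last Q). The
#' maximum of this statistic over a set of reference proteins is how a
#' data-driven span threshold can be derived (e.g. the tightest span that
#' still covers every known cluster protein).
#'
#' @param proteome A proteome.
#' @param k Number of motifs per tuple (default 3).
#' @param ids Optional protein ids over which to take the set maximum
#'   (default: all proteins with >= k hits). Ids with fewer than `k` hits
#'   are flagged in the `insufficient` attribute and excluded.
#' @param motif Residue-class pattern.
#' @return A list with `per_protein` (data.frame `protein_id`, `n_motifs`,
#'   `min_span`) and `max_min_span` (the set maximum over `ids`).
#' @examples
#' p <- synth_proteome_from_strings(c(
#'   A = "SQAAAAAAASQAAAAAAAASQ"))  # hits 1, 10, 20 -> min span 21
#' min_span_statistic(p, k = 3)
#' @export
min_span_statistic <- function(proteome, k = 3L, ids = NULL,
                               motif = "[ST]Q") {
  k <- as.integer(k)
  hits <- find_motifs(proteome, motif)
  ml <- length(parse_motif_pattern(motif))
  by_prot <- split(hits$position, hits$protein_id)
  mins <- vapply(by_prot, function(p) {
    p <- sort(p)
    n <- length(p)
    if (n < k) return(NA_integer_)
    min(p[k:n] + (ml - 1L) - p[seq_len(n - k + 1L)] + 1L)
  }, integer(1))
  per <- data.frame(protein_id = names(by_prot),
                    n_motifs = lengths(by_prot),
                    min_span = unname(mins),
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  if (is.null(ids)) ids <- per$protein_id[!is.na(per$min_span)]
  sel <- per$min_span[match(ids, per$protein_id)]
  insufficient <- ids[is.na(sel)]
  out <- list(per_protein = per,
              max_min_span = if (all(is.na(sel))) NA_integer_
                             else max(sel, na.rm = TRUE))
  attr(out, "insufficient") <- insufficient
  out
}

#' Build a proteome from named sequence strings
#'
#' Convenience constructor used in examples and tests: turns a named
#' character vector of residue strings into a proteome table.
#'
#' @param x Named character vector (names become ids).
#' @param source_label Source label attribute.
#' @return A proteome `data.frame`.
#' @export
synth_proteome_from_strings <- function(x, source_label = "in-memory") {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    names(x) <- paste0("P", seq_along(x))
  }
  new_proteome(names(x), "", toupper(unname(x)), source_label)
}
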