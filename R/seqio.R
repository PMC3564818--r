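# Sequence and table I/O: FASTA proteomes, phosphosite tables, annotation
# maps, census exports. All coordinates are 1-based inclusive internally;
# only the BED export converts to 0-based half-open.

# Residues admitted in a ProteinRecord: the 20 standard amino acids plus
# ambiguity/non-standard codes. Ambiguity codes never match the motif class.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_AMBIGUOUS <- c("B", "Z", "X", "U", "O", "*")

#' Read a protein FASTA file into a proteome table
#'
#' Parses a (possibly multi-line) FASTA file into a proteome: one row per
#' entry with columns `id`, `description`, `sequence` and `length`. The id
#' is the first whitespace-delimited token of the header; UniProt-style
#' `db|ACC|NAME` headers are reduced to the primary accession `ACC`.
#' Sequences are upper-cased and a terminal `*` is stripped. Records
#' containing characters outside the allowed alphabet (20 standard amino
#' acids plus `B Z X U O *`) are rejected with a summary message; the run
#' continues. Duplicate ids are an error.
#'
#' @param path Path to a FASTA file.
#' @param source_label Label stored as the `source_label` attribute;
#'   defaults to the file name.
#' @return A `data.frame` of class `proteome` with columns `id`,
#'   `description`, `sequence`, `length`. Rejected records (if any) are
#'   listed in the `rejected` attribute.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P00001|TEST test protein", "MSQ"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file is empty: ", path)
  }
  headers <- names(set)
  ids <- parse_fasta_id(headers)
  desc <- sub("^\\S*\\s*", "", headers)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)

  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }

  allowed <- c(AA_STANDARD, AA_AMBIGUOUS)
  bad_chars <- vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    paste(unique(ch[!(ch %in% allowed)]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  ok <- nzchar(seqs) & !nzchar(bad_chars)
  rejected <- data.frame(id = ids[!ok], reason = ifelse(
    nzchar(seqs[!ok]),
    paste0("illegal character(s): ", bad_chars[!ok]),
    "empty sequence"
  ), stringsAsFactors = FALSE)
  if (nrow(rejected) > 0L) {
    message(nrow(rejected), " record(s) rejected on read (",
            "illegal characters or empty sequence): ",
            paste(utils::head(rejected$id, 5L), collapse = ", "),
            if (nrow(rejected) > 5L) ", ..." else "")
  }

  prot <- new_proteome(ids[ok], desc[ok], seqs[ok], source_label)
  attr(prot, "rejected") <- rejected
  prot
}

parse_fasta_id <- function(headers) {
  tok <- sub("\\s.*$", "", headers)
  uni <- grepl("^[A-Za-z0-9]+\\|[^|]+\\|", tok)
  tok[uni] <- sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", tok[uni])
  tok
}

new_proteome <- function(id, description, sequence, source_label = "") {
  prot <- data.frame(id = as.character(id),
                     description = as.character(description),
                     sequence = as.character(sequence),
                     length = nchar(sequence),
                     stringsAsFactors = FALSE)
  rownames(prot) <- NULL
  attr(prot, "source_label") <- source_label
  class(prot) <- c("proteome", "data.frame")
  prot
}

#' @export
print.proteome <- function(x, ...) {
  cat("proteome:", nrow(x), "records",
      sprintf("(source: %s)\n", attr(x, "source_label") %||% ""))
  cat("residues:", sum(x$length),
      " length range:", if (nrow(x)) paste(range(x$length), collapse = "-") else "-",
      "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a proteome to FASTA
#'
#' Inverse of [read_fasta()]: headers are `id` or `id description`, one
#' sequence line per record. `read_fasta(write_fasta(p))` reproduces `p`.
#'
#' @param proteome A proteome as returned by [read_fasta()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  headers <- ifelse(nzchar(proteome$description),
                    paste(proteome$id, proteome$description),
                    proteome$id)
  set <- Biostrings::BStringSet(proteome$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read and validate a phosphosite table
#'
#' Reads a TSV with columns `protein_id`, `position`, `residue` and
#' validates each row against the proteome: the protein must exist, the
#' position must be an integer within the protein length, the stated
#' residue must be S or T and must equal the residue at that position of
#' the sequence. Failing rows are excluded and counted by reason.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param proteome A proteome as returned by [read_fasta()].
#' @return A `data.frame` with columns `protein_id`, `position`,
#'   `residue`; the `rejected` attribute holds a named count vector by
#'   rejection reason and the `rejected_rows` attribute the offending rows.
#' @export
read_phosphosites <- function(path, proteome) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("protein_id", "position", "residue")
  if (!all(need %in% names(raw))) {
    stop("phosphosite table must have columns: ",
         paste(need, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(raw$position))
  res <- toupper(raw$residue)
  idx <- match(raw$protein_id, proteome$id)

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(pos) | as.character(pos) != raw$position] <- "non_integer_position"
  reason[is.na(reason) & is.na(idx)] <- "unknown_protein"
  in_range <- !is.na(reason) | (pos >= 1L & pos <= proteome$length[idx])
  reason[is.na(reason) & !in_range] <- "position_out_of_range"
  reason[is.na(reason) & !(res %in% c("S", "T"))] <- "residue_not_st"
  ok <- is.na(reason)
  actual <- substr(proteome$sequence[idx[ok]], pos[ok], pos[ok])
  mism <- actual != res[ok]
  reason[which(ok)[mism]] <- "residue_mismatch"
  ok <- is.na(reason)

  if (any(!ok)) {
    warning(sum(!ok), " phosphosite row(s) rejected (",
            paste(sprintf("%s: %d", names(table(reason[!ok])),
                          as.integer(table(reason[!ok]))), collapse = "; "),
            ")")
  }
  out <- data.frame(protein_id = raw$protein_id[ok],
                    position = pos[ok],
                    residue = res[ok],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rejected") <- table(factor(reason[!ok]))
  attr(out, "rejected_rows") <- raw[!ok, , drop = FALSE]
  out
}

#' Read a term-to-protein annotation map
#'
#' Accepts either GAF 2.x (17-column gene association format; rows with a
#' `NOT` qualifier are skipped) or a two/three-column TSV
#' (`term_id`, `protein_id`[, `term_name`]). Protein sets per term are
#' deduplicated. Unparseable lines are skipped and counted.
#'
#' @param path Path to the annotation file.
#' @return An `annotation_map`: a list with `terms` (named list of protein
#'   id vectors) and `term_names` (named character vector). The number of
#'   skipped lines is in the `skipped` attribute.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(new_annotation_map(list(), character(0), skipped = 0L))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  is_gaf <- stats::median(nf) >= 15L

  if (is_gaf) {
    ok <- nf >= 15L
    term <- vapply(fields[ok], `[[`, character(1), 5L)
    prot <- vapply(fields[ok], `[[`, character(1), 2L)
    qual <- vapply(fields[ok], `[[`, character(1), 4L)
    keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
    term <- term[keep]
    prot <- prot[keep]
    name <- stats::setNames(term, term)
  } else {
    ok <- nf >= 2L
    term <- vapply(fields[ok], `[[`, character(1), 1L)
    prot <- vapply(fields[ok], `[[`, character(1), 2L)
    name3 <- vapply(fields[ok], function(f)
      if (length(f) >= 3L) f[[3L]] else NA_character_, character(1))
    name <- tapply(name3, term, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) v[[1L]] else NA_character_
    })
    name <- stats::setNames(ifelse(is.na(name), names(name), name),
                            names(name))
  }
  skipped <- sum(!ok)
  if (skipped > 0L) {
    message(skipped, " unparseable annotation line(s) skipped")
  }
  terms <- lapply(split(prot, term), function(v) sort(unique(v)))
  terms <- terms[lengths(terms) > 0L]
  new_annotation_map(terms, name[names(terms)], skipped = skipped)
}

new_annotation_map <- function(terms, term_names, skipped = 0L) {
  out <- list(terms = terms,
              term_names = stats::setNames(as.character(term_names),
                                           names(terms)))
  attr(out, "skipped") <- skipped
  class(out) <- "annotation_map"
  out
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("annotation_map:", length(x$terms), "terms,",
      length(unique(unlist(x$terms, use.names = FALSE))), "proteins\n")
  invisible(x)
}

#' Write an SCD census to TSV (and optionally BED6)
#'
#' The TSV has fixed columns `protein_id`, `start`, `end`, `span`,
#' `n_motifs`, `motif_positions` (comma-joined, 1-based inclusive). The
#' optional BED6 export converts to 0-based half-open coordinates
#' (`start - 1`, `end`), with name `SCD`, score `n_motifs`, strand `.`.
#'
#' @param regions A region table as produced by [scan_census()] (the
#'   `regions` element) or [find_scd_regions()].
#' @param path Output TSV path.
#' @param bed Optional output BED6 path.
#' @return `path`, invisibly.
#' @export
write_census <- function(regions, path, bed = NULL) {
  pos_str <- vapply(regions$motif_positions, function(p)
    paste(p, collapse = ","), character(1))
  tab <- data.frame(protein_id = regions$protein_id,
                    start = regions$start,
                    end = regions$end,
                    span = regions$end - regions$start + 1L,
                    n_motifs = regions$n_motifs,
                    motif_positions = pos_str,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed)) {
    bed_tab <- data.frame(chrom = regions$protein_id,
                          chromStart = regions$start - 1L,
                          chromEnd = regions$end,
                          name = rep("SCD", nrow(regions)),
                          score = regions$n_motifs,
                          strand = rep(".", nrow(regions)),
                          stringsAsFactors = FALSE)
    utils::write.table(bed_tab, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a census TSV written by [write_census()]
#'
#' @param path Path to the census TSV.
#' @return A region `data.frame` with `motif_positions` as a list column.
#' @export
read_census <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(protein_id = "character",
                                          motif_positions = "character"))
  tab$motif_positions <- lapply(strsplit(tab$motif_positions, ",",
                                         fixed = TRUE), as.integer)
  if (nrow(tab) == 0L) tab$motif_positions <- list()
  tab
}

#' Read a plain-text protein id list (one id per line)
#'
#' @param path Path to the list file; blank lines and `#` comments skipped.
#' @return Character vector of unique ids in file order.
#' @export
read_id_list <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  unique(ids)
}
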