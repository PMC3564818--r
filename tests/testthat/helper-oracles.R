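# Independent brute-force oracles and small generators shared across the
# test files. These stay deliberately naive: character-by-character scans
# and exhaustive subset enumeration, never the package's own algorithms.

# every index i with sequence[i] in {S,T} and sequence[i+1] == "Q"
oracle_motif_positions <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < 2L) return(integer(0))
  which(ch[-n] %in% c("S", "T") & ch[-1L] == "Q")
}

# union of the intervals [min, max + 1] of every k-subset of hit
# positions whose span (max + 1 - min + 1) is <= W; overlapping intervals
# merged; returns data.frame(start, end)
oracle_regions <- function(positions, k, W) {
  positions <- sort(positions)
  n <- length(positions)
  if (n < k) return(data.frame(start = integer(0), end = integer(0)))
  subsets <- utils::combn(positions, k)
  span <- subsets[k, ] + 1L - subsets[1L, ] + 1L
  qual <- span <= W
  if (!any(qual)) return(data.frame(start = integer(0), end = integer(0)))
  iv <- cbind(subsets[1L, qual], subsets[k, qual] + 1L)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (r in seq_len(nrow(iv))[-1L]) {
    if (iv[r, 1L] <= out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], iv[r, 2L])
    } else {
      out <- rbind(out, iv[r, , drop = FALSE])
    }
  }
  data.frame(start = out[, 1L], end = out[, 2L])
}

# random protein string from a composition (defaults to the yeast-like
# preset), for oracle-equivalence sweeps
random_protein <- function(len, freqs = yeast_like_frequencies()) {
  paste(sample(names(freqs), len, replace = TRUE, prob = freqs),
        collapse = "")
}

# P(X >= x) for a Poisson-binomial by exhaustive enumeration over all
# 2^n outcomes (n <= ~14)
oracle_poisbin_tail <- function(p, x) {
  n <- length(p)
  total <- 0
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code)[seq_len(n)])
    if (sum(bits) >= x) {
      total <- total + prod(ifelse(bits == 1L, p, 1 - p))
    }
  }
  total
}

# exact P(motif-cluster event) for a sequence of i.i.d. residue classes
# (S/T with prob s, Q with prob q) by enumeration over all 3^L class
# sequences; the event applies the same span rule as the scanner
oracle_composition_prob <- function(L, s, q, k, W) {
  probs <- c(s, q, 1 - s - q)
  grid <- expand.grid(rep(list(1:3), L))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    cls <- as.integer(grid[r, ])
    pos <- which(cls[-L] == 1L & cls[-1L] == 2L)
    n <- length(pos)
    if (n >= k && any(pos[k:n] - pos[seq_len(n - k + 1L)] <= W - 2L)) {
      total <- total + prod(probs[cls])
    }
  }
  total
}

# 20-vector with zero S/T/Q mass (no background motifs possible)
motif_free_frequencies <- function() {
  f <- stats::setNames(rep(1 / 17, 20), names(yeast_like_frequencies()))
  f[c("S", "T", "Q")] <- 0
  f
}
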