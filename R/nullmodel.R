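# Null model for the SCD census.
#
# Each protein i is a Bernoulli trial with success probability
# p_i = P(a protein of length L_i with per-residue motif rate lambda_i
# contains >= k motif events within a span of <= W residues). The expected
# census size is sum(p_i) and the census size under the null is
# Poisson-binomial; the upper tail gives the census significance.
#
# The event uses the scanner's span convention: motif events at positions
# p_1 < ... < p_k qualify when (p_k + 1) - p_1 + 1 <= W, i.e.
# p_k - p_1 <= W - 2 (the dipeptide's Q occupies position p + 1).
#
# Methods for p_i:
#   monte_carlo  - simulate per-residue Bernoulli(lambda) indicators and
#                  apply the span rule (seeded; standard error reported)
#   exact_small  - exhaustive enumeration over all 2^L indicator vectors
#                  (L <= 22), used as the oracle for the others
#   exact_dp     - exact dynamic program over inter-event gap states;
#                  same model as monte_carlo/exact_small, any L
#   approximation- product-type scan-statistic closed form, validated
#                  against the exact methods
# scd_probability_composition() is a separate exact null for sequences of
# i.i.d. residues with known P(S/T) and P(Q); unlike the Bernoulli
# idealization it accounts for the 2-residue motif footprint (adjacent
# motif starts are impossible).

#' Per-protein motif rate estimates
#'
#' Counts motif occurrences per protein and converts them to per-residue
#' rates under one of three estimators:
#' \describe{
#'   \item{per_protein}{`lambda_i = m_i / L_i` (default): each protein's
#'     own occurrence count divided by its length.}
#'   \item{global_mean_per_protein}{`lambda_i = mean(m) / L_i`: the
#'     proteome-mean occurrence count divided by each protein's length.}
#'   \item{global_per_residue}{`lambda_i = sum(m) / sum(L)`: one pooled
#'     rate for every protein.}
#' }
#'
#' @param proteome A proteome.
#' @param motif Residue-class pattern, default `"[ST]Q"`.
#' @param mode Rate estimator; see Details.
#' @return A `data.frame` with columns `protein_id`, `L`, `m`, `lambda`
#'   and a `mode` attribute.
#' @export
estimate_rates <- function(proteome, motif = "[ST]Q",
                           mode = c("per_protein", "global_mean_per_protein",
                                    "global_per_residue")) {
  mode <- match.arg(mode)
  if (nrow(proteome) == 0L) stop("proteome is empty")
  if (any(proteome$length == 0L)) stop("zero-length protein in proteome")
  hits <- find_motifs(proteome, motif)
  m <- integer(nrow(proteome))
  tab <- table(hits$protein_id)
  m[match(names(tab), proteome$id)] <- as.integer(tab)
  L <- proteome$length
  lambda <- switch(mode,
    per_protein = m / L,
    global_mean_per_protein = mean(m) / L,
    global_per_residue = rep(sum(m) / sum(L), length(L)))
  out <- data.frame(protein_id = proteome$id, L = L, m = m,
                    lambda = lambda, stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  out
}

#' Probability that a protein contains an SCD by chance
#'
#' Probability that a sequence of `L` i.i.d. per-residue Bernoulli(lambda)
#' motif indicators contains at least `k` events within a span of at most
#' `W` residues (span rule as in the scanner: last event position + 1 -
#' first event position + 1 <= W).
#'
#' @param L Protein length (residues).
#' @param lambda Per-residue motif rate; must lie in `[0, 1]`.
#' @param k Minimum number of events (default 3).
#' @param W Maximum span (default 50).
#' @param method One of `"monte_carlo"` (default), `"exact_small"`
#'   (enumeration, `L <= 22`), `"exact_dp"` (exact gap-state dynamic
#'   program, any `L`), `"approximation"` (closed-form scan-statistic
#'   approximation).
#' @param n_sims Number of Monte Carlo replicates (default `1e5`).
#' @param seed Optional seed for the Monte Carlo method.
#' @return A list with elements `p`, `se` (0 for exact methods), `method`,
#'   `L`, `lambda`, `k`, `W`.
#' @examples
#' scd_probability(100, 0.05, method = "exact_dp")
#' @export
scd_probability <- function(L, lambda, k = 3L, W = 50L,
                            method = c("monte_carlo", "approximation",
                                       "exact_small", "exact_dp"),
                            n_sims = 1e5, seed = NULL) {
  method <- match.arg(method)
  L <- as.integer(L); k <- as.integer(k); W <- as.integer(W)
  if (L < 1L) stop("L must be >= 1")
  if (lambda < 0 || lambda > 1) {
    stop("lambda must be a per-residue probability in [0, 1]")
  }
  if (lambda == 0 || 2L * k > L) {
    return(null_prob_result(0, 0, method, L, lambda, k, W))
  }
  p <- switch(method,
    monte_carlo = scd_prob_mc(L, lambda, k, W, n_sims, seed),
    exact_small = c(scd_prob_enum(L, lambda, k, W), 0),
    exact_dp = c(scd_prob_profile_bernoulli(L, lambda, k, W)[L], 0),
    approximation = c(scd_prob_approx(L, lambda, k, W), 0))
  null_prob_result(p[1L], p[2L], method, L, lambda, k, W)
}

null_prob_result <- function(p, se, method, L, lambda, k, W) {
  list(p = p, se = se, method = method, L = L, lambda = lambda,
       k = k, W = W)
}

with_preserved_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

# Monte Carlo: chunked Bernoulli indicator matrix; event = some window of
# width W - 1 holds >= k events.
scd_prob_mc <- function(L, lambda, k, W, n_sims, seed) {
  with_preserved_seed(seed, {
    v <- min(W - 1L, L)
    n_sims <- as.integer(n_sims)
    chunk <- max(1L, min(n_sims, as.integer(4e6 %/% L)))
    hits <- 0
    done <- 0L
    while (done < n_sims) {
      nr <- min(chunk, n_sims - done)
      M <- matrix(stats::rbinom(nr * L, 1L, lambda), nrow = nr)
      # row-wise cumulative counts, then sliding-window differences
      CS <- M
      for (j in seq_len(L)[-1L]) CS[, j] <- CS[, j - 1L] + M[, j]
      event <- CS[, v] >= k
      if (L > v) {
        for (t in 2L:(L - v + 1L)) {
          event <- event | (CS[, t + v - 1L] - CS[, t - 1L] >= k)
        }
      }
      hits <- hits + sum(event)
      done <- done + nr
    }
    phat <- hits / n_sims
    c(phat, sqrt(phat * (1 - phat) / n_sims))
  })
}

# Exhaustive enumeration over indicator vectors, grouped by event count m:
# p = sum_m (#qualifying m-subsets) lambda^m (1-lambda)^(L-m).
scd_prob_enum <- function(L, lambda, k, W) {
  if (L > 22L) stop("exact_small enumeration supports L <= 22")
  counts <- qualifying_subset_counts(L, k, W)
  m <- seq.int(k, L)
  sum(counts * lambda^m * (1 - lambda)^(L - m))
}

# Number of m-subsets of 1..L containing k consecutive members with
# diff <= W - 2, for m = k..L. Shared by enumeration-based tests.
qualifying_subset_counts <- function(L, k, W) {
  vapply(seq.int(k, L), function(m) {
    M <- utils::combn(L, m)
    if (m == k) {
      qual <- M[k, ] - M[1L, ] <= W - 2L
    } else {
      D <- M[k:m, , drop = FALSE] - M[seq_len(m - k + 1L), , drop = FALSE]
      qual <- apply(D, 2L, min) <= W - 2L
    }
    sum(qual)
  }, numeric(1))
}

# Product-type scan approximation: with window v = W - 1,
# P(no cluster) ~ q_v * (q_{v+1}/q_v)^(L - v), q_n = P(Binom(n, lambda) < k).
scd_prob_approx <- function(L, lambda, k, W) {
  v <- W - 1L
  if (L <= v) return(1 - stats::pbinom(k - 1, L, lambda))
  qv <- stats::pbinom(k - 1, v, lambda)
  qv1 <- stats::pbinom(k - 1, v + 1L, lambda)
  p <- 1 - qv * (qv1 / qv)^(L - v)
  min(max(p, 0), 1)
}

# ---- exact gap-state dynamic programs -------------------------------------
#
# State: distances (from the current position) to the k-1 most recent
# events, sorted increasing, capped at a "dead" value beyond which an old
# event can no longer complete a qualifying k-tuple. One forward pass
# yields P(event by length t) for every t up to L_max.

# Enumerate states: strictly increasing tuples of length k-1 over
# live_values, padded with the cap. Returns list(states=matrix rows,
# key=character ids).
gap_states <- function(k, live_values, cap) {
  tuples <- list(rep(cap, k - 1L))
  for (j in seq_len(k - 1L)) {
    if (length(live_values) < j) break
    combs <- utils::combn(live_values, j)
    pad <- matrix(rep(cap, (k - 1L - j) * ncol(combs)),
                  nrow = k - 1L - j, ncol = ncol(combs))
    block <- rbind(combs, pad)
    tuples <- c(tuples, lapply(seq_len(ncol(block)), function(i)
      block[, i]))
  }
  states <- do.call(rbind, tuples)
  list(states = states,
       key = apply(states, 1L, paste, collapse = ","))
}

state_index <- function(states_key, tuple) {
  match(paste(tuple, collapse = ","), states_key)
}

#' Exact SCD probability profile under the Bernoulli model
#'
#' One dynamic-programming pass returning `P(event by length t)` for every
#' `t = 1..L_max`, for per-residue Bernoulli(lambda) motif indicators and
#' the scanner span rule. Exact for the same model as
#' `scd_probability(method = "exact_small")`, but for arbitrary lengths.
#'
#' @param L_max Maximum length.
#' @param lambda Per-residue event rate in `[0, 1]`.
#' @param k Minimum events (>= 2).
#' @param W Maximum span.
#' @return Numeric vector `p` of length `L_max`; `p[t]` is the event
#'   probability for a protein of length `t`. (The short-protein guard
#'   `2k > L => p = 0` is applied by [scd_probability()], not here.)
#' @export
scd_prob_profile_bernoulli <- function(L_max, lambda, k = 3L, W = 50L) {
  k <- as.integer(k); W <- as.integer(W); L_max <- as.integer(L_max)
  if (lambda == 0) return(numeric(L_max))
  cap <- W - 2L                       # distances > W - 3 can never trigger
  live <- seq.int(0L, cap - 1L)
  st <- gap_states(k, live, cap)
  S <- nrow(st$states)
  d_last <- st$states[, k - 1L]

  # no-event transition: increment all distances, cap
  no_to <- vapply(seq_len(S), function(i) {
    state_index(st$key, pmin(st$states[i, ] + 1L, cap))
  }, integer(1))
  # event transition: trigger iff the (k-1)-th most recent event is live
  trig <- d_last < cap
  ev_to <- rep(NA_integer_, S)
  for (i in which(!trig)) {
    d <- st$states[i, ]
    newd <- sort(c(0L, pmin(d[seq_len(k - 2L)] + 1L, cap)))
    if (k == 2L) newd <- 0L
    ev_to[i] <- state_index(st$key, newd)
  }

  Tm <- Matrix::sparseMatrix(
    i = c(no_to, ev_to[!trig]),
    j = c(seq_len(S), which(!trig)),
    x = c(rep(1 - lambda, S), rep(lambda, sum(!trig))),
    dims = c(S, S))
  v <- numeric(S)
  v[state_index(st$key, rep(cap, k - 1L))] <- 1
  p <- numeric(L_max)
  for (t in seq_len(L_max)) {
    v <- as.numeric(Tm %*% v)
    p[t] <- 1 - sum(v)
  }
  pmin(pmax(p, 0), 1)
}

#' Exact SCD probability under an i.i.d. residue-composition null
#'
#' Exact probability that a protein of i.i.d. residues with
#' `P(S or T) = p_st` and `P(Q) = p_q` contains at least `k` S/T-Q motif
#' starts within a span of at most `W` residues. Unlike the Bernoulli
#' indicator idealization this respects the dipeptide footprint: motif
#' starts at adjacent positions are impossible, which lowers clustering
#' probabilities by roughly `k/W` relative to the idealization.
#' Returns the whole length profile from one dynamic-programming pass.
#'
#' @param L_max Maximum length.
#' @param p_st Probability that a residue is S or T.
#' @param p_q Probability that a residue is Q.
#' @param k Minimum motif count (default 3).
#' @param W Maximum span (default 50).
#' @return Numeric vector `p` of length `L_max` (`p[t]` for length `t`).
#' @export
scd_probability_composition <- function(L_max, p_st, p_q, k = 3L,
                                        W = 50L) {
  k <- as.integer(k); W <- as.integer(W); L_max <- as.integer(L_max)
  s <- p_st; q <- p_q
  if (s < 0 || q < 0 || s + q > 1) {
    stop("p_st and p_q must be non-negative with p_st + p_q <= 1")
  }
  if (s == 0 || q == 0) return(numeric(L_max))
  cap <- W - 1L                       # start distances > W - 2 are dead
  live <- seq.int(1L, cap - 1L)
  st <- gap_states(k, live, cap)
  S2 <- nrow(st$states)
  d_last <- st$states[, k - 1L]
  S <- 2L * S2                        # x (previous residue in S/T?)

  idx <- function(tuple, b) state_index(st$key, tuple) + b * S2
  inc <- vapply(seq_len(S2), function(i) {
    state_index(st$key, pmin(st$states[i, ] + 1L, cap))
  }, integer(1))
  trig <- d_last <= W - 2L            # live (k-1)-th distance triggers
  ev_to <- rep(NA_integer_, S2)
  for (i in which(!trig)) {
    d <- st$states[i, ]
    newd <- sort(c(1L, pmin(d[seq_len(k - 2L)] + 1L, cap)))
    if (k == 2L) newd <- 1L
    ev_to[i] <- state_index(st$key, newd)
  }

  src <- integer(0); dst <- integer(0); wt <- numeric(0)
  add <- function(from, to, w) {
    src <<- c(src, from); dst <<- c(dst, to)
    wt <<- c(wt, rep_len(w, length(from)))
  }
  for (b in 0:1) {
    from <- seq_len(S2) + b * S2
    # next residue S/T: no event either way
    add(from, inc + S2, s)
    # next residue other
    add(from, inc, 1 - s - q)
    # next residue Q: event iff previous residue was S/T
    if (b == 0L) {
      add(from, inc, q)
    } else {
      live_src <- which(!trig)
      add(from[live_src], ev_to[live_src], q)
      # triggered mass (trig states) is absorbed: no transition added
    }
  }
  Tm <- Matrix::sparseMatrix(i = dst, j = src, x = wt, dims = c(S, S))
  v <- numeric(S)
  v[idx(rep(cap, k - 1L), 0L)] <- 1
  p <- numeric(L_max)
  for (t in seq_len(L_max)) {
    v <- as.numeric(Tm %*% v)
    p[t] <- 1 - sum(v)
  }
  pmin(pmax(p, 0), 1)
}

#' Expected census size under the null
#'
#' The expected number of SCD-containing proteins is the sum over proteins
#' of the per-protein null probabilities.
#'
#' @param probs Numeric vector of per-protein probabilities `p_i` (or a
#'   list of results from [scd_probability()]).
#' @return A list with `expected_census`, `variance`
#'   (`sum p_i (1 - p_i)`) and `n_proteins`.
#' @export
expected_census <- function(probs) {
  p <- extract_probs(probs)
  list(expected_census = sum(p),
       variance = sum(p * (1 - p)),
       n_proteins = length(p))
}

extract_probs <- function(probs) {
  if (is.list(probs) && !is.data.frame(probs)) {
    p <- vapply(probs, function(x) if (is.list(x)) x$p else x, numeric(1))
  } else if (is.data.frame(probs)) {
    p <- probs$p
  } else {
    p <- as.numeric(probs)
  }
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  p
}

#' Poisson-binomial distribution of the census size
#'
#' Probability mass function of the number of successes among independent
#' Bernoulli trials with heterogeneous probabilities, by iterative
#' convolution.
#'
#' @param probs Per-protein probabilities.
#' @return Numeric vector of length `n + 1`: `P(X = 0), ..., P(X = n)`.
#' @export
poisson_binomial_pmf <- function(probs) {
  p <- extract_probs(probs)
  f <- 1
  for (pi in p) {
    f <- c(f * (1 - pi), 0) + c(0, f * pi)
  }
  f
}

#' Poisson-binomial upper tail
#'
#' `P(X >= x)` for the Poisson-binomial census-size distribution, by exact
#' convolution (`tail_method = "exact_dp"`) or a normal approximation with
#' continuity correction (`"normal_refined"`).
#'
#' @param probs Per-protein probabilities.
#' @param x Observed census size.
#' @param tail_method `"exact_dp"` (default) or `"normal_refined"`.
#' @return The upper-tail probability.
#' @export
poisson_binomial_tail <- function(probs, x,
                                  tail_method = c("exact_dp",
                                                  "normal_refined")) {
  tail_method <- match.arg(tail_method)
  p <- extract_probs(probs)
  x <- as.integer(x)
  if (x <= 0L) return(1)
  if (x > length(p)) return(0)
  if (tail_method == "exact_dp") {
    f <- poisson_binomial_pmf(p)
    tail <- f[(x + 1L):length(f)]
    sum(sort(tail))                  # small terms first for stability
  } else {
    mu <- sum(p)
    sigma <- sqrt(sum(p * (1 - p)))
    if (sigma == 0) return(as.numeric(x <= mu))
    stats::pnorm((x - 0.5 - mu) / sigma, lower.tail = FALSE)
  }
}

#' Significance of the observed census size
#'
#' Tests whether the observed number of SCD-containing proteins exceeds
#' the null expectation, using the exact Poisson-binomial upper tail
#' `P(X >= observed)` and/or its normal refinement.
#'
#' @param probs Per-protein null probabilities.
#' @param observed Observed census size (must not exceed the number of
#'   proteins).
#' @param tail_method `"exact_dp"`, `"normal_refined"` or `"both"`.
#' @return A list of class `null_model_result` with `expected_census`,
#'   `variance`, `observed_census`, `p_value` (named by method) and
#'   `tail_method`.
#' @export
census_significance <- function(probs, observed,
                                tail_method = c("exact_dp",
                                                "normal_refined", "both")) {
  tail_method <- match.arg(tail_method)
  p <- extract_probs(probs)
  observed <- as.integer(observed)
  if (observed > length(p)) {
    stop("observed census exceeds the number of proteins")
  }
  methods <- if (tail_method == "both") {
    c("exact_dp", "normal_refined")
  } else tail_method
  pv <- vapply(methods, function(mth)
    poisson_binomial_tail(p, observed, mth), numeric(1))
  structure(list(expected_census = sum(p),
                 variance = sum(p * (1 - p)),
                 observed_census = observed,
                 p_value = pv,
                 tail_method = tail_method),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("census: observed %d, expected %.2f (sd %.2f) under the null\n",
              x$observed_census, x$expected_census, sqrt(x$variance)))
  for (mth in names(x$p_value)) {
    pv <- x$p_value[[mth]]
    cat(sprintf("  P(X >= observed) [%s] = %s\n", mth,
                if (pv < 1e-15) "< 1e-15" else format(pv, digits = 4)))
  }
  invisible(x)
}

#' Null-model table for a proteome
#'
#' Convenience wrapper: estimates per-protein rates, computes each
#' protein's null probability (deduplicated by `(L, lambda)` class so
#' repeated lengths are computed once), and assembles the expected census
#' and its significance against an observed census size.
#'
#' @param proteome A proteome.
#' @param definition An [scd_definition()].
#' @param lambda_mode Rate estimator, see [estimate_rates()].
#' @param method Probability method, see [scd_probability()]; for
#'   `"exact_dp"` with a shared rate the whole length profile is computed
#'   in one pass.
#' @param n_sims,seed Monte Carlo controls.
#' @param observed Observed census size; defaults to the scanner's census
#'   on the same proteome and definition.
#' @return A list with `table` (per-protein `protein_id`, `L`, `m`,
#'   `lambda`, `p`, `se`), `expected_census`, `observed_census`,
#'   `significance` (a `null_model_result`).
#' @export
null_model <- function(proteome, definition = scd_definition(),
                       lambda_mode = "per_protein",
                       method = "monte_carlo", n_sims = 1e5,
                       seed = NULL, observed = NULL) {
  rates <- estimate_rates(proteome, definition$motif, lambda_mode)
  k <- definition$min_motifs
  W <- definition$max_span
  key <- paste(rates$L, signif(rates$lambda, 12))
  uniq <- !duplicated(key)
  res <- vector("list", sum(uniq))
  names(res) <- key[uniq]
  if (method == "exact_dp" && length(unique(rates$lambda)) == 1L) {
    prof <- scd_prob_profile_bernoulli(max(rates$L), rates$lambda[1L], k, W)
    for (kk in key[uniq]) {
      L <- rates$L[match(kk, key)]
      pv <- if (2L * k > L) 0 else prof[L]
      res[[kk]] <- list(p = pv, se = 0)
    }
  } else {
    for (i in which(uniq)) {
      r <- scd_probability(rates$L[i], rates$lambda[i], k, W,
                           method = method, n_sims = n_sims,
                           seed = if (is.null(seed)) NULL else seed + i)
      res[[key[i]]] <- r
    }
  }
  tab <- rates
  tab$p <- vapply(key, function(kk) res[[kk]]$p, numeric(1))
  tab$se <- vapply(key, function(kk) res[[kk]]$se, numeric(1))
  if (is.null(observed)) {
    observed <- scan_census(proteome, definition)$census_size
  }
  sig <- census_significance(tab$p, observed, "both")
  list(table = tab,
       expected_census = sum(tab$p),
       observed_census = observed,
       significance = sig)
}
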