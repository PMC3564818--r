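# Overlap tests, term enrichment and the census length-distribution
# goodness of fit.
#
# Overlap and enrichment use the hypergeometric distribution with the
# inclusive upper-tail convention P(X >= x). The universe defaults to the
# scanned proteome's id set; ids outside the universe are dropped with a
# logged count.

#' Hypergeometric overlap parameters and tail
#'
#' Core computation on counts: a universe of `N` proteins contains a
#' census of `K`; an external list of `n` is drawn; `x` overlap. The
#' expected overlap is `n * K / N` and the p-value is the inclusive upper
#' tail `P(X >= x)` of Hypergeometric(N, K, n).
#'
#' @param N Universe size.
#' @param K Census size within the universe.
#' @param n External list size within the universe.
#' @param x Observed overlap (optional; `NA` to get the expectation only).
#' @return A list of class `overlap_result` with `N`, `K`, `n`, `x`,
#'   `expected` and `p_value`.
#' @examples
#' hyper_overlap(6831, 436, 28, 7)    # expected 1.787
#' @export
hyper_overlap <- function(N, K, n, x = NA_integer_) {
  if (N <= 0) stop("universe size N must be positive")
  if (K > N || n > N) stop("K and n must not exceed N")
  expected <- n * K / N
  p_value <- if (is.na(x)) {
    NA_real_
  } else if (x <= 0) {
    1
  } else {
    stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  }
  structure(list(N = as.integer(N), K = as.integer(K), n = as.integer(n),
                 x = if (is.na(x)) NA_integer_ else as.integer(x),
                 expected = expected, p_value = p_value),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %s of n=%d in census K=%d (universe N=%d)\n",
              ifelse(is.na(x$x), "?", x$x), x$n, x$K, x$N))
  cat(sprintf("  expected %.3f", x$expected))
  if (!is.na(x$p_value)) {
    cat(sprintf("  P(X >= %d) = %s", x$x, format(x$p_value, digits = 4)))
  }
  cat("\n")
  invisible(x)
}

#' Overlap test between the census and an external protein list
#'
#' @param census_ids Character vector of census protein ids.
#' @param external_ids Character vector of external list ids.
#' @param universe_ids Character vector defining the universe. Ids of the
#'   census or external list outside the universe are dropped (their count
#'   is reported in the `dropped` attribute).
#' @return An `overlap_result` (see [hyper_overlap()]).
#' @export
overlap_test <- function(census_ids, external_ids, universe_ids) {
  universe_ids <- unique(universe_ids)
  if (length(universe_ids) == 0L) stop("universe is empty")
  census_ids <- unique(census_ids)
  external_ids <- unique(external_ids)
  dropped <- c(census = sum(!(census_ids %in% universe_ids)),
               external = sum(!(external_ids %in% universe_ids)))
  census_ids <- intersect(census_ids, universe_ids)
  external_ids <- intersect(external_ids, universe_ids)
  if (any(dropped > 0L)) {
    message(sum(dropped), " id(s) outside the universe dropped (census ",
            dropped[["census"]], ", external ", dropped[["external"]], ")")
  }
  out <- hyper_overlap(length(universe_ids), length(census_ids),
                       length(external_ids),
                       length(intersect(census_ids, external_ids)))
  attr(out, "dropped") <- dropped
  out
}

#' Term over-representation in the census
#'
#' One hypergeometric upper-tail test per annotation term with at least
#' `min_term_size` universe proteins. Bonferroni correction uses the
#' number of tested terms; Benjamini-Hochberg FDR is computed over the
#' same tested terms. Rows are ordered by raw p-value.
#'
#' @param census_ids Census protein ids.
#' @param annotations An `annotation_map` from [read_annotations()] or
#'   [generate_annotations()].
#' @param universe_ids Universe protein ids (annotations are restricted to
#'   the universe).
#' @param min_term_size Minimum number of universe proteins per tested
#'   term (default 2).
#' @param p_cutoff Bonferroni significance cutoff for the `significant`
#'   flag (default 0.01).
#' @return A `data.frame` with columns `term_id`, `term_name`, `x`, `K_t`,
#'   `n`, `N`, `expected`, `p_value`, `p_bonferroni`, `q_bh`,
#'   `significant`, sorted by `p_value`.
#' @export
term_enrichment <- function(census_ids, annotations, universe_ids,
                            min_term_size = 2L, p_cutoff = 0.01) {
  universe_ids <- unique(universe_ids)
  census_ids <- intersect(unique(census_ids), universe_ids)
  N <- length(universe_ids)
  n <- length(census_ids)
  sets <- lapply(annotations$terms, intersect, universe_ids)
  K_t <- lengths(sets)
  keep <- K_t >= min_term_size
  sets <- sets[keep]
  K_t <- K_t[keep]
  if (length(sets) == 0L) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      x = integer(0), K_t = integer(0), n = integer(0),
                      N = integer(0), expected = numeric(0),
                      p_value = numeric(0), p_bonferroni = numeric(0),
                      q_bh = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  x <- vapply(sets, function(s) length(intersect(s, census_ids)),
              integer(1))
  p <- ifelse(x <= 0L, 1,
              stats::phyper(x - 1L, K_t, N - K_t, n, lower.tail = FALSE))
  out <- data.frame(term_id = names(sets),
                    term_name = unname(annotations$term_names[names(sets)]),
                    x = x, K_t = K_t, n = n, N = N,
                    expected = n * K_t / N,
                    p_value = p,
                    p_bonferroni = stats::p.adjust(p, "bonferroni"),
                    q_bh = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_bonferroni <= p_cutoff
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Log-normal goodness of fit for protein lengths
#'
#' Fits a log-normal distribution to lengths by maximum likelihood
#' (reported as `mu_hat`, `sigma_hat`), forms equal-probability bins under
#' the fitted distribution, merges adjacent bins until every expected
#' count is at least 5, and computes Pearson's chi-square with
#' `df = bins - 1 - 2`. To keep the chi-square reference distribution
#' exact (Chernoff-Lehmann: parameters estimated from raw data make the
#' binned statistic stochastically larger than chi-square with
#' `bins - 3` df), the parameters entering the statistic are re-fit by
#' grouped (multinomial) maximum likelihood on the fixed bin edges.
#'
#' @param lengths Positive lengths (at least 30).
#' @param n_bins Initial number of equal-probability bins (default 20).
#' @return A list of class `gof_result` with `mu_hat`, `sigma_hat`
#'   (raw-data MLE), `mu_grouped`, `sigma_grouped`, `n_bins` (after
#'   merging), `chi2`, `df`, `p_value`, `observed`, `expected`.
#' @export
lognormal_gof <- function(lengths, n_bins = 20L) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 30L) stop("need at least 30 lengths")
  if (any(lengths < 1)) stop("lengths must be >= 1")
  x <- log(lengths)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))    # MLE (denominator n)
  if (sigma == 0) stop("all lengths identical: sigma = 0")

  n <- length(lengths)
  n_bins <- as.integer(n_bins)
  edges <- stats::qnorm(seq_len(n_bins - 1L) / n_bins, mu, sigma)
  breaks <- c(-Inf, edges, Inf)

  # grouped (multinomial) MLE on the fixed edges
  nll <- function(par) {
    pr <- diff(stats::pnorm(breaks, par[1L], exp(par[2L])))
    pr <- pmax(pr, 1e-12)
    obs <- tabulate(findInterval(x, breaks), nbins = n_bins)
    -sum(obs * log(pr))
  }
  fit <- stats::optim(c(mu, log(sigma)), nll, method = "BFGS")
  mu_g <- fit$par[1L]
  sigma_g <- exp(fit$par[2L])

  obs <- tabulate(findInterval(x, breaks), nbins = n_bins)
  expd <- n * diff(stats::pnorm(breaks, mu_g, sigma_g))
  # merge adjacent bins until every expected count >= 5
  while (length(expd) > 4L && min(expd) < 5) {
    i <- which.min(expd)
    j <- if (i == 1L) 2L else if (i == length(expd)) i - 1L
         else if (expd[i - 1L] <= expd[i + 1L]) i - 1L else i + 1L
    lo <- min(i, j); hi <- max(i, j)
    obs <- c(obs[seq_len(lo - 1L)], obs[lo] + obs[hi],
             obs[-seq_len(hi)])
    expd <- c(expd[seq_len(lo - 1L)], expd[lo] + expd[hi],
              expd[-seq_len(hi)])
  }
  df <- length(obs) - 3L
  if (df < 1L) stop("too few bins after merging (df < 1)")
  chi2 <- sum((obs - expd)^2 / expd)
  structure(list(mu_hat = mu, sigma_hat = sigma,
                 mu_grouped = mu_g, sigma_grouped = sigma_g,
                 n_bins = length(obs), chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 observed = obs, expected = expd),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("log-normal fit: mu = %.3f, sigma = %.3f (n bins = %d)\n",
              x$mu_hat, x$sigma_hat, x$n_bins))
  cat(sprintf("Pearson chi2 = %.2f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}
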