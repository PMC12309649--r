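# Resampling null models for group-level representation bias. The observed
# set of below-threshold maps is compared with repeated uniform draws
# (without replacement) of the same number of maps from the full map set;
# per-group counts across draws form the null distribution. Effect size is
# a signed percent difference, and an exact binomial tail probability
# complements the resampling interval.

#' Null distributions of per-group counts under random sampling
#'
#' Draws `S` samples of `m` maps uniformly *without replacement* from the
#' full map set and tabulates how many fall in each group. The mean count
#' for a group of size `N_g` converges to the hypergeometric expectation
#' `m * N_g / N`.
#'
#' @param labels Factor (or coercible) of group labels, one per map; `NA`
#'   labels stay in the sampling frame but count toward no group.
#' @param m Sample size: the observed number of below-threshold maps.
#' @param S Number of samples (default 1000).
#' @param seed Optional integer seed (uses and restores a private RNG
#'   stream).
#' @return Integer matrix `S x nlevels(labels)` of per-sample counts.
#' @export
draw_null_counts <- function(labels, m, S = 1000L, seed = NULL) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (m > n) stop("sample size `m` exceeds the number of maps", call. = FALSE)
  if (S < 1L) stop("`S` must be at least 1", call. = FALSE)
  code <- as.integer(labels)
  nlev <- nlevels(labels)
  with_seed(seed, {
    out <- matrix(0L, S, nlev, dimnames = list(NULL, levels(labels)))
    for (s in seq_len(S)) {
      idx <- sample.int(n, m)
      cd <- code[idx]
      out[s, ] <- tabulate(cd[!is.na(cd)], nbins = nlev)
    }
    out
  })
}

#' Signed percent difference between expectation and observation
#'
#' `100 * (null_mean - observed) / n_g`: negative when the group holds
#' *more* under-represented maps than expected by chance (the group is
#' worse represented), positive when fewer (better represented).
#'
#' @param observed Observed below-threshold count in the group.
#' @param null_mean Mean count across null samples.
#' @param n_g Total maps in the group.
#' @export
percent_difference <- function(observed, null_mean, n_g) {
  stopifnot(all(n_g > 0))
  100 * (null_mean - observed) / n_g
}

#' Exact binomial tail probability for a group's count
#'
#' With `X ~ Binomial(n_g, p)` and `p = m / N` (the marginal chance of any
#' one map landing in a null sample), the two-sided probability is
#' `min(1, 2 * min(P[X <= obs], P[X >= obs]))`, computed from exact tail
#' sums (no normal approximation).
#'
#' @param observed Observed count.
#' @param n_g Group size.
#' @param p Success probability in (0, 1).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @export
binom_tail_p <- function(observed, n_g, p,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!(p > 0 && p < 1)) stop("`p` must lie strictly in (0, 1)", call. = FALSE)
  lower <- stats::pbinom(observed, n_g, p)
  upper <- stats::pbinom(observed - 1, n_g, p, lower.tail = FALSE)
  switch(alternative,
         less = lower,
         greater = upper,
         two.sided = pmin(1, 2 * pmin(lower, upper)))
}

#' Group-level bias test against a resampling null
#'
#' For one grouping variable (order, family, single-important-habitat code,
#' Red List category), compares the observed number of below-threshold maps
#' per group with the null distribution from [draw_null_counts()]. A group
#' is significant when the central 95% interval of the per-sample
#' differences `100 * (count_s - observed) / N_g` excludes 0; the binomial
#' (or optionally hypergeometric) tail probability is reported alongside.
#' Groups smaller than `small_floor` maps are kept but flagged
#' `small_sample`, echoing how thin groups preclude a meaningful
#' assessment.
#'
#' @param labels Group label per map (`NA` = map belongs to no group but
#'   stays in the sampling frame).
#' @param flagged Logical per map: below the representation threshold?
#' @param S Number of null samples (default 1000).
#' @param seed Optional integer seed, recorded in the output.
#' @param small_floor Minimum group size before the small-sample flag
#'   (default 10).
#' @param method `"binomial"` (as stated for the analysis) or
#'   `"hypergeometric"` (exact for sampling without replacement).
#' @param alternative Tail(s) for the probability; default two-sided.
#' @return Data frame of class `null_model_result`, one row per group:
#'   `group`, `n_g`, `observed`, `null_mean`, `null_q2.5`, `null_q97.5`,
#'   `pct_difference`, `p_value`, `significant`, `small_sample`; attributes
#'   `S`, `m`, `seed`, `method`.
#' @export
null_model_bias <- function(labels, flagged, S = 1000L, seed = NULL,
                            small_floor = 10L,
                            method = c("binomial", "hypergeometric"),
                            alternative = "two.sided") {
  method <- match.arg(method)
  labels <- as.factor(labels)
  stopifnot(length(labels) == length(flagged))
  n <- length(labels)
  m <- sum(flagged)
  counts <- draw_null_counts(labels, m, S = S, seed = seed)
  lev <- levels(labels)
  n_g <- as.integer(table(labels)[lev])
  obs <- as.integer(table(labels[flagged])[lev])
  obs[is.na(obs)] <- 0L

  keep <- n_g > 0
  rows <- lapply(which(keep), function(k) {
    d <- 100 * (counts[, k] - obs[k]) / n_g[k]
    q <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
    p <- if (method == "binomial") {
      binom_tail_p(obs[k], n_g[k], m / n, alternative)
    } else {
      hyper_tail_p(obs[k], n_g[k], n, m, alternative)
    }
    data.frame(
      group = lev[k], n_g = n_g[k], observed = obs[k],
      null_mean = mean(counts[, k]),
      null_q2.5 = stats::quantile(counts[, k], 0.025, names = FALSE),
      null_q97.5 = stats::quantile(counts[, k], 0.975, names = FALSE),
      pct_difference = percent_difference(obs[k], mean(counts[, k]), n_g[k]),
      p_value = p,
      significant = q[1] > 0 || q[2] < 0,
      small_sample = n_g[k] < small_floor,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("null_model_result", "data.frame"),
            S = S, m = m, seed = seed, method = method)
}

# exact two-sided hypergeometric tail (sampling without replacement)
hyper_tail_p <- function(observed, n_g, n, m, alternative = "two.sided") {
  lower <- stats::phyper(observed, n_g, n - n_g, m)
  upper <- stats::phyper(observed - 1, n_g, n - n_g, m, lower.tail = FALSE)
  switch(alternative,
         less = lower,
         greater = upper,
         two.sided = pmin(1, 2 * pmin(lower, upper)))
}
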