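# The gamma statistic, its asymptotic and Monte Carlo (MCCR) tests,
# lineage-through-time curves, posterior-sample summaries, and the small
# age arithmetic used around them.

#' The gamma statistic of branching-time concentration
#'
#' Summarises where a chronogram's nodes sit in time:
#' `gamma = [ mean(T_2..T_{n-1}) - T/2 ] / [ T * sqrt(1/(12(n-2))) ]`
#' with `T_i = sum_{k=2..i} k g_k` and `T = T_n`.  Under a complete-sampling
#' pure-birth process the `k g_k` are iid exponentials, so `T_i / T` behave
#' as uniform order statistics and gamma has mean 0 and standard deviation 1
#' (asymptotically standard normal).  Negative values indicate branching
#' concentrated toward the root, i.e. a slowdown.
#'
#' @param x A chronogram (`phylo`), a `branching_times` object, or a numeric
#'   vector of node ages.
#' @return An object of class `"gamma_test"`: list with `gamma`,
#'   `p_one_tailed` (lower tail of N(0,1)) and `n`.
#' @examples
#' gamma_statistic(read_chronogram(text = "((A:1,B:1):1,C:2);"))
#' @export
gamma_statistic <- function(x) {
  bt <- branching_times(x)
  n <- bt$n
  T <- bt$total
  if (T <= 0) stop("degenerate chronogram: all internode intervals are zero")
  g <- (mean(bt$cumulative[seq_len(n - 2L)]) - T / 2) /
    (T * sqrt(1 / (12 * (n - 2L))))
  structure(list(gamma = g, p_one_tailed = stats::pnorm(g), n = n),
            class = "gamma_test")
}

#' @export
print.gamma_test <- function(x, ...) {
  cat(sprintf("gamma = %.4f (n = %d tips), one-tailed p = %.4g\n",
              x$gamma, x$n, x$p_one_tailed))
  invisible(x)
}

#' One-tailed critical value of the asymptotic gamma test
#'
#' @param alpha Type I error probability (one tailed).
#' @return The N(0,1) lower-tail quantile; `-1.645` at `alpha = 0.05`.
#' @export
gamma_crit <- function(alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stats::qnorm(alpha)
}

#' Reject constant-rate diversification on the asymptotic gamma null?
#'
#' @param gamma Observed gamma value.
#' @param alpha One-tailed type I error probability.
#' @return `TRUE` iff `gamma < qnorm(alpha)`.
#' @export
gamma_reject_constant <- function(gamma, alpha = 0.05) {
  gamma < gamma_crit(alpha)
}

#' Monte Carlo constant-rates (MCCR) test for incompletely sampled clades
#'
#' Incomplete sampling biases gamma negative, so the `-1.645` critical value
#' is anti-conservative.  The MCCR test simulates `reps` pure-birth trees of
#' the hypothetical full clade size (known richness plus an
#' `extra_fraction` allowance for unknown diversity), randomly prunes each
#' down to the number of sampled terminals, and takes the empirical
#' `alpha`-quantile of the null gamma sample as the corrected critical
#' value.
#'
#' @param gamma_obs Observed gamma (scalar, or anything accepted by
#'   [gamma_statistic()]).
#' @param n_sampled Number of terminals in the analysed chronogram.
#' @param known_total Known species richness of the clade.
#' @param reps Null replicates (default 5000).
#' @param alpha One-tailed level for the critical value.
#' @param extra_fraction Assumed unknown extra diversity (default 0.10).
#' @param seed Integer base seed for the null simulation.
#' @return Class `"mccr_test"`: `gamma_obs`, `critical_value` (the
#'   linear-interpolation `alpha`-quantile of the null), `p`
#'   (`(1 + #{null <= gamma_obs}) / (reps + 1)`), `alpha`, `reps`,
#'   `null_sample`, `n_sampled`, `n_full`.
#' @export
mccr_test <- function(gamma_obs, n_sampled, known_total, reps = 5000,
                      alpha = 0.05, extra_fraction = 0.10, seed = 1) {
  if (!is.numeric(gamma_obs) || length(gamma_obs) != 1L)
    gamma_obs <- gamma_statistic(gamma_obs)$gamma
  if (n_sampled < 3L) stop("n_sampled must be at least 3")
  if (known_total < n_sampled) stop("known_total must be >= n_sampled")
  n_full <- full_clade_size(known_total, extra_fraction)
  null_trees <- simulate_pruned_null(n_sampled, n_full, reps, seed = seed)
  null_gamma <- vapply(null_trees, function(tr)
    gamma_statistic(.bt_from_ages(as.numeric(ape::branching.times(tr))))$gamma,
    numeric(1L))
  structure(list(
    gamma_obs = gamma_obs,
    critical_value = unname(stats::quantile(null_gamma, alpha, type = 7)),
    p = (1 + sum(null_gamma <= gamma_obs)) / (reps + 1),
    alpha = alpha, reps = reps, null_sample = null_gamma,
    n_sampled = n_sampled, n_full = n_full),
    class = "mccr_test")
}

#' @export
print.mccr_test <- function(x, ...) {
  cat(sprintf(paste0(
    "MCCR test: %d of %d tips sampled (full size incl. unknown diversity)\n",
    "  gamma = %.4f, corrected critical value (alpha = %.3g) = %.4f\n",
    "  Monte Carlo p = %.4g (%d replicates)\n"),
    x$n_sampled, x$n_full, x$gamma_obs, x$alpha, x$critical_value,
    x$p, x$reps))
  invisible(x)
}

#' Lineage-through-time curve
#'
#' The step curve of reconstructed lineage count against age before
#' present, from `(crown age, 2)` down to `(0, n)`.  Under constant-rate
#' pure birth, log counts are linear in time.
#'
#' @param phy A chronogram, or a `multiPhylo` sample (then a `tree` index
#'   column is added).
#' @return A data frame with columns `age` and `lineages` (and `tree` for
#'   samples).
#' @examples
#' ltt(read_chronogram(text = "((A:1,B:1):1,C:2);"))
#' @export
ltt <- function(phy) {
  if (inherits(phy, "multiPhylo")) {
    out <- lapply(seq_along(phy), function(i) cbind(tree = i, ltt(phy[[i]])))
    return(do.call(rbind, out))
  }
  bt <- branching_times(phy)
  data.frame(age = c(bt$ages, 0),
             lineages = c(2:bt$n, bt$n))
}

#' Write an LTT curve as CSV
#'
#' @param x Output of [ltt()] (or anything [ltt()] accepts).
#' @param file Output path.
#' @export
write_ltt <- function(x, file) {
  if (!is.data.frame(x)) x <- ltt(x)
  utils::write.csv(x, file, row.names = FALSE)
}

#' Gamma over a sample of trees
#'
#' Computes gamma for every tree of a sample (e.g. posterior draws) and
#' summarises the spread as a measure of uncertainty.
#'
#' @param trees A `multiPhylo` or list of chronograms.
#' @return Class `"gamma_sample"`: `gamma` (per-tree values), `mean`, `sd`
#'   (0 with a warning for a single tree), and the 2.5/97.5 percentiles.
#' @export
gamma_over_sample <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("empty tree sample")
  g <- vapply(trees, function(tr) gamma_statistic(tr)$gamma, numeric(1L))
  s <- if (length(g) == 1L) {
    warning("single-tree sample: sd reported as 0")
    0
  } else stats::sd(g)
  structure(list(gamma = g, mean = mean(g), sd = s,
                 q025 = unname(stats::quantile(g, 0.025)),
                 q975 = unname(stats::quantile(g, 0.975))),
            class = "gamma_sample")
}

#' @export
print.gamma_sample <- function(x, ...) {
  cat(sprintf("gamma over %d trees: mean %.3f, sd %.3f, 95%% range [%.3f, %.3f]\n",
              length(x$gamma), x$mean, x$sd, x$q025, x$q975))
  invisible(x)
}

#' Pearson correlation between clade age and clade size
#'
#' @param age,size Numeric vectors (>= 3 pairs), or `age` may be a
#'   two-column data frame.
#' @return List with `pairs` (data frame) and `r`.
#' @examples
#' cl <- nc_clades()
#' pearson_age_size(cl$age_ma, cl$n_sampled)$r
#' @export
pearson_age_size <- function(age, size = NULL) {
  if (is.data.frame(age)) { size <- age[[2L]]; age <- age[[1L]] }
  if (length(age) != length(size) || length(age) < 3L)
    stop("need at least 3 (age, size) pairs")
  if (stats::var(age) == 0 || stats::var(size) == 0)
    stop("undefined correlation: zero variance")
  list(pairs = data.frame(age = age, size = size),
       r = stats::cor(age, size))
}

#' Clade age from COI pairwise divergence
#'
#' Linear molecular-clock arithmetic: age in Ma is the percent pairwise
#' divergence divided by the clock rate (default 2.3 percent per million
#' years, the standard arthropod COI rate).
#'
#' @param percent_divergence Pairwise divergence in percent (>= 0).
#' @param rate Divergence accumulation rate, percent per Ma (> 0).
#' @return Age in Ma.
#' @examples
#' age_from_divergence(2.3)  # 1 Ma
#' @export
age_from_divergence <- function(percent_divergence, rate = 2.3) {
  if (rate <= 0) stop("rate must be positive")
  if (any(percent_divergence < 0)) stop("divergence must be non-negative")
  percent_divergence / rate
}
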