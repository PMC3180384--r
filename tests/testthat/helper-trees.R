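# Shared fixtures and independent oracles, all built in code.

tree3 <- function() read_chronogram(text = "((A:1,B:1):1,C:2);")

# balanced 4-tip tree: cherries at age 0.5, root at 1
tree4_balanced <- function()
  read_chronogram(text = "((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")

# branching_times object straight from interval durations g_2..g_n
bt_from_intervals <- function(g) {
  n <- length(g) + 1L
  ages <- rev(cumsum(rev(g)))           # age at the start of interval k
  branching_times(ages)
}

# independent gamma oracle: direct transcription of the defining formula,
# computed from a tree via ape only
gamma_oracle <- function(phy) ape::gammaStat(phy)

# Dense-enumeration oracle for the DDL estimator: the profile likelihood
# over K (rate profiled out in closed form) diverges on the
# non-identifiable ridge where the weighted exposure E(K) tends to 0+, so
# the estimand is the best interior local maximum of the profile.  This
# enumerates it by brute force on a two-stage grid (coarse log-spaced,
# then linear at <= 1e-3 resolution around the winner), independently of
# the package's golden-section refinement.
ddl_profile_oracle <- function(bt) {
  n <- bt$n; k <- 2:n; g <- bt$intervals
  prof <- function(K) {
    E <- sum(k * (1 - k / K) * g)
    if (E <= 0) return(-Inf)
    model_loglik(bt, "ddl", list(r1 = (n - 2) / E, K = K))
  }
  best_interior <- function(Ks) {
    ll <- vapply(Ks, prof, numeric(1))
    m <- length(ll)
    ok <- which(is.finite(ll[2:(m - 1)]) & is.finite(ll[1:(m - 2)]) &
                is.finite(ll[3:m]) & ll[2:(m - 1)] >= ll[1:(m - 2)] &
                ll[2:(m - 1)] >= ll[3:m]) + 1
    if (!length(ok)) return(NULL)
    i <- ok[which.max(ll[ok])]
    list(K = Ks[i], loglik = ll[i])
  }
  coarse <- best_interior((n - 1) + exp(seq(-14, 20, length.out = 20001)))
  yule_ll <- model_loglik(bt, "yule1",
                          list(lambda = (n - 2) / bt$total))
  if (is.null(coarse)) return(list(K = Inf, loglik = yule_ll))
  fine <- best_interior(seq(max(n - 1 + 1e-9, coarse$K - 0.5),
                            coarse$K + 0.5, by = 1e-3))
  out <- if (is.null(fine)) coarse else fine
  if (yule_ll >= out$loglik) list(K = Inf, loglik = yule_ll) else out
}

# iterated dense grid search, the optimiser-independent fitting oracle.
# Refines a full grid around the incumbent until spacing <= final_step.
grid_fit_oracle <- function(bt, ll_fun, lower, upper, final_step = 1e-3,
                            n_grid = 41L) {
  stopifnot(length(lower) == 2L, length(upper) == 2L)
  lo <- lower; hi <- upper
  best <- c(NA, NA); bestll <- -Inf
  repeat {
    g1 <- seq(lo[1L], hi[1L], length.out = n_grid)
    g2 <- seq(lo[2L], hi[2L], length.out = n_grid)
    for (a in g1) for (b in g2) {
      ll <- ll_fun(bt, a, b)
      if (ll > bestll) { bestll <- ll; best <- c(a, b) }
    }
    step <- c(g1[2L] - g1[1L], g2[2L] - g2[1L])
    if (all(step <= final_step)) break
    lo <- pmax(lower, best - 2 * step)
    hi <- pmin(upper, best + 2 * step)
  }
  list(par = best, loglik = bestll)
}
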