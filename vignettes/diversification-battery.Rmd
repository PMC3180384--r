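---
title: "Detecting diversification slowdowns: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diversification slowdowns: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divbattery)
```

## The question and the data

Island radiations pose a recurring question: did lineages accumulate at a
steady rate over long periods (a "museum" of gradually acquired
diversity), or did diversification start fast and slow down as ecological
space filled?  The data for answering it are *chronograms* — rooted,
binary, ultrametric trees whose branch lengths are proportional to time —
together with two per-clade constants: how many terminals were sampled,
and how many species the clade is known to contain.  All analyses in this
package consume only the vector of branching times (node ages before
present), which is the sufficient statistic for every model fitted here;
trees are routinely rescaled to unit root depth, to which every test
statistic and AIC difference below is invariant.

## The gamma statistic and its null

For a chronogram with $n$ tips, let $g_k$ be the duration during which
exactly $k$ reconstructed lineages exist, and
$T_i = \sum_{k=2}^{i} k\,g_k$, with $T = T_n$.  Then

$$\gamma \;=\; \frac{\tfrac{1}{n-2}\sum_{i=2}^{n-1} T_i \;-\; T/2}
                    {T\sqrt{1/(12(n-2))}}.$$

Under constant-rate pure birth the $k\,g_k$ are iid exponential, so
$(T_2,\dots,T_{n-1})/T$ behave as uniform order statistics: $\gamma$ has
mean 0 and standard deviation 1 at *every* $n$, and is asymptotically
standard normal.  Nodes concentrated toward the root — the signature of a
slowdown — push $\gamma$ negative; the one-tailed constancy test rejects
at $\gamma < \Phi^{-1}(\alpha)$, i.e. $-1.645$ at $\alpha = 0.05$.

## Incomplete sampling and the MCCR correction

Random omission of extant taxa deletes recent nodes preferentially and so
biases $\gamma$ negative.  `mccr_test()` recalibrates the critical value
by simulation: pure-birth trees are grown to the clade's *hypothetical
full size* — the known richness inflated by a 10% allowance for unknown
species, rounded half away from zero (`full_clade_size()`) — randomly
pruned to the sampled size, and the empirical $\alpha$-quantile
(linear-interpolation definition) of the null $\gamma$ sample becomes the
corrected critical value.  Monte Carlo p-values use the add-one convention
$(1+b)/(\text{reps}+1)$, so a reported $p$ can never be exactly zero and
its floor is $1/(\text{reps}+1)$.

## The simulator is part of the statistics

The pure-birth family simulator draws, while $k$ lineages exist, a
waiting time $\sim \text{Exponential}(k\lambda_k)$, attaches the new
lineage to a uniformly chosen extant lineage, and cuts the tree at the
instant the $(n{+}1)$-th event *would* begin — the final interval is a
full $\text{Exponential}(n\lambda_n)$ draw, justified by memorylessness
(the process observed at an arbitrary moment while it has $n$ species).
This choice is load-bearing.  Truncating instead at the $n$-th speciation
event, as some older simulation tools did, leaves a zero-length final
interval and shifts the null $\gamma$ mean to $+\sqrt{3/(n-2)}$ (about
$+0.61$ at $n = 10$), which in turn moves MCCR critical values markedly
toward zero at small clade sizes.  Our construction agrees
distributionally with `ape::rphylo` and `phytools::pbtree`, and keeps the
complete-sampling null at mean 0, sd 1; published critical values
computed with event-truncating simulators can therefore differ
substantially from this package's output for clades of ten or so species,
and the difference reflects the simulators, not Monte Carlo error.

Per-lineage rates implement each model: constant $\lambda$ (`yule`),
$r_1(1-k/K)$ (`ddl`, requiring $K > n$ so every interval has positive
rate), $r_1 k^{-x}$ (`ddx`), and an epoch switch from $r_1$ to $r_2$
(`yule2`).  Because total depth is unknown while simulating forward, the
`yule2` shift time is specified forward from the crown during simulation,
whereas the *fitted* shift `st` is an age before present.  Constant
birth–death trees are grown forward with extinction and accepted once
$n$ lineages are simultaneously alive (retry on extinction, capped at
$10^5$ attempts), then cut after an $\text{Exponential}(n(\lambda+\mu))$
interval and pruned of extinct lineages.

Replicate $i$ of any null sample uses seed $\texttt{seed}+i$, so
replicate sets are reproducible and insensitive to evaluation order, and
all seeded draws restore the caller's RNG state.

## Likelihoods

For the pure-birth family the log-likelihood is

$$\mathcal{L} \;=\; \sum_{k=2}^{n-1}\ln(k\lambda_k)\;-\;\sum_{k=2}^{n} k\lambda_k g_k ,$$

with the combinatorial $\sum\ln k$ constant included throughout (it
cancels from every likelihood ratio and AIC difference, so cross-package
comparisons of *absolute* likelihoods must account for convention).  A
rate that is non-positive at an observed branching yields $-\infty$
rather than an error, so optimisers may probe boundaries.  The constant
birth–death model uses the reconstructed-process likelihood in the
$(r, a) = (\lambda-\mu, \mu/\lambda)$ parameterisation, conditioned on
the crown age with both crown lineages surviving; at $a = 0$ it reduces
*exactly* to the Yule expression, and its deviance matches
`ape::birthdeath` to machine precision (a test enforces this).

The time-varying extensions decay in forward time $t$ from the crown:
`spvar` has $\lambda(t) = \lambda_0 e^{-kt}$ with constant $\mu_0$;
`exvar` has constant $\lambda_0$ with $\mu(t) = \mu_0(1-e^{-zt})$ rising
toward the present; `bothvar` combines them.  Writing $\rho(x)$ for the
cumulative net decline and $P(x)$ for the survival probability of a
lineage of age $x$, the likelihood generalises the constant-rate form
term by term; $\rho$ uses closed-form rate integrals and $P$ a single
adaptive quadrature per node age (absolute tolerance $10^{-8}$).  Setting
the decay parameters to zero recovers the constant birth–death likelihood
exactly (`spvar` with $k=0$) or the Yule likelihood (`exvar`/`bothvar`
with $z=0$, which switches extinction off entirely).

## Fitting and its one genuinely delicate point

The Yule rate has the closed form $\hat\lambda = (n-2)/T$.  The two-rate
Yule is profiled over the observed branching ages (excluding the root and
the most recent), with closed-form per-epoch rates = events/exposure; an
interval straddling the shift contributes exposure to both epochs, and
the event at the shift age itself belongs to the older epoch.  `bd`,
`ddx` and the time-varying models use Nelder–Mead on log/logit-transformed
parameters with quasi-random restarts (default 10) seeded from a hash of
the branching times, plus explicit evaluation of every nested boundary
(pure birth inside `bd`, the no-decay limits of the extensions), so a
fitted nested model never scores below the model it contains.

`ddl` needs care.  Profiling the rate out in closed form,
$\hat r_1(K) = (n-2)/E(K)$ with exposure $E(K) = \sum_k k(1-k/K)g_k$,
leaves a one-dimensional profile over $K \in (n-1, \infty)$.  We admit
$K$ between $n-1$ and $n$ — the final interval's rate is then negative
and its survival term is evaluated as-is, which is how fitted ceilings
slightly below the tip count arise — but on trees with long final
intervals $E(K)$ crosses zero inside the feasible range, and as
$E(K)\to 0^+$ the profile diverges to $+\infty$ along a ridge on which
$\hat r_1$ runs away and nothing is identified.  No maximum-likelihood
estimate exists there; bounded local searches started at sensible values
never report that ridge.  The estimator is therefore defined as the best
*interior stationary maximum* of the profile (dense log-grid scan over
513 points, golden-section refinement, Yule as the $K\to\infty$
fallback), and the test suite checks it against an independent
dense-enumeration oracle at $10^{-3}$ resolution.

## Model selection and its null

The headline contrast is $\Delta\mathrm{AIC} = \mathrm{AIC}_{\text{best
rate-constant}} - \mathrm{AIC}_{\text{best rate-variable}}$, with
rate-constant = \{`yule1`, `bd`\} and rate-variable = \{`yule2`, `ddl`,
`ddx`\}; positive values favour rate variation.  The time-varying
extensions are reported alongside but excluded from this contrast.
Because the sets are not nested in each other, $\Delta\mathrm{AIC}$ has
no analytic null; `delta_aic_p()` simulates it: pure-birth trees at the
hypothetical full clade size, randomly pruned, rescaled, fed through the
same model selection, with the add-one p-value on
$\#\{\Delta\mathrm{AIC}_{\text{null}} \ge \Delta\mathrm{AIC}_{\text{obs}}\}$.
Non-converged replicates are redrawn (logged, capped at twice the
requested count).

## Synthetic fixtures, and what passing tests do not show

`make_fixture_suite()` ships nine synthetic clades mirroring the study
system's sampling fractions and ages (e.g. 11 of 13 known harvestman
species at 49 Ma; 75 of 80 caddisflies at 21.9 Ma), generated under
diversity-dependent speciation with ceiling $K$ = the clade's
hypothetical full size and $r_1 = 5$ (within the range that
diversity-dependent fits to such radiations typically report), except one
pure-birth clade mirroring the single constant-rate case.  These
fixtures exercise the full pipeline deterministically; they are labelled
synthetic and are *not* reconstructions of the real phylogenies.  The
generator draws from exactly the model families the battery fits, so
green tests demonstrate internal consistency, calibration and parameter
recovery — not robustness to rate heterogeneity across lineages,
ultrametrization error, or non-random taxon sampling, none of which the
generator emulates.

## Numerical conventions, problem sizes, limitations

Ultrametricity is enforced to a relative tolerance of $10^{-6}$ (typical
rounding noise of numerical ultrametrization), after which tips are
snapped to exactly contemporaneous; larger deviations are errors, never
warnings.  Tied node ages (zero-length intervals) are legal everywhere;
no likelihood divides by $g_k$.  Quantiles are the linear-interpolation
type; at 5000 replicates the choice moves MCCR critical values by under
0.01.  The test suite uses 2000 replicates at $n = 50$ for the $\gamma$
null, 5000-replicate MCCR nulls, 200 replicates for diversity-dependence
recovery ($r_1 = 5$, $K = 40$, $n = 38$), and 199/200-replicate
$\Delta\mathrm{AIC}$ size checks at $n = 40$ — sizes at which Monte Carlo
error is comfortably inside each asserted band on a single CPU.  Known
limitations: extinction-through-time inference from molecular phylogenies
alone is notoriously weak (the extensions are reported, not emphasised);
$\gamma$ loses power to detect diversity dependence once a clade has sat
at its ceiling for long; and the $\Delta\mathrm{AIC}$ bootstrap assumes
the pure-birth null with the same 10% unknown-diversity allowance used by
the MCCR test.
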