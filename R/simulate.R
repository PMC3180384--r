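# Forward simulation of reconstructed trees under the diversification
# models used as nulls and fixtures: pure birth (Yule), constant birth-death,
# two-rate Yule, and linear / exponential diversity-dependent speciation.
#
# Pure-birth-family trees are built sequentially: while k lineages exist the
# waiting time to the next speciation is Exponential(k * lambda_k), the new
# lineage attaches to a uniformly chosen extant lineage, and the tree is cut
# at the instant the (n+1)-th event would begin, i.e. the final interval is
# a full Exponential(n * lambda_n) draw (memorylessness makes this the
# reconstructed process observed at an arbitrary instant with n species).
# This construction leaves the gamma statistic with its exact null moments
# (mean 0, sd 1) at every n.  Truncating instead at the n-th speciation
# event (as some older simulators did) leaves a zero-length final interval
# and biases gamma positive by about sqrt(3 / (n - 2)).

# per-lineage speciation rate while k lineages exist
.rate_k <- function(k, model, r1, K, x) {
  switch(model,
    yule = r1,
    ddl  = r1 * (1 - k / K),
    ddx  = r1 * k^(-x),
    stop("no stationary rate for model ", model))
}

# Assemble a phylo from forward event times `ev` (births of lineages
# 3..n, increasing) and the cut time `depth`.  Attachment is uniform over
# extant lineages; tip labels t1..tn are assigned in birth order.
.assemble_tree <- function(n, ev, depth) {
  pn <- integer(n); bt <- numeric(n)
  pn[1:2] <- n + 1L
  edge <- matrix(0L, 2L * n - 2L, 2L)
  elen <- numeric(2L * n - 2L)
  ne <- 0L
  nextnode <- n + 2L
  k <- 2L
  for (tsplit in ev) {
    j <- sample.int(k, 1L)
    ne <- ne + 1L
    edge[ne, ] <- c(pn[j], nextnode)
    elen[ne] <- tsplit - bt[j]
    pn[j] <- nextnode; bt[j] <- tsplit
    k <- k + 1L
    pn[k] <- nextnode; bt[k] <- tsplit
    nextnode <- nextnode + 1L
  }
  for (j in seq_len(n)) {
    ne <- ne + 1L
    edge[ne, ] <- c(pn[j], j)
    elen[ne] <- depth - bt[j]
  }
  structure(list(edge = edge, edge.length = elen, Nnode = n - 1L,
                 tip.label = paste0("t", seq_len(n))),
            class = "phylo")
}

# two-rate waiting time: per-lineage rate r1 before forward time `shift`,
# r2 after; k concurrent lineages; returns the next event time after t0
.wait_two_rate <- function(t0, k, r1, r2, shift) {
  if (t0 < shift) {
    e <- stats::rexp(1L, k * r1)
    if (t0 + e <= shift) return(t0 + e)
    return(shift + stats::rexp(1L, k * r2))   # memoryless restart at the shift
  }
  t0 + stats::rexp(1L, k * r2)
}

#' Simulate a reconstructed chronogram
#'
#' Forward simulation to exactly `n_tips` contemporaneous tips under one of
#' five diversification models:
#' \describe{
#'   \item{`yule`}{pure birth at rate `lambda`;}
#'   \item{`bd`}{constant birth-death (`lambda`, `mu`), run forward with
#'     extinction and retried until `n_tips` lineages are simultaneously
#'     alive, then cut and pruned of extinct lineages;}
#'   \item{`yule2`}{pure birth with per-lineage rate `r1` before the shift
#'     and `r2` after it (`st` is the shift measured forward from the crown,
#'     since the total depth is unknown while simulating forward);}
#'   \item{`ddl`}{linear diversity dependence, rate `r1 * (1 - k / K)` while
#'     `k` lineages exist (requires `K > n_tips` so every interval,
#'     including the final one, has a positive rate);}
#'   \item{`ddx`}{exponential diversity dependence, rate `r1 * k^(-x)`.}
#' }
#'
#' @param model One of `"yule"`, `"bd"`, `"yule2"`, `"ddl"`, `"ddx"`.
#' @param n_tips Number of extant tips (>= 3).
#' @param lambda,mu Speciation and extinction rates (`yule`/`bd`).
#' @param r1,r2 Initial and late per-lineage rates (`yule2`, `ddl`, `ddx`).
#' @param K Linear diversity-dependence ceiling (`ddl`).
#' @param x Exponential diversity-dependence exponent (`ddx`).
#' @param st Rate-shift time, forward from the crown (`yule2`).
#' @param seed Optional integer seed (reproducible, RNG state restored).
#' @return A `phylo` chronogram with `n_tips` tips.
#' @examples
#' tr <- simulate_tree("yule", n_tips = 20, lambda = 1, seed = 1)
#' gamma_statistic(tr)
#' @export
simulate_tree <- function(model = c("yule", "bd", "yule2", "ddl", "ddx"),
                          n_tips, lambda = 1, mu = 0, r1 = NULL, r2 = NULL,
                          K = NULL, x = NULL, st = NULL, seed = NULL) {
  model <- match.arg(model)
  n <- as.integer(n_tips)
  if (n < 3L) stop("n_tips must be at least 3")
  with_local_seed(seed, {
    if (model == "bd") {
      if (lambda <= 0 || mu < 0) stop("need lambda > 0 and mu >= 0")
      return(.sim_bd(n, lambda, mu))
    }
    if (model == "yule2") {
      if (is.null(r1) || is.null(r2) || is.null(st) ||
          r1 <= 0 || r2 <= 0 || st <= 0)
        stop("yule2 requires r1 > 0, r2 > 0 and st > 0")
      t <- 0
      ev <- numeric(n - 2L)
      for (k in 2:(n - 1L)) {
        t <- .wait_two_rate(t, k, r1, r2, st)
        ev[k - 1L] <- t
      }
      depth <- .wait_two_rate(t, n, r1, r2, st)
      return(.assemble_tree(n, ev, depth))
    }
    if (model == "yule") r1 <- lambda
    if (is.null(r1) || r1 <= 0) stop("need a positive rate")
    if (model == "ddl") {
      if (is.null(K)) stop("ddl requires K")
      if (r1 * (1 - (n - 1L) / K) <= 0)
        stop("infeasible parameters: ddl rate non-positive before reaching ",
             n, " lineages (K = ", K, ")")
      if (r1 * (1 - n / K) <= 0)
        stop("infeasible parameters: ddl simulation needs K > n_tips so the ",
             "final interval has a positive rate")
    }
    if (model == "ddx" && is.null(x)) stop("ddx requires x")
    rates <- vapply(2:n, .rate_k, numeric(1L), model = model,
                    r1 = r1, K = K, x = x)
    w <- stats::rexp(n - 1L, rate = (2:n) * rates)
    s <- cumsum(w)
    .assemble_tree(n, s[seq_len(n - 2L)], s[n - 1L])
  })
}

# forward birth-death with acceptance sampling: retry until n lineages are
# simultaneously alive, cut Exponential(n * (lambda + mu)) after that
# instant, then prune extinct lineages
.sim_bd <- function(n, lambda, mu, max_attempts = 1e5L) {
  if (mu == 0) {
    w <- stats::rexp(n - 1L, rate = (2:n) * lambda)
    s <- cumsum(w)
    return(.assemble_tree(n, s[seq_len(n - 2L)], s[n - 1L]))
  }
  for (attempt in seq_len(max_attempts)) {
    pn <- c(0L, 0L)          # parent node per lineage (0 = crown, fixed later)
    bt <- c(0, 0)            # birth time of the pendant edge
    alive <- c(TRUE, TRUE)
    t <- 0
    events <- list()         # (type, time, lineage)
    repeat {
      k <- sum(alive)
      if (k == 0L || k >= n) break
      t <- t + stats::rexp(1L, k * (lambda + mu))
      j <- which(alive)[sample.int(k, 1L)]
      if (stats::runif(1L) < lambda / (lambda + mu)) {
        events[[length(events) + 1L]] <- list("b", t, j)
        pn <- c(pn, NA); bt <- c(bt, t); alive <- c(alive, TRUE)
      } else {
        events[[length(events) + 1L]] <- list("d", t, j)
        alive[j] <- FALSE
      }
    }
    if (sum(alive) < n) next
    depth <- t + stats::rexp(1L, n * (lambda + mu))
    # rebuild as a phylo: replay events, assigning nodes in order
    m <- length(pn)                       # total lineages ever born
    tipn <- 0L
    labs <- character(m)
    node <- m + 1L                        # ape node ids; root = m+1
    pnode <- rep(m + 1L, m); pb <- bt
    edge <- matrix(0L, 2L * m - 2L, 2L); elen <- numeric(2L * m - 2L); ne <- 0L
    nextnode <- m + 2L
    born <- 2L
    for (e in events) {
      j <- e[[3L]]; tt <- e[[2L]]
      if (e[[1L]] == "b") {
        born <- born + 1L
        ne <- ne + 1L
        edge[ne, ] <- c(pnode[j], nextnode); elen[ne] <- tt - pb[j]
        pnode[j] <- nextnode; pb[j] <- tt
        pnode[born] <- nextnode; pb[born] <- tt
        nextnode <- nextnode + 1L
      } else {
        tipn <- tipn + 1L
        ne <- ne + 1L
        edge[ne, ] <- c(pnode[j], tipn); elen[ne] <- tt - pb[j]
        labs[tipn] <- paste0("x", tipn)    # extinct
      }
    }
    extinct <- labs[seq_len(tipn)]
    for (j in which(alive)) {
      tipn <- tipn + 1L
      ne <- ne + 1L
      edge[ne, ] <- c(pnode[j], tipn); elen[ne] <- depth - pb[j]
      labs[tipn] <- paste0("t", tipn)
    }
    phy <- structure(list(edge = edge[seq_len(ne), , drop = FALSE],
                          edge.length = elen[seq_len(ne)],
                          Nnode = m - 1L, tip.label = labs[seq_len(tipn)]),
                     class = "phylo")
    if (length(extinct)) phy <- ape::drop.tip(phy, extinct)
    phy$root.edge <- NULL
    return(phy)
  }
  stop("birth-death simulation failed to reach ", n, " surviving lineages in ",
       max_attempts, " attempts")
}

#' Hypothetical full clade size under the missing-taxa rule
#'
#' The known total richness inflated by a fraction of assumed unknown
#' (undescribed, unsampled) diversity, rounded to the nearest integer with
#' halves away from zero.  The default 10 percent is the conservative
#' allowance used when building MCCR and bootstrap nulls.
#'
#' @param known_total Known species richness (described plus known
#'   undescribed; >= 3).
#' @param extra_fraction Assumed additional unknown diversity (default 0.10).
#' @return Integer full clade size.
#' @examples
#' full_clade_size(13)   # 14
#' full_clade_size(10)   # 11
#' @export
full_clade_size <- function(known_total, extra_fraction = 0.10) {
  if (known_total < 3) stop("known_total must be at least 3")
  if (extra_fraction < 0) stop("extra_fraction must be non-negative")
  as.integer(floor(known_total * (1 + extra_fraction) + 0.5))
}

#' Pure-birth null sample with random pruning
#'
#' Simulates `reps` pure-birth trees of `n_full` tips, prunes each
#' uniformly at random down to `n_sampled` tips, and rescales to unit
#' depth.  Replicate `i` uses seed `seed + i`, so replicate sets are
#' reproducible and order-independent.
#'
#' @param n_sampled Tips retained after pruning (>= 3).
#' @param n_full Full clade size simulated (>= `n_sampled`).
#' @param reps Number of replicate trees.
#' @param seed Integer base seed.
#' @param lambda Speciation rate (irrelevant after unit-depth scaling).
#' @return A `multiPhylo` of `reps` trees, each with `n_sampled` tips and
#'   depth 1.
#' @export
simulate_pruned_null <- function(n_sampled, n_full, reps, seed = 1,
                                 lambda = 1) {
  if (n_sampled < 3L) stop("n_sampled must be at least 3")
  if (n_sampled > n_full) stop("n_sampled exceeds n_full")
  out <- vector("list", reps)
  for (i in seq_len(reps)) {
    out[[i]] <- with_local_seed(seed + i, {
      tr <- simulate_tree("yule", n_full, lambda = lambda)
      if (n_sampled < n_full)
        tr <- ape::drop.tip(tr, sample(tr$tip.label, n_full - n_sampled))
      scale_to_unit_depth(tr)
    })
  }
  class(out) <- "multiPhylo"
  attr(out, "label") <- sprintf("pure-birth null: %d of %d tips, %d reps",
                                n_sampled, n_full, reps)
  out
}

#' The nine New Caledonian study clades
#'
#' Sampled terminals, known total richness, crown age (midpoint where a
#' range was reported) and the generating model used for the synthetic
#' fixture suite.  These per-clade constants drive [make_fixture_suite()]
#' and the age-size correlation example.
#'
#' @return A data frame with columns `name`, `n_sampled`, `known_total`,
#'   `age_ma`, `model`.
#' @export
nc_clades <- function() {
  data.frame(
    name = c("Niemeyera", "Scincidae", "Troglosironidae", "Papuadytes",
             "Gracilipsodes", "Helicopha", "Xanthochorema",
             "Hydropsychinae", "Agmina"),
    n_sampled   = c(47L, 42L, 11L, 15L, 10L, 19L, 10L, 28L, 75L),
    known_total = c(55L, 47L, 13L, 18L, 10L, 20L, 10L, 29L, 80L),
    age_ma      = c(32.4, 38.05, 49, 9, 14.4, 8.2, 11.9, 28.2, 21.9),
    model       = c("ddl", "ddl", "ddl", "ddl", "ddl", "yule", "ddl",
                    "ddl", "ddl"),
    stringsAsFactors = FALSE)
}

#' Write a synthetic fixture suite
#'
#' Simulates one chronogram per clade specification (unit depth) and writes
#' a Newick file plus a combined metadata table.  The default suite is the
#' nine-clade table of [nc_clades()]: diversity-dependent (DDL) generators
#' with ceiling `K` equal to the clade's hypothetical full size for every
#' clade except Helicopha, which is pure birth.  These are synthetic
#' stand-ins with the study clades' sampling fractions and ages, not
#' reconstructions of the real phylogenies.
#'
#' @param dir Output directory (created if absent).
#' @param specs Data frame as returned by [nc_clades()].
#' @param seed Integer base seed; file contents are byte-reproducible.
#' @param r1 Initial speciation rate for the generators.
#' @return Invisibly, the metadata data frame (with a `file` column).
#' @export
make_fixture_suite <- function(dir, specs = nc_clades(), seed = 1, r1 = 5) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  specs$file <- file.path(dir, paste0(specs$name, ".nwk"))
  for (i in seq_len(nrow(specs))) {
    n <- specs$n_sampled[i]
    tr <- if (specs$model[i] == "yule") {
      simulate_tree("yule", n, lambda = r1, seed = seed + i)
    } else {
      simulate_tree("ddl", n, r1 = r1, K = full_clade_size(specs$known_total[i]),
                    seed = seed + i)
    }
    write_chronogram(scale_to_unit_depth(tr), specs$file[i])
  }
  utils::write.table(specs, file.path(dir, "fixtures.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(specs)
}
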