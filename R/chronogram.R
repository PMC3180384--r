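# Chronogram input, validation and elementary transforms.
#
# A chronogram is an ape "phylo" object that is rooted, strictly binary,
# carries branch lengths on every edge, and is ultrametric (all tips
# contemporaneous) up to a small relative tolerance.  All analyses in this
# package consume validated chronograms or the branching-time summaries
# derived from them.

#' Read one or more chronograms from Newick
#'
#' Parses Newick text (one tree per line) and validates every tree as a
#' chronogram: rooted, binary, branch lengths on all edges, ultrametric
#' within `tol`.  Tips are snapped to exactly contemporaneous by adjusting
#' terminal edge lengths when the deviation is inside the tolerance; larger
#' deviations are errors.  Any root edge is discarded; inner node labels are
#' ignored.
#'
#' @param file Path to a Newick file.  Multi-line files yield a
#'   `multiPhylo` tree sample.
#' @param text Newick string, used instead of `file` when given.
#' @param tol Relative ultrametricity tolerance (deviation of root-to-tip
#'   path lengths, as a fraction of tree depth).
#' @return A validated `phylo`, or a `multiPhylo` when the input holds
#'   several trees.
#' @examples
#' tr <- read_chronogram(text = "((A:1,B:1):1,C:2);")
#' branching_times(tr)
#' @export
read_chronogram <- function(file = NULL, text = NULL, tol = 1e-6) {
  if (is.null(file) && is.null(text))
    stop("supply either `file` or `text`")
  phy <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(phy)) stop("could not parse Newick input")
  if (inherits(phy, "multiPhylo")) {
    out <- lapply(phy, validate_chronogram, tol = tol)
    class(out) <- "multiPhylo"
    return(out)
  }
  validate_chronogram(phy, tol = tol)
}

#' Validate a phylogeny as a chronogram
#'
#' @param phy A `phylo` object.
#' @param tol Relative ultrametricity tolerance; see [read_chronogram()].
#' @return The validated (and tip-snapped) `phylo`.
#' @export
validate_chronogram <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("not a \"phylo\" object")
  n <- length(phy$tip.label)
  if (n < 3L)
    stop("chronogram has ", n, " tips; at least 3 are required")
  if (is.null(phy$edge.length) || anyNA(phy$edge.length))
    stop("format error: branch lengths missing on one or more edges")
  if (any(phy$edge.length < 0))
    stop("format error: negative branch lengths")
  if (!ape::is.rooted(phy)) stop("structural error: tree is not rooted")
  nchild <- tabulate(phy$edge[, 1], nbins = n + phy$Nnode)
  poly <- which(nchild > 2L)
  if (length(poly))
    stop("structural error: polytomy at node ", poly[1L],
         " (", nchild[poly[1L]], " children)")
  if (any(nchild[(n + 1L):(n + phy$Nnode)] == 1L))
    stop("structural error: unary internal node present")
  phy$root.edge <- NULL
  phy$node.label <- NULL
  depths <- ape::node.depth.edgelength(phy)[seq_len(n)]
  depth <- max(depths)
  if (depth <= 0) stop("degenerate tree: zero depth")
  dev <- max(depth - depths) / depth
  if (dev > tol)
    stop(sprintf(
      "validation error: tree not ultrametric (max relative deviation %.3g > %.3g)",
      dev, tol))
  if (dev > 0) {
    # snap tips to the present by stretching terminal edges
    term <- match(seq_len(n), phy$edge[, 2])
    phy$edge.length[term] <- phy$edge.length[term] + (depth - depths)
  }
  phy
}

#' Write chronograms as Newick
#'
#' Branch lengths are emitted with 10 significant digits; multi-tree
#' samples are written one tree per line.
#'
#' @param phy A `phylo` or `multiPhylo`.
#' @param file Output path, or `""` to return the string(s).
#' @return Invisibly (or visibly for `file = ""`), the Newick string(s).
#' @export
write_chronogram <- function(phy, file = "") {
  ape::write.tree(phy, file = file, digits = 10)
}

#' Branching times, internode intervals and their cumulative sums
#'
#' Extracts from a chronogram the node ages before present (descending;
#' the first is the crown age), the internode intervals `g_k` during which
#' exactly `k` reconstructed lineages exist (`k = 2..n`, the last running
#' from the youngest node to the present), and the cumulative sums
#' `T_i = sum_{k=2..i} k * g_k` on which the gamma statistic and the
#' pure-birth likelihoods are built.
#'
#' @param x A chronogram (`phylo`), or a numeric vector of node ages
#'   before present (any order; `n - 1` values for `n` tips).
#' @param tol Ultrametricity tolerance forwarded to validation.
#' @return An object of class `"branching_times"`: a list with elements
#'   `n`, `ages` (descending), `intervals` (named `g2..gn`),
#'   `cumulative` (`T_2..T_n`), `total` (`T = T_n`) and `depth`.
#' @examples
#' branching_times(read_chronogram(text = "((A:1,B:1):1,C:2);"))
#' @export
branching_times <- function(x, tol = 1e-6) {
  if (inherits(x, "branching_times")) return(x)
  if (inherits(x, "phylo")) {
    x <- validate_chronogram(x, tol = tol)
    ages <- as.numeric(ape::branching.times(x))
  } else if (is.numeric(x)) {
    ages <- as.numeric(x)
  } else stop("cannot extract branching times from a ", class(x)[1L])
  .bt_from_ages(ages)
}

# fast path used by simulators and null loops: no validation
.bt_from_ages <- function(ages) {
  n <- length(ages) + 1L
  if (n < 3L) stop("unsupported size: need at least 3 tips (n = ", n, ")")
  ages <- sort(ages, decreasing = TRUE)
  if (ages[length(ages)] < 0) stop("negative node age")
  g <- c(-diff(ages), ages[n - 1L])        # g_2 .. g_n
  names(g) <- paste0("g", 2:n)
  Ti <- unname(cumsum((2:n) * g))
  structure(list(n = n, ages = unname(ages), intervals = g,
                 cumulative = Ti, total = Ti[n - 1L], depth = unname(ages[1L])),
            class = "branching_times")
}

#' @export
print.branching_times <- function(x, ...) {
  cat("Branching times: n =", x$n, "tips, crown age", format(x$depth), "\n")
  cat("  ages:", paste(format(x$ages, digits = 4), collapse = " "), "\n")
  cat("  T =", format(x$total, digits = 6), "\n")
  invisible(x)
}

#' Rescale a chronogram to unit root-to-tip depth
#'
#' Divides every branch length by the tree depth so that the crown age
#' becomes 1.  The gamma statistic and all AIC differences are invariant
#' under this rescaling; rate estimates scale by the depth.
#'
#' @param phy A chronogram.
#' @return The rescaled `phylo`.
#' @export
scale_to_unit_depth <- function(phy) {
  depth <- max(ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)])
  if (!is.finite(depth) || depth <= 0) stop("degenerate tree: zero depth")
  phy$edge.length <- phy$edge.length / depth
  phy
}

#' Randomly prune a chronogram to a given number of tips
#'
#' Retains a uniformly chosen subset of tips, mimicking incomplete taxon
#' sampling.  Suppressed unary nodes have their edge lengths summed, so the
#' result is again ultrametric with depth equal to the age of the most
#' recent common ancestor of the surviving tips.
#'
#' @param phy A chronogram.
#' @param keep Number of tips to retain (`3 <= keep <= n`).
#' @param seed Optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return The pruned `phylo`.
#' @export
prune_random <- function(phy, keep, seed = NULL) {
  n <- length(phy$tip.label)
  if (keep > n) stop("argument error: keep (", keep, ") exceeds tip count (", n, ")")
  if (keep < 3L) stop("argument error: keep must be at least 3")
  if (keep == n) return(phy)
  drop <- with_local_seed(seed, sample(phy$tip.label, n - keep))
  ape::drop.tip(phy, drop)
}

# Run `expr` under a temporary RNG state seeded with `seed` (NULL = use the
# current stream).  Restores the caller's .Random.seed afterwards.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}
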