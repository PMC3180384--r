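# Orchestration: run the full battery on one dataset and emit a
# Table-style report row, plus companion LTT curves.

#' Run the full diversification battery on one chronogram
#'
#' Scales the tree to unit depth, computes the gamma statistic with its
#' asymptotic p-value, the MCCR-corrected critical value and Monte Carlo p,
#' all core model fits with AIC, the rate-constant versus rate-variable
#' AIC difference and its parametric-bootstrap p-value, and (optionally)
#' the time-varying extensions and a gamma summary over a tree sample.
#'
#' @param tree A chronogram (`phylo`), or a path to a Newick file.
#' @param name Dataset label.
#' @param known_total Known species richness of the clade (>= tip count).
#' @param n_sampled Expected tip count; checked against the tree when given.
#' @param method_label Free-text provenance label for the tree (e.g. which
#'   ultrametrization produced it).
#' @param sample Optional `multiPhylo` (e.g. posterior draws); gamma is
#'   summarised over up to `max_sample` trees drawn without replacement.
#' @param mccr_reps,daic_reps Monte Carlo replicates for the MCCR test and
#'   the bootstrap AIC p-value.
#' @param alpha One-tailed level for the MCCR critical value.
#' @param extra_fraction Assumed unknown extra diversity for null sizes.
#' @param seed Integer base seed (all Monte Carlo draws derive from it).
#' @param restarts Optimiser restarts per model fit.
#' @param extended Also fit `spvar`/`exvar`/`bothvar`?
#' @param max_sample Cap on the number of sample trees summarised.
#' @return Class `"battery_record"`; see [as.data.frame.battery_record()]
#'   for the flat report row.
#' @export
run_battery <- function(tree, name = "dataset", known_total,
                        n_sampled = NULL, method_label = "",
                        sample = NULL, mccr_reps = 5000, daic_reps = 1000,
                        alpha = 0.05, extra_fraction = 0.10, seed = 1,
                        restarts = 10L, extended = TRUE, max_sample = 1000L) {
  if (is.character(tree)) tree <- read_chronogram(tree)
  tree <- validate_chronogram(tree)
  n <- length(tree$tip.label)
  if (!is.null(n_sampled) && n_sampled != n)
    stop("dataset ", name, ": tree has ", n, " tips but n_sampled = ", n_sampled)
  if (known_total < n)
    stop("dataset ", name, ": known_total (", known_total,
         ") below tip count (", n, ")")
  tree <- scale_to_unit_depth(tree)
  bt <- branching_times(tree)
  n_full <- full_clade_size(known_total, extra_fraction)
  message(sprintf(
    "battery[%s]: n = %d, known_total = %d, full size = %d, mccr_reps = %d, daic_reps = %d, seed = %d",
    name, n, known_total, n_full, mccr_reps, daic_reps, seed))
  gam <- gamma_statistic(bt)
  mccr <- mccr_test(gam$gamma, n, known_total, reps = mccr_reps,
                    alpha = alpha, extra_fraction = extra_fraction,
                    seed = seed)
  sel <- select_models(bt, restarts = restarts)
  dp <- delta_aic_p(sel$delta_aic, n, known_total, reps = daic_reps,
                    seed = seed + 10000L, extra_fraction = extra_fraction,
                    restarts = restarts)
  ext <- if (extended) fit_extended(bt, restarts = restarts) else NULL
  gsam <- NULL
  if (!is.null(sample)) {
    idx <- seq_along(sample)
    if (length(idx) > max_sample)
      idx <- with_local_seed(seed + 20000L,
                             sample(idx, max_sample, replace = FALSE))
    gsam <- gamma_over_sample(sample[idx])
  }
  structure(list(
    name = name, method_label = method_label, n_sampled = n,
    known_total = known_total, n_full = n_full,
    gamma = gam, mccr = mccr, selection = sel, delta_aic_p = dp,
    extended = ext, gamma_sample = gsam, ltt = ltt(tree),
    seed = seed, alpha = alpha),
    class = "battery_record")
}

#' @export
print.battery_record <- function(x, ...) {
  cat("== Diversification battery:", x$name,
      if (nzchar(x$method_label)) paste0("(", x$method_label, ")"), "==\n")
  cat(sprintf("  %d of %d known species sampled (null full size %d)\n",
              x$n_sampled, x$known_total, x$n_full))
  print(x$gamma); print(x$mccr); print(x$selection)
  cat(sprintf("  dAIC bootstrap p = %.4g (%d reps)\n",
              x$delta_aic_p$p, x$delta_aic_p$reps))
  if (!is.null(x$gamma_sample)) print(x$gamma_sample)
  invisible(x)
}

#' Flatten a battery record to one report row
#'
#' Column order mirrors the per-clade result tables of diversification
#' studies: gamma and its asymptotic p, the MCCR critical value and p, the
#' pure-birth fit (LH, AIC, r1), the best rate-variable fit (model, LH,
#' AIC, r1, r2, K, x, st as applicable), the AIC difference and its
#' bootstrap p.
#'
#' @param x A `battery_record`.
#' @param ... Unused.
#' @return A one-row data frame.
#' @export
as.data.frame.battery_record <- function(x, ...) {
  pb <- x$selection$fits$yule1
  rv <- x$selection$best_rv
  pick <- function(f, p) if (p %in% names(f$params)) f$params[[p]] else NA_real_
  data.frame(
    dataset = x$name, method = x$method_label,
    n_sampled = x$n_sampled, known_total = x$known_total, n_full = x$n_full,
    gamma = x$gamma$gamma, gamma_p = x$gamma$p_one_tailed,
    gamma_C = x$mccr$critical_value, mccr_p = x$mccr$p,
    pb_LH = pb$loglik, pb_AIC = pb$aic, pb_r1 = pb$params[["lambda"]],
    rv_model = rv$model, rv_LH = rv$loglik, rv_AIC = rv$aic,
    rv_r1 = pick(rv, "r1"), rv_r2 = pick(rv, "r2"), rv_k = pick(rv, "K"),
    rv_x = pick(rv, "x"), rv_st = pick(rv, "st"),
    delta_aic = x$selection$delta_aic, delta_aic_p = x$delta_aic_p$p,
    converged = x$selection$converged,
    stringsAsFactors = FALSE)
}

#' Write a battery report as TSV (plus companion LTT curves)
#'
#' One row per record, in input order; point estimates to 3 decimals,
#' p-values to 3 significant figures.  When `ltt_dir` is given, each
#' record's LTT curve is written as `<dataset>_ltt.csv` there.
#'
#' @param records A `battery_record` or list of them.
#' @param path Output TSV path.
#' @param ltt_dir Optional directory for per-dataset LTT CSV files.
#' @return Invisibly, the unformatted report data frame.
#' @export
write_report <- function(records, path, ltt_dir = NULL) {
  if (inherits(records, "battery_record")) records <- list(records)
  if (!length(records)) stop("no records to report")
  df <- do.call(rbind, lapply(records, as.data.frame))
  out <- df
  pcols <- c("gamma_p", "mccr_p", "delta_aic_p")
  for (cl in names(out)) {
    if (!is.numeric(out[[cl]])) next
    out[[cl]] <- if (cl %in% pcols) signif(out[[cl]], 3L)
                 else round(out[[cl]], 3L)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ltt_dir)) {
    if (!dir.exists(ltt_dir)) dir.create(ltt_dir, recursive = TRUE)
    for (r in records)
      write_ltt(r$ltt, file.path(ltt_dir, paste0(r$name, "_ltt.csv")))
  }
  invisible(df)
}
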