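#' Fit a single-expansion demographic model to an observed phylogeny
#'
#' The package's main entry point. Takes a rooted haplogroup tree with
#' SNP-count branch lengths, computes its statistic triple
#' ([tree_stats()]) and mutation-clock TMRCA ([empirical_tmrca_years()]),
#' and runs the sequential grid-refinement search
#' ([sequential_search()]) for the four expansion parameters — starting and
#' ending male effective population size, expansion duration and expansion
#' end time — that make simulated genealogies match the observed tree.
#'
#' @param tree A rooted `phylo` tree with SNP-count branch lengths, or a
#'   path to a Newick file.
#' @param config A [sim_config()]; defaults to the standard constants with
#'   `n_tips` taken from the tree.
#' @param grid Initial [param_grid()]; defaults to [default_grid()] bounded
#'   by the tree's empirical TMRCA.
#' @param max_tmrca_years TMRCA bound for scenario exclusion; defaults to
#'   the tree's own [empirical_tmrca_years()].
#' @param reps Simulated genealogies per scenario (default from `config`,
#'   normally 1000; 200 gives a quick desk-scale fit).
#' @param seed Integer seed governing the whole search.
#' @param ... Further arguments passed to [sequential_search()]
#'   (`and_cutoff`, `stop_frac`, `max_rounds`, `mutate`, `verbose`, ...).
#' @return An object of class `expansion_fit` with `print`, `summary`,
#'   `coef`, `plot`, `simulate` and `residuals` methods. `coef` returns the
#'   per-parameter medians over the accepted (AND < cutoff) scenarios.
#' @examples
#' \donttest{
#' fit <- fit_expansion(haplogroup_fixture("R1b"), reps = 100, seed = 1)
#' coef(fit)
#' summary(fit)
#' }
#' @export
fit_expansion <- function(tree, config = NULL, grid = NULL,
                          max_tmrca_years = NULL, reps = NULL, seed = 1, ...) {
  cl <- match.call()
  if (is.character(tree)) tree <- read_tree(tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(config)) config <- sim_config(n_tips = ape::Ntip(tree))
  if (config$n_tips != ape::Ntip(tree))
    stop("config$n_tips (", config$n_tips, ") does not match the tree (",
         ape::Ntip(tree), " tips)")
  if (is.null(reps)) reps <- config$reps
  obs <- tree_stats(tree)
  if (!all(is.finite(obs)))
    stop("observed tree has non-finite statistics (perfect star?); ",
         "the model cannot be fitted to it")
  tmrca <- empirical_tmrca_years(tree, config)
  if (is.null(max_tmrca_years)) max_tmrca_years <- tmrca
  if (is.null(grid))
    grid <- default_grid(max_tmrca_years, gen_years = config$gen_years)
  search <- sequential_search(obs, grid, config, max_tmrca_years,
                              reps = reps, seed = seed, ...)
  co <- vapply(search$summaries, function(s) s$median, numeric(1))
  structure(list(call = cl, obs_stats = obs, tmrca_years = tmrca,
                 coefficients = co, search = search, config = config,
                 seed = seed),
            class = "expansion_fit")
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat("Single-expansion demographic fit\n\nCall:\n  ")
  print(x$call)
  cat(sprintf("\nObserved: r = %.4g, mean depth = %.4g, depth SD = %.4g\n",
              x$obs_stats[["r"]], x$obs_stats[["tmrca_mean"]],
              x$obs_stats[["tmrca_sd"]]))
  cat(sprintf("Empirical TMRCA: %.0f years\n", x$tmrca_years))
  cat(sprintf("\n%d round(s), %d accepted scenarios (AND < %g)\n",
              x$search$n_rounds, nrow(x$search$accepted),
              x$search$and_cutoff))
  cat("\nCoefficients (medians over accepted scenarios):\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.expansion_fit <- function(object, ...) object$coefficients

#' @export
summary.expansion_fit <- function(object, ...) {
  s <- object$search$summaries
  tab <- do.call(rbind, lapply(s, function(p)
    c(median = p$median, lower_2.5 = p$interval[1], upper_97.5 = p$interval[2])))
  structure(list(fit = object, table = tab), class = "summary.expansion_fit")
}

#' @export
print.summary.expansion_fit <- function(x, ...) {
  f <- x$fit
  cat(sprintf(
    "Expansion-model fit: %d accepted scenarios after %d round(s)%s\n\n",
    nrow(f$search$accepted), f$search$n_rounds,
    if (f$search$converged) "" else " (round limit reached)"))
  print(signif(x$table, 4))
  cat(sprintf("\nBest AND: %.4f   acceptance cutoff: %g   reps/scenario: %d\n",
              min(f$search$accepted$and), f$search$and_cutoff, f$search$reps))
  best <- fitted_model(f)
  cat(sprintf("Median model: %g -> %g men over %g years, ending %g years ago\n",
              best$start_n, best$end_n, best$duration_years, best$t_end_years))
  invisible(x)
}

#' Expansion model at the fitted medians
#'
#' @param object An `expansion_fit`.
#' @return An [expansion_model()] built from the median accepted values.
#' @export
fitted_model <- function(object) {
  stopifnot(inherits(object, "expansion_fit"))
  co <- object$coefficients
  expansion_model(co[["start_n"]], co[["end_n"]], co[["t_end_years"]],
                  co[["duration_years"]])
}

#' @export
residuals.expansion_fit <- function(object, ...) {
  # relative deviation of each averaged statistic at the best accepted cell
  acc <- object$search$accepted
  best <- acc[which.min(acc$and), ]
  sim <- c(r = best$r_s, tmrca_mean = best$m_s, tmrca_sd = best$d_s)
  (sim - object$obs_stats) / object$obs_stats
}

#' Simulate genealogies from a fitted expansion model
#'
#' @param object An `expansion_fit`.
#' @param nsim Number of genealogies.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `phylo` genealogies (class `multiPhylo`) simulated
#'   under the median accepted model.
#' @export
simulate.expansion_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  model <- fitted_model(object)
  out <- replicate(nsim, simulate_genealogy(model, object$config),
                   simplify = FALSE)
  class(out) <- "multiPhylo"
  out
}

#' Plot a fitted expansion model
#'
#' `which = "hist"` draws the per-parameter frequency histograms of the
#' accepted scenarios (the fit's approximate posterior); `which = "surface"`
#' draws the final-round AND surface, minimised over the two time axes, as a
#' heat map over starting and ending population size with accepted cells
#' dotted.
#'
#' @param x An `expansion_fit`.
#' @param which `"hist"` or `"surface"`.
#' @param ... Passed to the underlying plotting calls.
#' @return `x`, invisibly.
#' @export
plot.expansion_fit <- function(x, which = c("hist", "surface"), ...) {
  which <- match.arg(which)
  if (which == "hist") {
    op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    labs <- c(start_n = "starting size (men)", end_n = "ending size (men)",
              t_end_years = "expansion end (years ago)",
              duration_years = "expansion duration (years)")
    for (p in names(x$search$summaries)) {
      h <- x$search$summaries[[p]]$histogram
      graphics::barplot(as.numeric(h), names.arg = names(h),
                        main = labs[[p]], ylab = "accepted scenarios",
                        las = 2, cex.names = 0.7, ...)
    }
  } else {
    final <- x$search$rounds[[x$search$n_rounds]]$surface
    grid <- x$search$rounds[[x$search$n_rounds]]$grid
    sn <- grid$axes$start_n
    en <- grid$axes$end_n
    z <- matrix(NA_real_, length(sn), length(en))
    for (i in seq_along(sn)) for (j in seq_along(en)) {
      sel <- final$start_n == sn[i] & final$end_n == en[j] & !final$excluded
      if (any(sel)) z[i, j] <- min(final$and[sel], na.rm = TRUE)
    }
    graphics::image(log10(sn), log10(en), z,
                    col = rev(grDevices::heat.colors(24)),
                    xlab = "log10 starting size", ylab = "log10 ending size",
                    main = "min AND over time axes", ...)
    acc <- z <= x$search$and_cutoff
    pts <- which(acc, arr.ind = TRUE)
    if (nrow(pts))
      graphics::points(log10(sn)[pts[, 1]], log10(en)[pts[, 2]], pch = 16)
  }
  invisible(x)
}

#' Export a fit surface as TSV
#'
#' Long-format table of one search round: the four parameter values, the
#' averaged simulated statistics, the AND value and the exclusion flag —
#' the machine-readable counterpart of a heat-map panel.
#'
#' @param fit An `expansion_fit` (or `expansion_search`).
#' @param file Output path.
#' @param round Which round to export (default: final).
#' @return The file path, invisibly.
#' @export
write_fit_surface <- function(fit, file, round = NULL) {
  search <- if (inherits(fit, "expansion_fit")) fit$search else fit
  stopifnot(inherits(search, "expansion_search"))
  if (is.null(round)) round <- search$n_rounds
  utils::write.table(search$rounds[[round]]$surface, file = file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export search results as JSON
#'
#' Serialises the accepted scenarios, per-parameter summaries, settings and
#' per-round grids of a search to JSON.
#'
#' @param fit An `expansion_fit` (or `expansion_search`).
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_fit_json <- function(fit, file) {
  search <- if (inherits(fit, "expansion_fit")) fit$search else fit
  stopifnot(inherits(search, "expansion_search"))
  summaries <- lapply(search$summaries, function(s)
    list(median = s$median, interval = s$interval,
         histogram = as.list(s$histogram)))
  payload <- list(
    n_rounds = search$n_rounds,
    converged = search$converged,
    and_cutoff = search$and_cutoff,
    reps = search$reps,
    seed = search$seed,
    max_tmrca_years = search$max_tmrca_years,
    grids = lapply(search$rounds, function(r) r$grid$axes),
    accepted = search$accepted,
    summaries = summaries)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(file)
}

#' Statistics report for a tree
#'
#' Convenience reporter: reads a tree (path or `phylo`), prints its three
#' summary statistics, SNP totals, empirical TMRCA, and flags near-star
#' structure (a single internal branch).
#'
#' @param tree A `phylo` object or path to a Newick file.
#' @param config Optional [sim_config()]; defaults to standard constants
#'   with the tree's tip count.
#' @return Invisibly, a list with `stats`, `tmrca_years`, `n_tips`,
#'   `n_internal_branches` and `total_snps`.
#' @examples
#' tree_stats_report(haplogroup_fixture("R1b"))
#' @export
tree_stats_report <- function(tree, config = NULL) {
  if (is.character(tree)) tree <- read_tree(tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(config)) config <- sim_config(n_tips = ape::Ntip(tree))
  n <- ape::Ntip(tree)
  n_int <- sum(tree$edge[, 2] > n)
  st <- tree_stats(tree)
  tm <- empirical_tmrca_years(tree, config)
  cat(sprintf("%d tips, %d internal branch(es), %g SNPs in total\n",
              n, n_int, total_branch_length(tree)))
  if (n_int == 0) cat("perfect star: no internal branches, r is infinite\n")
  if (n_int == 1) cat("near-star: single internal branch\n")
  cat(sprintf("r = %.5g, mean depth = %.5g, depth SD = %.5g (normalised)\n",
              st[["r"]], st[["tmrca_mean"]], st[["tmrca_sd"]]))
  cat(sprintf("empirical TMRCA: %.0f years\n", tm))
  invisible(list(stats = st, tmrca_years = tm, n_tips = n,
                 n_internal_branches = n_int,
                 total_snps = total_branch_length(tree)))
}
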