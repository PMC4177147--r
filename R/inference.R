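#' Average normalised delta between simulated and observed statistics
#'
#' The fit statistic minimised by the grid search: each of the three tree
#' statistics is compared by its absolute relative deviation from the
#' observed value, and the three deviations are averaged:
#' \deqn{\mathrm{AND} = \frac{|r_s - r_o|/r_o + |m_s - m_o|/m_o +
#'       |d_s - d_o|/d_o}{3}}
#' Lower is better; 0 means an exact match. Any non-finite simulated
#' component (a star-like scenario with infinite r) gives `Inf` — the worst
#' possible fit — rather than an error.
#'
#' @param sim Simulated statistic triple, as from [tree_stats()] or a
#'   scenario average.
#' @param obs Observed statistic triple; all components must be finite and
#'   positive.
#' @return A single non-negative number, possibly `Inf`.
#' @examples
#' and_distance(c(1.5, 0.4, 0.1), c(1, 0.5, 0.1))  # (0.5 + 0.2 + 0) / 3
#' @export
and_distance <- function(sim, obs) {
  sim <- as.numeric(sim)
  obs <- as.numeric(obs)
  if (length(sim) != 3 || length(obs) != 3)
    stop("sim and obs must each hold three statistics (r, mean, sd)")
  if (any(!is.finite(obs)) || any(obs <= 0))
    stop("observed statistics must be finite and positive")
  if (any(!is.finite(sim))) return(Inf)
  mean(abs(sim - obs) / obs)
}

#' Empirical TMRCA of an observed SNP tree, in years
#'
#' Converts the mean root-to-tip SNP count into calendar time using the
#' mutation clock: `mean SNPs / (mu * seq_len)` generations, times the
#' generation time. The mutation rate simply scales the result — halving the
#' rate doubles the years.
#'
#' @param tree A `phylo` tree with SNP-count branch lengths.
#' @param config A [sim_config()] supplying `mu`, `seq_len` and `gen_years`.
#' @return The TMRCA estimate in years before present.
#' @examples
#' empirical_tmrca_years(haplogroup_fixture("R1b"), sim_config(6))
#' @export
empirical_tmrca_years <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  if (total_branch_length(tree) <= 0) stop("degenerate tree: zero length")
  n <- ape::Ntip(tree)
  dmat <- ape::dist.nodes(tree)
  root <- n + 1
  mean(dmat[root, seq_len(n)]) / (config$mu * config$seq_len) * config$gen_years
}

#' Is an expansion scenario compatible with a maximum TMRCA?
#'
#' A haplogroup's expansion cannot have begun before the haplogroup itself
#' existed, so scenarios whose expansion start (`t_end_years +
#' duration_years`) predates the haplogroup's TMRCA are excluded from the
#' grid before any simulation. The boundary is inclusive.
#'
#' @param model An [expansion_model()].
#' @param max_tmrca_years Maximum TMRCA of the haplogroup, in years.
#' @return `TRUE` if the scenario's expansion begins at or after
#'   `max_tmrca_years` before present.
#' @examples
#' tmrca_compatible(expansion_model(2, 9500, 12000, 300), 13000)  # TRUE
#' @export
tmrca_compatible <- function(model, max_tmrca_years) {
  stopifnot(inherits(model, "expansion_model"))
  if (max_tmrca_years <= 0) stop("max_tmrca_years must be positive")
  model$t_end_years + model$duration_years <= max_tmrca_years
}

geom_seq <- function(lo, hi, n) {
  if (lo <= 0) stop("geometric axis needs positive bounds")
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Four-axis parameter grid
#'
#' Defines the Cartesian grid of expansion scenarios evaluated in one round
#' of the search. Each axis is a strictly increasing value vector; `spacing`
#' records whether refinement steps on that axis are taken geometrically or
#' linearly; `bounds` are global limits that refinement never escapes.
#'
#' @param start_n,end_n,t_end_years,duration_years Axis value vectors.
#' @param spacing Named character vector, `"geometric"` or `"linear"` per
#'   axis.
#' @param bounds Named list of `c(lo, hi)` global bounds per axis; defaults
#'   to each axis's own range.
#' @return An object of class `param_grid`.
#' @seealso [default_grid()] for the standard wide starting grid.
#' @export
param_grid <- function(start_n, end_n, t_end_years, duration_years,
                       spacing = c(start_n = "geometric", end_n = "geometric",
                                   t_end_years = "linear",
                                   duration_years = "geometric"),
                       bounds = NULL) {
  axes <- list(start_n = start_n, end_n = end_n, t_end_years = t_end_years,
               duration_years = duration_years)
  for (nm in names(axes)) {
    v <- axes[[nm]]
    if (length(v) < 1 || is.unsorted(v, strictly = TRUE))
      stop("axis ", nm, " must be non-empty and strictly increasing")
  }
  if (is.null(bounds)) bounds <- lapply(axes, range)
  spacing <- spacing[names(axes)]
  if (!all(spacing %in% c("geometric", "linear")))
    stop("spacing must be 'geometric' or 'linear'")
  structure(list(axes = axes, spacing = spacing, bounds = bounds),
            class = "param_grid")
}

#' @export
print.param_grid <- function(x, ...) {
  cat("param_grid:", prod(lengths(x$axes)), "scenarios\n")
  for (nm in names(x$axes))
    cat(sprintf("  %-15s [%s] %s\n", nm,
                paste(signif(x$axes[[nm]], 4), collapse = ", "),
                x$spacing[[nm]]))
  invisible(x)
}

#' Default wide starting grid
#'
#' The first-round grid spans all plausible values: starting size 1 to 5,000
#' men and ending size 100 to 100,000 men (both geometric), expansion end
#' time 0 to the haplogroup's TMRCA and expansion duration one generation to
#' the TMRCA (both linear; a linear measure on the time axes keeps the
#' accepted-set marginals from piling onto very short durations when the fit
#' surface is flat along its degenerate directions). Time axes deliberately
#' extend to the empirical TMRCA, the oldest moment at which the expansion
#' could have begun.
#'
#' @param max_tmrca_years Empirical TMRCA of the haplogroup in years,
#'   typically from [empirical_tmrca_years()].
#' @param n_points Values per axis.
#' @param gen_years Generation time, setting the shortest duration.
#' @return A [param_grid()].
#' @export
default_grid <- function(max_tmrca_years, n_points = 5, gen_years = 30) {
  param_grid(start_n = geom_seq(1, 5000, n_points),
             end_n = geom_seq(100, 1e5, n_points),
             t_end_years = seq(0, max_tmrca_years, length.out = n_points),
             duration_years = seq(gen_years, max_tmrca_years,
                                  length.out = n_points),
             spacing = c(start_n = "geometric", end_n = "geometric",
                         t_end_years = "linear",
                         duration_years = "linear"))
}

#' Evaluate one demographic scenario against observed statistics
#'
#' Simulates `reps` genealogies under `model`, computes the statistic triple
#' of each replicate on its normalised tree, averages each statistic across
#' replicates, and returns the AND distance of the averaged triple from the
#' observed one.
#'
#' Replicates with infinite `r` (possible in `mutate` mode, probability zero
#' on continuous genealogies) are dropped from the `r` average and their
#' fraction reported; if more than half are infinite the scenario's AND is
#' `Inf`. Replicates with no variants at all (`mutate` mode) are dropped from
#' every average; if all replicates are degenerate, an error.
#'
#' @param model An [expansion_model()].
#' @param obs Observed statistic triple from [tree_stats()].
#' @param config A [sim_config()].
#' @param reps Replicates; defaults to `config$reps`.
#' @param seed Optional seed set before simulating.
#' @param mutate Compute replicate statistics on Poisson-mutated SNP trees
#'   instead of genealogy branch lengths.
#' @return A list with `stats` (the averaged triple), `and`, `frac_inf_r`,
#'   `n_degenerate` and `reps`.
#' @examples
#' obs <- tree_stats(haplogroup_fixture("R1b"))
#' evaluate_scenario(expansion_model(2, 9500, 12000, 325), obs,
#'                   sim_config(6), reps = 50, seed = 1)
#' @export
evaluate_scenario <- function(model, obs, config, reps = config$reps,
                              seed = NULL, mutate = FALSE) {
  if (reps < 1) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sims <- scenario_stats(model, config, reps = reps, mutate = mutate)
  ok <- !is.na(sims[, "tmrca_mean"])
  n_deg <- sum(!ok)
  if (!any(ok)) stop("all replicates degenerate (no variants simulated)")
  r_vals <- sims[ok, "r"]
  finite_r <- is.finite(r_vals)
  frac_inf <- 1 - mean(finite_r)
  r_bar <- if (frac_inf > 0.5 || !any(finite_r)) Inf else mean(r_vals[finite_r])
  stats <- c(r = r_bar,
             tmrca_mean = mean(sims[ok, "tmrca_mean"]),
             tmrca_sd = mean(sims[ok, "tmrca_sd"]))
  list(stats = stats, and = and_distance(stats, obs),
       frac_inf_r = frac_inf, n_degenerate = n_deg, reps = reps)
}

cell_seed <- function(seed, round, cell) {
  as.integer((as.double(seed) %% 65011 + 1) * 30011 +
               round * 1013 + cell * 7) %% 2147483629L
}

#' Evaluate every scenario on a parameter grid
#'
#' Runs [evaluate_scenario()] for each cell of the grid's Cartesian product,
#' skipping cells excluded by the TMRCA-compatibility filter
#' ([tmrca_compatible()]). Per-cell RNG seeds are derived from `(seed, round,
#' cell index)`, so a surface is reproducible for a given seed and
#' independent of evaluation order.
#'
#' @param grid A [param_grid()].
#' @param obs Observed statistic triple.
#' @param config A [sim_config()].
#' @param max_tmrca_years TMRCA bound for the exclusion filter.
#' @param reps Replicates per scenario.
#' @param seed Integer seed for the whole surface.
#' @param round Round number (enters the per-cell seed derivation).
#' @param mutate Passed to [evaluate_scenario()].
#' @return A `data.frame` of class `fit_surface`: one row per cell with the
#'   four parameter values, averaged statistics `r_s`, `m_s`, `d_s`, `and`,
#'   `excluded` and `frac_inf_r`.
#' @export
evaluate_grid <- function(grid, obs, config, max_tmrca_years,
                          reps = config$reps, seed = 1, round = 1,
                          mutate = FALSE) {
  stopifnot(inherits(grid, "param_grid"))
  cells <- expand.grid(grid$axes, KEEP.OUT.ATTRS = FALSE)
  nc <- nrow(cells)
  r_s <- m_s <- d_s <- and <- frac_inf <- rep(NA_real_, nc)
  excluded <- cells$t_end_years + cells$duration_years > max_tmrca_years
  for (i in seq_len(nc)) {
    if (excluded[i]) next
    model <- expansion_model(cells$start_n[i], cells$end_n[i],
                             cells$t_end_years[i], cells$duration_years[i])
    ev <- evaluate_scenario(model, obs, config, reps = reps,
                            seed = cell_seed(seed, round, i), mutate = mutate)
    r_s[i] <- ev$stats[["r"]]
    m_s[i] <- ev$stats[["tmrca_mean"]]
    d_s[i] <- ev$stats[["tmrca_sd"]]
    and[i] <- ev$and
    frac_inf[i] <- ev$frac_inf_r
  }
  out <- cbind(cells, r_s = r_s, m_s = m_s, d_s = d_s, and = and,
               excluded = excluded, frac_inf_r = frac_inf)
  class(out) <- c("fit_surface", class(out))
  out
}

#' Narrow a parameter grid around its best-fitting cells
#'
#' The refinement step of the sequential search: keeps a conservative
#' selection of the lowest-AND cells and rebuilds each axis to span the kept
#' cells' values extended by one grid step on each side, clipped to the
#' grid's global bounds, re-discretised at `n_points` values with the axis's
#' spacing. Two selection rules are available:
#' \describe{
#'   \item{`"quantile"` (default)}{keep the lowest `keep_frac` fraction of
#'     evaluated cells by AND value — steady narrowing regardless of the
#'     noise floor;}
#'   \item{`"threshold"`}{keep cells with
#'     `AND <= max(cutoff, retain_factor * round minimum)`.}
#' }
#' Either way at least `min_keep` cells are carried (topped up by the
#' next-lowest).
#'
#' @param surface A `fit_surface` from [evaluate_grid()].
#' @param grid The [param_grid()] that produced it.
#' @param rule Selection rule, `"quantile"` or `"threshold"`.
#' @param keep_frac Fraction of evaluated cells kept under the quantile rule.
#' @param and_cutoff Acceptance threshold (default 0.05).
#' @param retain_factor Multiple of the round minimum retained under the
#'   threshold rule.
#' @param min_keep Minimum number of cells carried into the next round.
#' @param n_points Values per axis in the refined grid.
#' @return A new [param_grid()] with the same spacing and global bounds.
#' @export
refine_grid <- function(surface, grid, rule = c("quantile", "threshold"),
                        keep_frac = 0.2, and_cutoff = 0.05,
                        retain_factor = 1.5, min_keep = 5, n_points = 5) {
  stopifnot(inherits(grid, "param_grid"))
  rule <- match.arg(rule)
  n_points <- max(n_points, 2)
  ok <- !surface$excluded & is.finite(surface$and)
  if (!any(ok))
    stop("refinement failed: no evaluated cell has a finite AND value")
  best <- min(surface$and[ok])
  lim <- if (rule == "quantile") {
    stats::quantile(surface$and[ok], keep_frac, names = FALSE)
  } else {
    max(and_cutoff, best * retain_factor)
  }
  keep <- ok & surface$and <= lim
  if (sum(keep) < min_keep) {
    ord <- order(ifelse(ok, surface$and, Inf))
    keep[ord[seq_len(min(min_keep, sum(ok)))]] <- TRUE
  }
  axes <- grid$axes
  new_axes <- list()
  for (nm in names(axes)) {
    v <- axes[[nm]]
    b <- grid$bounds[[nm]]
    geo <- grid$spacing[[nm]] == "geometric"
    kv <- unique(surface[[nm]][keep])
    if (geo) kv <- log(kv)
    # robust span over the kept cells' distinct axis values: stragglers must
    # not pin the range open (or the search never narrows at noisy reps), and
    # distinct values rather than cells keep axis regions thinned by the
    # TMRCA exclusion from being under-weighted
    kept <- if (length(kv) >= 4)
      stats::quantile(kv, c(0.1, 0.9), names = FALSE) else range(kv)
    if (geo) {
      f <- if (length(v) > 1) log(v[2] / v[1]) else log(2)
      lo <- kept[1] - f
      hi <- kept[2] + f
      old <- log(range(v))
      if (hi - lo > diff(old)) {          # monotone narrowing
        mid <- (lo + hi) / 2
        lo <- mid - diff(old) / 2
        hi <- mid + diff(old) / 2
      }
      lo <- max(lo, log(b[1]))
      hi <- min(hi, log(b[2]))
      if (hi <= lo) hi <- lo + 1e-6
      new_axes[[nm]] <- exp(seq(lo, hi, length.out = n_points))
    } else {
      s <- if (length(v) > 1) v[2] - v[1] else
        max(diff(b) / (n_points - 1), 1e-9)
      lo <- kept[1] - s
      hi <- kept[2] + s
      old <- range(v)
      if (hi - lo > diff(old)) {
        mid <- (lo + hi) / 2
        lo <- mid - diff(old) / 2
        hi <- mid + diff(old) / 2
      }
      lo <- max(lo, b[1])
      hi <- min(hi, b[2])
      if (hi <= lo) hi <- lo + max(s * 1e-6, 1e-9)
      new_axes[[nm]] <- seq(lo, hi, length.out = n_points)
    }
  }
  # snap float dust to zero on linear axes and de-duplicate near-identical
  # values (both can arise once an axis pins against its bounds)
  for (nm in names(new_axes)) {
    v <- new_axes[[nm]]
    if (grid$spacing[[nm]] == "linear") v[abs(v) < 1e-6] <- 0
    new_axes[[nm]] <- sort(unique(signif(v, 12)))
  }
  param_grid(new_axes$start_n, new_axes$end_n, new_axes$t_end_years,
             new_axes$duration_years, spacing = grid$spacing,
             bounds = grid$bounds)
}

#' Sequential grid-refinement search
#'
#' The core inference loop: evaluate a grid of expansion scenarios against
#' the observed statistics, narrow the parameter ranges around the
#' best-fitting cells with [refine_grid()], and repeat until at least
#' `stop_frac` of the evaluated cells fit well (`AND < and_cutoff`) or
#' `max_rounds` is reached. The final round's sub-cutoff cells form the
#' accepted set, summarised per parameter by a frequency histogram, the
#' median, and the 2.5–97.5 percentile interval.
#'
#' @param obs Observed statistic triple from [tree_stats()].
#' @param grid Initial [param_grid()]; see [default_grid()].
#' @param config A [sim_config()].
#' @param max_tmrca_years TMRCA bound for scenario exclusion.
#' @param reps Replicates per scenario per round.
#' @param and_cutoff Acceptance threshold on AND (default 0.05).
#' @param rule,keep_frac,retain_factor,min_keep Refinement selection rule;
#'   see [refine_grid()].
#' @param stop_frac Stop once this fraction of evaluated cells is below
#'   `and_cutoff`.
#' @param max_rounds Upper bound on rounds.
#' @param seed Integer seed governing the entire search.
#' @param mutate Score scenarios on Poisson-mutated SNP trees instead of
#'   raw genealogy branch lengths (a sensitivity option; see the vignette
#'   for the trade-off).
#' @param accept `"pooled"` (default) collects sub-cutoff cells from every
#'   round; `"final"` uses only the last round's.
#' @param verbose Print one line per round.
#' @return An object of class `expansion_search`: a list with `rounds` (each
#'   round's grid and surface), `accepted` (final sub-cutoff cells),
#'   `summaries` (per-parameter median, interval and histogram), `converged`,
#'   and the settings used.
#' @seealso [fit_expansion()] for the one-call interface on an observed tree.
#' @export
sequential_search <- function(obs, grid, config, max_tmrca_years,
                              reps = config$reps, and_cutoff = 0.05,
                              rule = c("quantile", "threshold"),
                              keep_frac = 0.2, retain_factor = 1.5,
                              min_keep = 5, stop_frac = 0.5, max_rounds = 15,
                              seed = 1, mutate = FALSE,
                              accept = c("pooled", "final"),
                              verbose = FALSE) {
  rule <- match.arg(rule)
  accept <- match.arg(accept)
  rounds <- list()
  for (rd in seq_len(max_rounds)) {
    surface <- evaluate_grid(grid, obs, config, max_tmrca_years,
                             reps = reps, seed = seed, round = rd,
                             mutate = mutate)
    ok <- !surface$excluded
    if (!any(ok))
      stop("all scenarios excluded by the TMRCA bound (", max_tmrca_years,
           " years); widen the grid or the bound")
    frac_fit <- mean(surface$and[ok] < and_cutoff, na.rm = TRUE)
    rounds[[rd]] <- list(grid = grid, surface = surface, frac_fit = frac_fit)
    if (verbose)
      message(sprintf("round %2d: min AND = %.4f, %4.1f%% of %d cells < %.2f",
                      rd, suppressWarnings(min(surface$and[ok], na.rm = TRUE)),
                      100 * frac_fit, sum(ok), and_cutoff))
    if (frac_fit >= stop_frac) break
    if (rd < max_rounds)
      grid <- refine_grid(surface, grid, rule = rule, keep_frac = keep_frac,
                          and_cutoff = and_cutoff,
                          retain_factor = retain_factor, min_keep = min_keep,
                          n_points = max(lengths(grid$axes)))
  }
  pool <- if (accept == "final") {
    rounds[[length(rounds)]]$surface
  } else {
    do.call(rbind, lapply(rounds, `[[`, "surface"))
  }
  acc <- pool[!pool$excluded & is.finite(pool$and) &
                pool$and < and_cutoff, , drop = FALSE]
  acc <- acc[!duplicated(acc[, c("start_n", "end_n", "t_end_years",
                                 "duration_years")]), , drop = FALSE]
  if (nrow(acc) == 0)
    stop("search did not find any scenario with AND < ", and_cutoff,
         " after ", length(rounds), " rounds (best: ",
         signif(min(pool$and[!pool$excluded], na.rm = TRUE), 3), ")")
  structure(list(rounds = rounds, accepted = acc,
                 summaries = summarize_accepted(acc),
                 converged = rounds[[length(rounds)]]$frac_fit >= stop_frac,
                 n_rounds = length(rounds), and_cutoff = and_cutoff,
                 accept = accept, reps = reps, seed = seed,
                 max_tmrca_years = max_tmrca_years),
            class = "expansion_search")
}

#' Summaries of the accepted parameter combinations
#'
#' For each of the four parameters: the frequency histogram of the accepted
#' cells' axis values (each accepted cell counting once), the median, and
#' the 2.5–97.5 percentile interval.
#'
#' @param accepted Data frame of accepted cells (rows of a `fit_surface`).
#' @return Named list per parameter with `median`, `interval`, `values` and
#'   `histogram` (a `table`).
#' @export
summarize_accepted <- function(accepted) {
  if (nrow(accepted) == 0) stop("empty accepted set")
  pars <- c("start_n", "end_n", "t_end_years", "duration_years")
  out <- lapply(pars, function(p) {
    v <- accepted[[p]]
    list(median = stats::median(v),
         interval = unname(stats::quantile(v, c(0.025, 0.975))),
         values = v,
         histogram = table(signif(v, 6)))
  })
  names(out) <- pars
  out
}

#' @export
print.expansion_search <- function(x, ...) {
  cat(sprintf("expansion_search: %d round(s), %d accepted cells (AND < %g)%s\n",
              x$n_rounds, nrow(x$accepted), x$and_cutoff,
              if (x$converged) "" else " [max rounds reached]"))
  for (p in names(x$summaries)) {
    s <- x$summaries[[p]]
    cat(sprintf("  %-15s median %10.4g  95%% interval [%.4g, %.4g]\n",
                p, s$median, s$interval[1], s$interval[2]))
  }
  invisible(x)
}
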