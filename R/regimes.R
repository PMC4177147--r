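#' Continental expansion regimes for recovery experiments
#'
#' Pre-packaged experiment specifications whose generating models are the
#' fitted point estimates for the two contrasting Neolithic male expansions:
#'
#' * **Europe** (R1b-like): 2 men growing to 9,500 over 325 years, ending
#'   12,000 years ago; 6 sampled chromosomes. An explosive, star-producing
#'   regime.
#' * **Africa** (E1b1a-like): 40 men growing to 2,000 over 12,000 years,
#'   ending 2,000 years ago; 8 sampled chromosomes. A slower expansion
#'   leaving a bifurcating tree with greater time depth.
#'
#' Generating synthetic observations from these regimes and re-fitting them
#' with [fit_expansion()] is the package's end-to-end parameter-recovery
#' check, and doubles as a qualitative contrast of the two continental
#' tree shapes.
#'
#' @param reps Simulations per scenario used when the experiment is
#'   searched.
#' @return An object of class `experiment_spec`: a list with `name`,
#'   `model` (the generating [expansion_model()]) and `config`
#'   (a [sim_config()]).
#' @examples
#' europe_regime_spec()$model
#' @export
europe_regime_spec <- function(reps = 1000) {
  structure(list(name = "europe",
                 model = expansion_model(start_n = 2, end_n = 9500,
                                         t_end_years = 12000,
                                         duration_years = 325),
                 config = sim_config(n_tips = 6, reps = reps)),
            class = "experiment_spec")
}

#' @rdname europe_regime_spec
#' @export
africa_regime_spec <- function(reps = 1000) {
  structure(list(name = "africa",
                 model = expansion_model(start_n = 40, end_n = 2000,
                                         t_end_years = 2000,
                                         duration_years = 12000),
                 config = sim_config(n_tips = 8, reps = reps)),
            class = "experiment_spec")
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat("experiment_spec:", x$name, "\n")
  print(x$model)
  print(x$config)
  invisible(x)
}

#' Generate a synthetic observation for a recovery experiment
#'
#' Draws a synthetic observed SNP tree from the spec's generating model
#' ([make_synthetic_observed()]), collapses zero-variant internal branches
#' (as an observed SNP tree would show them), and computes the observed
#' statistic triple. Two kinds of draw are discarded and redrawn
#' deterministically: trees with no internal variants at all (infinite r,
#' unusable as an observation — the empirical trees all have at least one
#' shared variant), and trees whose mutation-clock TMRCA is younger than the
#' generating model's expansion start. The latter keeps the experiment
#' well-posed: the search bounds its time axes by the observed tree's
#' TMRCA, and the generating model must lie inside those bounds for
#' recovery to be meaningful. The number of discarded draws is reported.
#'
#' @param spec An `experiment_spec` from [europe_regime_spec()] or
#'   [africa_regime_spec()].
#' @param seed Integer seed; the whole result is deterministic in it.
#' @param max_attempts Redraw limit before giving up.
#' @return A list with `tree` (the observed SNP tree), `obs` (its
#'   [tree_stats()] triple), `tmrca_years` ([empirical_tmrca_years()]),
#'   `spec`, `seed` and `n_discarded`.
#' @examples
#' ex <- generate_experiment(africa_regime_spec(), seed = 1)
#' ex$obs
#' @export
generate_experiment <- function(spec, seed, max_attempts = 1000) {
  stopifnot(inherits(spec, "experiment_spec"))
  for (attempt in 0:max_attempts) {
    tree <- make_synthetic_observed(spec$model, spec$config,
                                    seed = seed + 7919L * attempt)
    tree <- collapse_zero_branches(tree)
    if (total_branch_length(tree) == 0) next
    st <- tree_stats(tree)
    if (!all(is.finite(st))) next
    tmrca <- empirical_tmrca_years(tree, spec$config)
    if (tmrca >= spec$model$t_end_years + spec$model$duration_years) {
      return(list(tree = tree, obs = st, tmrca_years = tmrca,
                  spec = spec, seed = seed, n_discarded = attempt))
    }
  }
  stop("no usable observation in ", max_attempts, " draws")
}
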