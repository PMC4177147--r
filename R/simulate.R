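#' Simulate a coalescent genealogy
#'
#' Draws one genealogy of `config$n_tips` lineages under the variable-size
#' Kingman coalescent defined by an [expansion_model()]. Waiting times come
#' from [coalescent_waiting_time()]; at each coalescence a pair of lineages
#' is chosen uniformly at random. The result is an ultrametric rooted binary
#' tree with branch lengths in generations. Randomness is taken from R's
#' global RNG stream, so `set.seed()` controls reproducibility.
#'
#' @param model An [expansion_model()].
#' @param config A [sim_config()].
#' @return A rooted `phylo` tree with `config$n_tips` tips labelled
#'   `t1 ... tn` and branch lengths in generations.
#' @examples
#' set.seed(1)
#' tr <- simulate_genealogy(expansion_model(1000, 1000, 0, 0), sim_config(6))
#' @seealso [sprinkle_mutations()], [make_synthetic_observed()],
#'   [scenario_stats()] for the fast many-replicate path.
#' @export
simulate_genealogy <- function(model, config) {
  stopifnot(inherits(model, "expansion_model"), inherits(config, "sim_config"))
  n <- config$n_tips
  sub <- paste0("t", seq_len(n))
  rtime <- numeric(n)
  t <- 0
  for (k in n:2) {
    u <- stats::runif(1)
    t <- t + coalescent_waiting_time(k, model, t, u, config$gen_years)
    npairs <- k * (k - 1) / 2
    idx <- floor(stats::runif(1) * npairs)
    if (idx >= npairs) idx <- npairs - 1
    i <- 0                     # lexicographic 0-based pair (i < j)
    repeat {
      cnt <- k - 1 - i
      if (idx < cnt) { j <- i + 1 + idx; break }
      idx <- idx - cnt
      i <- i + 1
    }
    i <- i + 1
    j <- j + 1
    sub[i] <- sprintf("(%s:%.12g,%s:%.12g)",
                      sub[i], t - rtime[i], sub[j], t - rtime[j])
    rtime[i] <- t
    if (j != k) {             # swap-remove slot j, shrink active set to k - 1
      sub[j] <- sub[k]
      rtime[j] <- rtime[k]
    }
  }
  ape::read.tree(text = paste0(sub[1], ";"))
}

#' Drop mutations onto a genealogy
#'
#' Replaces each branch length (in generations) by an infinite-sites variant
#' count: an independent Poisson draw with mean
#' `length * config$mu * config$seq_len`. At the default constants this is
#' 0.264 expected variants per generation of branch.
#'
#' @param tree A `phylo` tree with branch lengths in generations.
#' @param config A [sim_config()].
#' @return The tree with integer SNP-count branch lengths.
#' @examples
#' set.seed(1)
#' g <- simulate_genealogy(expansion_model(1000, 1000, 0, 0), sim_config(6))
#' sprinkle_mutations(g, sim_config(6))
#' @export
sprinkle_mutations <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  tree$edge.length <- stats::rpois(length(tree$edge.length),
                                   tree$edge.length * config$mu * config$seq_len)
  tree
}

#' Generate a synthetic observed tree
#'
#' Simulates a genealogy under `model` and converts it to a SNP-count tree
#' with [sprinkle_mutations()], emulating an observed haplogroup phylogeny
#' built from fully sequenced chromosomes. Deterministic for a given `seed`.
#'
#' @param model An [expansion_model()].
#' @param config A [sim_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `phylo` tree with integer SNP-count branch lengths.
#' @examples
#' make_synthetic_observed(expansion_model(40, 2000, 2000, 12000),
#'                         sim_config(8), seed = 1)
#' @export
make_synthetic_observed <- function(model, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sprinkle_mutations(simulate_genealogy(model, config), config)
}

#' Per-replicate tree statistics for a demographic scenario
#'
#' The fast path used by the grid search: simulates `reps` genealogies under
#' `model` in compiled code and returns the three summary statistics of each
#' replicate, computed on the tree normalised to total branch length 1,
#' together with the unnormalised TMRCA and total length. With
#' `mutate = TRUE` the statistics are instead computed on Poisson variant
#' counts (as [sprinkle_mutations()] would produce); replicates whose trees
#' carry no variants at all then yield `NA` statistics, and trees with no
#' internal variants yield `r = Inf`.
#'
#' The compiled path consumes R's RNG stream exactly as
#' [simulate_genealogy()] does (for `mutate = FALSE`), so seed-matched
#' replicates agree with the plain-R simulator to numerical round-off.
#'
#' @param model An [expansion_model()].
#' @param config A [sim_config()].
#' @param reps Number of replicates; defaults to `config$reps`.
#' @param mutate Compute statistics on Poisson-mutated SNP trees instead of
#'   genealogy branch lengths.
#' @return A `reps` x 5 matrix with columns `r`, `tmrca_mean`, `tmrca_sd`,
#'   `tmrca_gen`, `total_len`.
#' @examples
#' set.seed(1)
#' colMeans(scenario_stats(expansion_model(1000, 1000, 0, 0),
#'                         sim_config(6), reps = 100))
#' @export
scenario_stats <- function(model, config, reps = config$reps, mutate = FALSE) {
  stopifnot(inherits(model, "expansion_model"), inherits(config, "sim_config"))
  g <- config$gen_years
  cpp_scenario_stats(config$n_tips, model$start_n, model$end_n,
                     model$t_end_years / g, model$duration_years / g,
                     as.integer(reps), isTRUE(mutate),
                     config$mu * config$seq_len)
}
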