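#' Four-parameter single-expansion demographic model
#'
#' Describes one exponential change in male effective population size, the
#' demography fitted throughout this package. Forward in time the population
#' holds at `start_n` men, grows (or shrinks) exponentially to `end_n` men
#' over `duration_years`, finishing `t_end_years` before the present, and
#' then holds at `end_n` until today.
#'
#' Backwards in time, with `t` in generations before present and
#' `g = t_end_years / gen_years`, `d = duration_years / gen_years`:
#' \deqn{N(t) = \mathrm{end\_n}, \quad t \in [0, g)}
#' \deqn{N(t) = \mathrm{end\_n}\, e^{-\beta (t - g)}, \quad
#'       \beta = \log(\mathrm{end\_n}/\mathrm{start\_n})/d, \quad
#'       t \in [g, g + d)}
#' \deqn{N(t) = \mathrm{start\_n}, \quad t \ge g + d}
#'
#' Sizes are counts of men (a haploid Y-chromosome coalescent: a pair of
#' lineages coalesces at rate \eqn{1/N(t)} per generation). `duration_years
#' = 0` means an instantaneous size change; `start_n == end_n` means a
#' constant-size population.
#'
#' @param start_n Ancestral male effective population size (men, >= 1).
#' @param end_n Final male effective population size (men, >= 1).
#' @param t_end_years Time before present at which the expansion ended
#'   (years, >= 0).
#' @param duration_years Length of the expansion (years, >= 0).
#' @return An object of class `expansion_model`.
#' @examples
#' expansion_model(start_n = 2, end_n = 9500,
#'                 t_end_years = 12000, duration_years = 325)
#' @seealso [population_size_at()], [simulate_genealogy()], [fit_expansion()]
#' @export
expansion_model <- function(start_n, end_n, t_end_years, duration_years) {
  vals <- c(start_n = start_n, end_n = end_n, t_end_years = t_end_years,
            duration_years = duration_years)
  if (!all(is.finite(vals))) stop("all model parameters must be finite")
  if (start_n < 1 || end_n < 1) stop("population sizes must be >= 1")
  if (t_end_years < 0 || duration_years < 0) stop("times must be >= 0")
  structure(as.list(vals), class = "expansion_model")
}

#' @export
print.expansion_model <- function(x, ...) {
  cat("Single-expansion demographic model\n")
  cat(sprintf("  start size: %g men   end size: %g men\n", x$start_n, x$end_n))
  cat(sprintf("  expansion: %g years, ending %g years before present\n",
              x$duration_years, x$t_end_years))
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles the biological constants and sampling settings used by the
#' coalescent simulator. The defaults are the constants used for the
#' Y-chromosome haplogroup analyses: 8.8 Mb of callable sequence, a mutation
#' rate of 3e-8 per nucleotide per generation (0.264 expected variants per
#' generation of branch length), a 30-year generation time, and zero
#' recombination (the simulator has no recombination machinery at all).
#'
#' @param n_tips Number of sampled chromosomes (6 for the R1b example,
#'   8 for E1b1a).
#' @param seq_len Callable sequence length in nucleotides.
#' @param mu Mutation rate per nucleotide per generation.
#' @param gen_years Generation time in years.
#' @param reps Simulated genealogies per demographic scenario.
#' @param seed Optional integer seed recorded with the configuration.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(n_tips = 6)
#' @export
sim_config <- function(n_tips, seq_len = 8.8e6, mu = 3e-8, gen_years = 30,
                       reps = 1000, seed = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (seq_len <= 0 || mu < 0 || gen_years <= 0 || reps < 1)
    stop("seq_len and gen_years must be positive, mu >= 0, reps >= 1")
  structure(list(n_tips = as.integer(n_tips), seq_len = seq_len, mu = mu,
                 gen_years = gen_years, reps = as.integer(reps), seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d tips, %.3g nt, mu = %.3g /nt/gen, %g y/gen, %d reps\n",
    x$n_tips, x$seq_len, x$mu, x$gen_years, x$reps))
  invisible(x)
}

#' Population size at a time in the past
#'
#' Evaluates the piecewise size function of an [expansion_model()] at times
#' given in generations before present.
#'
#' @param model An [expansion_model()].
#' @param t Vector of times in generations before present (>= 0).
#' @param gen_years Generation time used to convert the model's year-based
#'   epochs to generations.
#' @return Numeric vector of male effective population sizes.
#' @examples
#' m <- expansion_model(2, 9500, 12000, 325)
#' population_size_at(m, c(0, 400, 500))
#' @export
population_size_at <- function(model, t, gen_years = 30) {
  stopifnot(inherits(model, "expansion_model"))
  if (any(t < 0)) stop("t must be non-negative")
  g_end <- model$t_end_years / gen_years
  g_dur <- model$duration_years / gen_years
  beta <- if (g_dur > 0) log(model$end_n / model$start_n) / g_dur else 0
  ifelse(t < g_end, model$end_n,
         ifelse(t < g_end + g_dur,
                model$end_n * exp(-beta * (t - g_end)),
                model$start_n))
}

#' Coalescent waiting time under the expansion model
#'
#' Inverse-CDF sample of the time until the next coalescence among `k`
#' lineages, starting from `t0` generations before present. The pairwise
#' coalescence rate is \eqn{\binom{k}{2}/N(t)} per generation; the target
#' cumulative hazard \eqn{-\log(u)} is inverted in closed form within each
#' epoch of the size function, carrying residual hazard across epoch
#' boundaries.
#'
#' @param k Number of extant lineages (>= 2).
#' @param model An [expansion_model()].
#' @param t0 Current time in generations before present.
#' @param u A uniform(0, 1) draw.
#' @param gen_years Generation time in years.
#' @return Waiting time in generations (a single non-negative number).
#' @examples
#' m <- expansion_model(1000, 1000, 0, 0)
#' coalescent_waiting_time(2, m, 0, 0.5)  # median of Exp(1/1000)
#' @export
coalescent_waiting_time <- function(k, model, t0, u, gen_years = 30) {
  stopifnot(inherits(model, "expansion_model"))
  if (k < 2) stop("k must be >= 2")
  if (t0 < 0) stop("t0 must be non-negative")
  if (!is.finite(u) || u <= 0 || u >= 1) stop("u must lie strictly in (0, 1)")
  cc <- k * (k - 1) / 2
  H <- -log(u)
  g_end <- model$t_end_years / gen_years
  g_dur <- model$duration_years / gen_years
  beta <- if (g_dur > 0) log(model$end_n / model$start_n) / g_dur else 0
  t <- t0
  if (t < g_end) {
    rate <- cc / model$end_n
    h_full <- rate * (g_end - t)
    if (H <= h_full) return(t + H / rate - t0)
    H <- H - h_full
    t <- g_end
  }
  b2 <- g_end + g_dur
  if (t < b2) {
    if (abs(beta) < 1e-14) {
      rate <- cc / model$end_n
      h_full <- rate * (b2 - t)
      if (H <= h_full) return(t + H / rate - t0)
      H <- H - h_full
    } else {
      e0 <- exp(beta * (t - g_end))
      eb <- exp(beta * (b2 - g_end))
      h_full <- cc / (model$end_n * beta) * (eb - e0)
      if (H <= h_full) {
        s <- log(e0 + H * model$end_n * beta / cc) / beta - (t - g_end)
        return(t + s - t0)
      }
      H <- H - h_full
    }
    t <- b2
  }
  t + H * model$start_n / cc - t0
}
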