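test_that("and_distance identity, arithmetic and propagation", {
  obs <- c(1, 0.5, 0.1)
  expect_equal(and_distance(obs, obs), 0)
  expect_equal(and_distance(c(1.5, 0.4, 0.1), obs), (0.5 + 0.2 + 0) / 3)
  expect_identical(and_distance(c(Inf, 0.5, 0.1), obs), Inf)
  expect_error(and_distance(c(1, 1, 1), c(Inf, 0.5, 0.1)), "finite")
  expect_error(and_distance(c(1, 1, 1), c(1, -0.5, 0.1)), "finite|positive")
  expect_error(and_distance(c(1, 1), obs), "three")
})

test_that("empirical TMRCA inverts the mutation clock", {
  cfg <- sim_config(3)
  # mean root-to-tip of 100 SNPs at 0.264 SNPs/generation and 30 y/gen
  tr <- parse_newick("(A:100,B:100,C:100);")
  expect_equal(empirical_tmrca_years(tr, cfg), 100 / 0.264 * 30,
               tolerance = 1e-9)
  # g generations' worth of SNPs maps back to 30 g years
  g <- 417
  tr2 <- parse_newick(sprintf("(A:%g,B:%g,C:%g);", g * 0.264, g * 0.264,
                              g * 0.264))
  expect_equal(empirical_tmrca_years(tr2, cfg), g * 30, tolerance = 1e-9)
  # doubling the sequence length halves the estimate
  cfg2 <- sim_config(3, seq_len = 2 * 8.8e6)
  expect_equal(empirical_tmrca_years(tr, cfg2),
               empirical_tmrca_years(tr, cfg) / 2)
  expect_error(empirical_tmrca_years(parse_newick("(A:0,B:0);"), sim_config(2)),
               "degenerate")
})

test_that("TMRCA compatibility gates on the expansion start, inclusively", {
  expect_true(tmrca_compatible(expansion_model(2, 9500, 12000, 300), 13000))
  expect_false(tmrca_compatible(expansion_model(2, 9500, 12000, 3000), 13000))
  expect_true(tmrca_compatible(expansion_model(2, 9500, 13000, 0), 13000))
  expect_error(tmrca_compatible(expansion_model(2, 9500, 0, 0), -1), "positive")
})

test_that("evaluate_scenario with reps = 1 is the single replicate", {
  m <- expansion_model(300, 300, 0, 0)
  cfg <- sim_config(6)
  obs <- c(r = 2, tmrca_mean = 0.2, tmrca_sd = 0.05)
  ev <- evaluate_scenario(m, obs, cfg, reps = 1, seed = 9, mutate = FALSE)
  set.seed(9)
  one <- scenario_stats(m, cfg, reps = 1)[1, 1:3]
  expect_equal(unname(ev$stats), unname(one))
  expect_equal(ev$and, and_distance(one, obs))
})

test_that("a scenario fits itself: AND = 0 against its own averages", {
  m <- expansion_model(40, 2000, 2000, 12000)
  cfg <- sim_config(8)
  ev1 <- evaluate_scenario(m, c(1, 1, 1), cfg, reps = 100, seed = 4)
  ev2 <- evaluate_scenario(m, ev1$stats, cfg, reps = 100, seed = 4)
  expect_equal(ev2$and, 0, tolerance = 1e-12)
  expect_equal(ev2$stats, ev1$stats)
})

test_that("evaluate_grid flags TMRCA-incompatible cells and is reproducible", {
  grid <- param_grid(start_n = c(10, 100), end_n = 1000,
                     t_end_years = c(1000, 9000), duration_years = c(3000))
  obs <- c(2, 0.2, 0.05)
  cfg <- sim_config(6)
  s1 <- evaluate_grid(grid, obs, cfg, max_tmrca_years = 8000, reps = 50,
                      seed = 2)
  expect_equal(nrow(s1), 4)
  expect_equal(s1$excluded, c(FALSE, FALSE, TRUE, TRUE))  # 9000+3000 > 8000
  expect_true(all(is.na(s1$and[s1$excluded])))
  expect_true(all(is.finite(s1$and[!s1$excluded])))
  s2 <- evaluate_grid(grid, obs, cfg, max_tmrca_years = 8000, reps = 50,
                      seed = 2)
  expect_identical(s1, s2)
  # a 1x1x1x1 grid reproduces evaluate_scenario at the derived cell seed
  g1 <- param_grid(40, 2000, 2000, 3000)
  s3 <- evaluate_grid(g1, obs, cfg, max_tmrca_years = 2e4, reps = 50, seed = 7)
  ev <- evaluate_scenario(expansion_model(40, 2000, 2000, 3000), obs, cfg,
                          reps = 50, seed = coalexp:::cell_seed(7, 1, 1))
  expect_equal(s3$and, ev$and)
})

test_that("refine_grid narrows around an interior minimum", {
  grid <- default_grid(15000)
  cells <- expand.grid(grid$axes, KEEP.OUT.ATTRS = FALSE)
  and <- rep(1, nrow(cells))
  target <- cells$start_n == grid$axes$start_n[3] &
    cells$end_n == grid$axes$end_n[3] &
    cells$t_end_years == grid$axes$t_end_years[3] &
    cells$duration_years == grid$axes$duration_years[3]
  and[target] <- 0.01
  surface <- cbind(cells, and = and, excluded = FALSE)
  out <- refine_grid(surface, grid, rule = "threshold", min_keep = 1)
  for (nm in names(out$axes)) {
    expect_lte(min(out$axes[[nm]]), grid$axes[[nm]][3])
    expect_gte(max(out$axes[[nm]]), grid$axes[[nm]][3])
    # narrowed: new range inside old range extended by one step
    expect_gte(min(out$axes[[nm]]), min(grid$axes[[nm]]) * 0.99 - 1e-9)
    expect_lt(diff(range(out$axes[[nm]])), diff(range(grid$axes[[nm]])))
  }
})

test_that("refine_grid extends past a boundary minimum up to global bounds", {
  grid <- param_grid(start_n = c(10, 100, 1000), end_n = c(1000, 2000),
                     t_end_years = c(0, 5000), duration_years = c(100, 1000),
                     bounds = list(start_n = c(1, 5000), end_n = c(100, 1e5),
                                   t_end_years = c(0, 2e4),
                                   duration_years = c(30, 2e4)))
  cells <- expand.grid(grid$axes, KEEP.OUT.ATTRS = FALSE)
  and <- rep(1, nrow(cells))
  and[cells$start_n == 10] <- 0.01  # minimum on the low start_n edge
  surface <- cbind(cells, and = and, excluded = FALSE)
  out <- refine_grid(surface, grid, rule = "threshold", min_keep = 1)
  expect_lt(min(out$axes$start_n), 10)   # pushed past the old edge
  expect_gte(min(out$axes$start_n), 1)   # but clipped to the global bound
})

test_that("refine_grid keeps ranges when every cell fits equally", {
  grid <- param_grid(start_n = c(10, 100), end_n = c(1000, 2000),
                     t_end_years = c(0, 5000), duration_years = c(100, 1000))
  cells <- expand.grid(grid$axes, KEEP.OUT.ATTRS = FALSE)
  surface <- cbind(cells, and = rep(0.02, nrow(cells)), excluded = FALSE)
  out <- refine_grid(surface, grid)
  for (nm in names(out$axes))
    expect_equal(range(out$axes[[nm]]), range(grid$axes[[nm]]),
                 tolerance = 1e-9)
  # and errors when nothing can be kept
  surface$and <- Inf
  expect_error(refine_grid(surface, grid), "refinement failed")
})

test_that("summarize_accepted computes order statistics per parameter", {
  acc <- data.frame(start_n = c(1, 2, 2, 3), end_n = 2000,
                    t_end_years = c(0, 0, 1000, 1000),
                    duration_years = c(5, 6, 7, 8))
  s <- summarize_accepted(acc)
  expect_equal(s$start_n$median, 2)
  expect_equal(s$end_n$median, 2000)
  expect_equal(s$end_n$interval, c(2000, 2000))
  expect_equal(as.numeric(s$end_n$histogram), 4)
  for (p in names(s)) {
    expect_gte(s[[p]]$median, s[[p]]$interval[1])
    expect_lte(s[[p]]$median, s[[p]]$interval[2])
  }
  expect_error(summarize_accepted(acc[0, ]), "empty")
})

test_that("sequential_search stops immediately on an all-fitting grid", {
  m <- expansion_model(40, 2000, 2000, 3000)
  cfg <- sim_config(6)
  # observe exactly what the search's first round will simulate (same
  # derived cell seed), so the single cell self-fits with AND = 0
  ev <- evaluate_scenario(m, c(1, 1, 1), cfg, reps = 200,
                          seed = coalexp:::cell_seed(31, 1, 1))
  g1 <- param_grid(40, 2000, 2000, 3000)
  res <- sequential_search(ev$stats, g1, cfg, max_tmrca_years = 2e4,
                           reps = 200, seed = 31)
  expect_equal(res$n_rounds, 1)
  expect_true(res$converged)
  expect_equal(nrow(res$accepted), 1)
  # all cells excluded is an error
  expect_error(
    sequential_search(ev$stats, param_grid(40, 2000, 9000, 9000), cfg,
                      max_tmrca_years = 8000, reps = 10, seed = 1),
    "excluded")
})
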