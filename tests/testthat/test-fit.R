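make_small_fit <- function() {
  # compact search around the African generating model so the whole fit
  # runs in a couple of seconds
  ex <- generate_experiment(africa_regime_spec(), seed = 3)
  grid <- param_grid(start_n = c(10, 40, 160), end_n = c(500, 2000, 8000),
                     t_end_years = c(0, 2000, 6000),
                     duration_years = c(3000, 12000),
                     bounds = list(start_n = c(1, 5000), end_n = c(100, 1e5),
                                   t_end_years = c(0, ex$tmrca_years),
                                   duration_years = c(30, ex$tmrca_years)))
  fit <- fit_expansion(ex$tree, grid = grid, reps = 150, seed = 5,
                       max_rounds = 4)
  list(ex = ex, fit = fit)
}

test_that("fit_expansion returns a working model object", {
  sf <- make_small_fit()
  fit <- sf$fit
  expect_s3_class(fit, "expansion_fit")
  expect_gte(nrow(fit$search$accepted), 1)
  expect_true(all(fit$search$accepted$and < 0.05))

  co <- coef(fit)
  expect_named(co, c("start_n", "end_n", "t_end_years", "duration_years"))
  for (p in names(co)) {
    iv <- fit$search$summaries[[p]]$interval
    expect_gte(co[[p]], iv[1])
    expect_lte(co[[p]], iv[2])
  }

  expect_output(print(fit), "accepted scenarios")
  expect_output(print(summary(fit)), "Median model")

  res <- residuals(fit)
  expect_named(res, c("r", "tmrca_mean", "tmrca_sd"))
  expect_true(all(abs(res) < 1))  # best cell fits every statistic closely

  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_s3_class(sims, "multiPhylo")
  expect_length(sims, 3)
  expect_equal(ape::Ntip(sims[[1]]), 8)

  m <- fitted_model(fit)
  expect_s3_class(m, "expansion_model")
  expect_equal(m$start_n, co[["start_n"]])
})

test_that("fit surfaces and search results can be exported", {
  sf <- make_small_fit()
  tsv <- tempfile(fileext = ".tsv")
  write_fit_surface(sf$fit, tsv)
  surf <- utils::read.delim(tsv)
  expect_true(all(c("start_n", "end_n", "t_end_years", "duration_years",
                    "r_s", "m_s", "d_s", "and", "excluded") %in% names(surf)))
  final_round <- sf$fit$search$n_rounds
  expect_equal(nrow(surf),
               nrow(sf$fit$search$rounds[[final_round]]$surface))
  first <- tempfile(fileext = ".tsv")
  write_fit_surface(sf$fit, first, round = 1)
  expect_equal(nrow(utils::read.delim(first)), 3 * 3 * 3 * 2)

  js <- tempfile(fileext = ".json")
  write_fit_json(sf$fit, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$reps, 150)
  expect_named(parsed$summaries,
               c("start_n", "end_n", "t_end_years", "duration_years"))
  expect_equal(length(parsed$grids), sf$fit$search$n_rounds)

  png_path <- tempfile(fileext = ".png")
  grDevices::png(png_path)
  plot(sf$fit, which = "hist")
  plot(sf$fit, which = "surface")
  grDevices::dev.off()
  expect_true(file.exists(png_path))
})

test_that("fit_expansion validates its inputs", {
  star <- parse_newick("(A:100,B:110,C:95);")
  expect_error(fit_expansion(star), "star")
  tr <- generate_experiment(africa_regime_spec(), seed = 1)$tree
  expect_error(fit_expansion(tr, config = sim_config(6)), "does not match")
})

test_that("tree_stats_report flags near-star structure", {
  out <- utils::capture.output(
    rep <- tree_stats_report(haplogroup_fixture("R1b")))
  expect_true(any(grepl("near-star", out)))
  expect_equal(rep$n_tips, 6)
  expect_equal(rep$n_internal_branches, 1)
  expect_equal(rep$stats, tree_stats(haplogroup_fixture("R1b")))
})
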