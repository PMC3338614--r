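# The nine-strength promoter-library grid used by the reporter assay.
library_grid <- c(0.07, 0.11, 0.16, 0.25, 0.32, 0.49, 0.68, 0.95, 1.17)

test_that("hill_signal evaluates the model and its limits", {
  expect_equal(hill_signal(0.3, 100, 20, 0.3, 1), 60)   # halfway at the IC50
  expect_equal(hill_signal(0, 100, 20, 0.3, 1), 100)    # no competition: Top
  expect_equal(hill_signal(0.6, 100, 20, 0.3, 2), 36)   # 20 + 80/5
  expect_error(hill_signal(-0.1, 100, 20, 0.3), "ps")
  expect_error(hill_signal(0.3, 100, 20, -1), "ic50")
})

test_that("hill_signal is strictly decreasing in PS whenever top > bottom", {
  withr::with_seed(42, {
    for (i in 1:25) {
      top <- runif(1, 10, 200)
      bottom <- runif(1, 0, top - 1)
      ic50 <- runif(1, 0.05, 2)
      h <- runif(1, 0.3, 5)
      y <- hill_signal(seq(0, 3, length.out = 40), top, bottom, ic50, h)
      expect_true(all(diff(y) < 0))
    }
  })
})

test_that("noise-free curves are recovered to high relative accuracy", {
  for (pars in list(c(100, 20, 0.3, 1), c(5000, 300, 0.6, 2),
                    c(80, 0, 0.15, 0.7))) {
    d <- simulate_dose_response(pars[1], pars[2], pars[3], pars[4],
                                ps_grid = c(0.07, 0.16, 0.32, 0.68, 0.95),
                                noise_sd = 0)
    f <- fit_hill(d$ps, d$signal)
    expect_true(f$converged)
    expect_equal(f$top, pars[1], tolerance = 1e-6)
    expect_equal(f$bottom, pars[2], tolerance = 1e-6 * max(1, pars[2]))
    expect_equal(f$ic50, pars[3], tolerance = 1e-6)
    expect_equal(f$h, pars[4], tolerance = 1e-6)
    expect_lt(f$rss, 1e-9 * (pars[1] - pars[2])^2)
  }
})

test_that("degenerate inputs follow the contract", {
  expect_error(fit_hill(c(0.1, 0.2, 0.3), c(5, 4, 3)), "4 distinct")
  flat <- fit_hill(c(0.07, 0.16, 0.32, 0.68, 0.95), rep(50, 5))
  expect_false(flat$converged)
  expect_true(is.na(flat$ic50))
})

test_that("PS rescaling rescales the IC50 and nothing else", {
  d <- simulate_dose_response(100, 20, 0.3, h = 1.5,
                              ps_grid = c(0.07, 0.16, 0.32, 0.68, 0.95),
                              noise_sd = 1, seed = 11)
  f1 <- fit_hill(d$ps, d$signal)
  for (c_scale in c(0.5, 4)) {
    f2 <- fit_hill(d$ps * c_scale, d$signal)
    expect_equal(f2$ic50, f1$ic50 * c_scale, tolerance = 1e-5)
    expect_equal(f2$top, f1$top, tolerance = 1e-5)
    expect_equal(f2$bottom, f1$bottom, tolerance = 1e-5)
    expect_equal(f2$h, f1$h, tolerance = 1e-5)
  }
})

test_that("optimiser matches a dense brute-force grid search on small curves", {
  withr::with_seed(8, {
    for (i in 1:3) {
      d <- simulate_dose_response(100, 20, 0.35, h = 1,
                                  ps_grid = c(0.07, 0.16, 0.32, 0.68, 0.95),
                                  n_replicates = 1, noise_sd = 3, seed = 100 + i)
      f <- fit_hill(d$ps, d$signal)
      g <- hill_grid_oracle(d$ps, d$signal,
                            top_grid = seq(70, 140, by = 1),
                            bottom_grid = seq(0, 50, by = 1),
                            ic_grid = exp(seq(log(0.03), log(3), length.out = 80)),
                            h_grid = exp(seq(log(0.2), log(5), length.out = 40)))
      # the continuous optimiser must do at least as well as the grid
      expect_lte(f$rss, g$rss * (1 + 1e-6))
    }
  })
})

test_that("IC50 is recoverable from noisy curves at the assay's design", {
  errs <- vapply(1:200, function(s) {
    d <- simulate_dose_response(100, 20, 0.3, ps_grid = library_grid,
                                noise_sd = 0.02 * 80, seed = s)
    f <- fit_hill(d$ps, d$signal)
    abs(f$ic50 - 0.3) / 0.3
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("fixing the Hill slope is supported", {
  d <- simulate_dose_response(100, 20, 0.3, h = 1, noise_sd = 0)
  f <- fit_hill(d$ps, d$signal, fix_slope = 1)
  expect_equal(f$h, 1)
  expect_equal(f$ic50, 0.3, tolerance = 1e-6)
  expect_error(fit_hill(d$ps, d$signal, fix_slope = -1), "fix_slope")
})

test_that("compare_ic50: identity, constructed dosage ratio, and state errors", {
  d <- simulate_dose_response(100, 20, 0.3, ps_grid = library_grid, noise_sd = 0)
  f <- fit_hill(d$ps, d$signal)
  expect_equal(compare_ic50(f, f)$ratio, 1)

  d2 <- simulate_dose_response(100, 20, 0.6, ps_grid = library_grid, noise_sd = 0)
  f2 <- fit_hill(d2$ps, d2$signal)
  expect_equal(compare_ic50(f, f2)$ratio, 2, tolerance = 1e-6)

  flat <- fit_hill(c(0.07, 0.16, 0.32, 0.68, 0.95), rep(1, 5))
  expect_error(compare_ic50(f, flat), "converged")
})

test_that("paired noisy haploid/diploid fits cover the dosage ratio of 2", {
  ratios <- vapply(1:100, function(s) {
    a <- fit_hill(simulate_dose_response(100, 20, 0.3, ps_grid = library_grid,
                                         noise_sd = 1.6, seed = s))
    b <- fit_hill(simulate_dose_response(100, 20, 0.6, ps_grid = library_grid,
                                         noise_sd = 1.6, seed = s + 10000))
    if (a$converged && b$converged) compare_ic50(a, b)$ratio else NA_real_
  }, numeric(1))
  q <- quantile(ratios, c(0.025, 0.975), na.rm = TRUE)
  expect_lt(q[1], 2)
  expect_gt(q[2], 2)
  expect_equal(median(ratios, na.rm = TRUE), 2, tolerance = 0.15)
})

test_that("dose-response CSV and JSON fit round-trips work", {
  d <- withr::local_tempdir()
  curve <- simulate_dose_response(100, 20, 0.3, noise_sd = 0)
  write_table_commented(curve, file.path(d, "dr.csv"))
  back <- read_dose_response(file.path(d, "dr.csv"))
  expect_equal(back$signal, curve$signal)
  f <- fit_hill(back$ps, back$signal)
  write_hill_fit(f, file.path(d, "fit.json"))
  j <- jsonlite::read_json(file.path(d, "fit.json"))
  expect_equal(j$ic50, 0.3, tolerance = 1e-6)
  expect_true(j$converged)
})
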