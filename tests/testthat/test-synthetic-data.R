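test_that("archetype means follow the residual-activity model exactly", {
  cfg <- synth_config(n_ca_up = 1, n_ca_down = 0, n_nca = 0, n_fn = 0,
                      n_opp = 0, n_null = 0, ps_grid = c(0.07, 0.3, 0.68, 0.95),
                      noise_sd = 0, k_range = c(0.3 - 1e-9, 0.3 + 1e-9),
                      hill_slope = 1)
  ds <- simulate_expression(cfg)
  # at PS = K_g the response is exactly half the asymptotic effect
  v <- ds$expr["g0001", condition_samples(ds, "MUTANT", 0.3)]
  expect_equal(unname(v), rep(8 + 2 / 2, 3), tolerance = 1e-6)
  expect_equal(unname(ds$expr["g0001", condition_samples(ds, "KNOCKOUT")]),
               rep(10, 3))
  expect_equal(unname(ds$expr["g0001", condition_samples(ds, "CONTROL")]),
               rep(8, 3))
})

test_that("noise-free archetypes have the constructed shapes", {
  ds <- tiny_dataset(ps_grid = c(0.07, 0.16, 0.32, 0.68, 0.95))
  tr <- ds$truth
  ps <- c(0.07, 0.16, 0.32, 0.68, 0.95)
  level_means <- function(gene) {
    vapply(ps, function(p) mean(ds$expr[gene, condition_samples(ds, "MUTANT", p)]),
           numeric(1))
  }
  ko_mean <- function(gene) mean(ds$expr[gene, condition_samples(ds, "KNOCKOUT")])

  for (i in seq_len(nrow(tr))) {
    m <- level_means(tr$gene_id[i])
    switch(tr$archetype[i],
      CA_UP = {
        expect_true(all(diff(m) > 0))  # strictly monotone in PS
        # asymptote (PS -> Inf) equals the knockout mean
        expect_equal(8 + 2, ko_mean(tr$gene_id[i]))
      },
      CA_DOWN = expect_true(all(diff(m) < 0)),
      NCA = {
        expect_equal(m, rep(8, 5))  # flat across the titration
        expect_equal(abs(ko_mean(tr$gene_id[i]) - 8), 2)
      },
      FN = {
        expect_true(all(diff(m) != 0))
        expect_equal(ko_mean(tr$gene_id[i]), 8)  # compensated in the knockout
      },
      OPP = {
        expect_true(all(diff(m) > 0))
        expect_equal(ko_mean(tr$gene_id[i]), 8 - 2)  # opposite side
      },
      "NULL" = expect_equal(m, rep(8, 5)))
  }
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- synth_config(n_ca_up = 5, n_null = 5, noise_sd = 0.3, seed = 99)
  expect_identical(simulate_expression(cfg)$expr, simulate_expression(cfg)$expr)
  d1 <- simulate_dose_response(100, 20, 0.3, noise_sd = 2, seed = 7)
  d2 <- simulate_dose_response(100, 20, 0.3, noise_sd = 2, seed = 7)
  expect_identical(d1, d2)
  g1 <- simulate_growth_curves(c(a = 0.3, b = 0.4), noise_sd = 0.02, seed = 3)
  g2 <- simulate_growth_curves(c(a = 0.3, b = 0.4), noise_sd = 0.02, seed = 3)
  expect_identical(g1, g2)
  # a generator call must not disturb the session RNG
  set.seed(123); before <- .Random.seed
  invisible(simulate_expression(cfg))
  expect_identical(before, .Random.seed)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(synth_config(n_ca_up = -1), "n_ca_up")
  expect_error(synth_config(ps_grid = c(0.3, 0.2)), "ps_grid")
  expect_error(synth_config(ps_grid = c(0, 0.5)), "ps_grid")
  expect_error(synth_config(n_replicates = 1), "n_replicates")
  expect_error(synth_config(noise_sd = -0.1), "noise_sd")
  expect_error(synth_config(k_range = c(0.5, 0.1)), "k_range")
  expect_error(synth_config(effect_log2 = 0), "effect_log2")
})

test_that("dose-response generator honours the model and its contract", {
  d <- simulate_dose_response(100, 20, 0.3, noise_sd = 0, n_replicates = 1)
  expect_equal(d$signal[d$ps == 0.32], hill_signal(0.32, 100, 20, 0.3))
  d2 <- simulate_dose_response(100, 20, 0.05, ps_grid = c(0.0001, 0.5),
                               noise_sd = 0, n_replicates = 1)
  expect_equal(d2$signal[1], 100, tolerance = 1e-2)  # PS -> 0 limit is Top
  d3 <- simulate_dose_response(100, 20, 0.05, ps_grid = 0.5, h = 1,
                               noise_sd = 0, n_replicates = 1)
  expect_equal(d3$signal, 20 + 80 / 11)  # PS = 10 * IC50
  expect_error(simulate_dose_response(20, 100, 0.3), "top")
  expect_error(simulate_dose_response(100, 20, -1), "ic50")
})

test_that("growth generator: exponential limit, zero rate, logistic shape", {
  t <- seq(0, 10, by = 0.5)
  g <- simulate_growth_curves(c(s = 0.4), od0 = 0.1, t_grid = t, noise_sd = 0,
                              carrying_capacity = Inf)
  expect_equal(log(g$od), log(0.1) + 0.4 * t)
  g0 <- simulate_growth_curves(c(s = 0), od0 = 0.1, t_grid = t, noise_sd = 0)
  expect_equal(g0$od, rep(0.1, length(t)))
  gl <- simulate_growth_curves(c(s = 0.4), od0 = 0.1, t_grid = t, noise_sd = 0,
                               carrying_capacity = 1.5)
  expect_true(all(gl$od < 1.5) && all(diff(gl$od) > 0))
  expect_error(simulate_growth_curves(c(s = 0.4), t_grid = numeric(0)),
               "time grid")
})

test_that("annotation generator: null construction and full depletion", {
  truth <- data.frame(gene_id = sprintf("g%05d", 1:4000),
                      archetype = rep(c("CA_UP", "NULL"), each = 2000),
                      direction = rep(c(1L, 0L), each = 2000))
  ann0 <- simulate_annotations(truth, marks = c("m1", "m2"),
                               background_rate = 0.3,
                               depletion_strength = 0, seed = 5)
  for (m in c("m1", "m2")) {
    up_rate <- length(intersect(ann0$sets[[m]], truth$gene_id[1:2000])) / 2000
    # null: class overlap at background rate within 3 binomial sd
    expect_lt(abs(up_rate - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
  }
  ann1 <- simulate_annotations(truth, marks = "m1", depletion_strength = 1,
                               seed = 5)
  expect_length(intersect(ann1$sets$m1, truth$gene_id[1:2000]), 0)
})

test_that("expression dataset round-trips through the TSV pair", {
  ds <- tiny_dataset(noise_sd = 0.2, seed = 4)
  d <- withr::local_tempdir()
  write_expression_dataset(ds, file.path(d, "m.tsv"), file.path(d, "d.tsv"),
                           file.path(d, "t.tsv"), meta = list(seed = 4))
  back <- read_expression_dataset(file.path(d, "m.tsv"), file.path(d, "d.tsv"),
                                  file.path(d, "t.tsv"))
  expect_equal(back$expr, ds$expr, tolerance = 1e-12)
  expect_equal(back$design$condition, ds$design$condition)
  expect_equal(back$truth$archetype, ds$truth$archetype)
  # header comment present
  expect_match(readLines(file.path(d, "m.tsv"), n = 1), "^# gradedmut")
})

test_that("GMT files round-trip and validate the universe", {
  ann <- annotation_collection(list(A = c("g1", "g2"), B = "g3"),
                               universe = c("g1", "g2", "g3", "g4"))
  d <- withr::local_tempdir()
  write_gmt(ann, file.path(d, "x.gmt"))
  back <- read_gmt(file.path(d, "x.gmt"), universe = c("g1", "g2", "g3", "g4"))
  expect_equal(lapply(back$sets, sort), lapply(ann$sets, sort))
  expect_error(annotation_collection(list(A = "g9"), universe = "g1"),
               "outside the universe")
  expect_error(annotation_collection(list(A = "g1", A = "g1"), universe = "g1"),
               "unique")
})
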