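test_that("identical groups give zero fold change and no significance", {
  ds <- tiny_dataset()
  de <- differential_expression(ds, "CONTROL", "CONTROL")
  expect_equal(de$log2fc, rep(0, nrow(de)))
  expect_false(any(de$significant))
})

test_that("moderated t agrees with an independent empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  # heteroscedastic per-gene noise so the variance prior has finite df
  withr::with_seed(21, {
    n <- 400
    sds <- sqrt(0.06 * rchisq(n, df = 5) / 5)
    expr <- matrix(8 + rnorm(n * 6, 0, rep(sds, 6)), n, 6,
                   dimnames = list(sprintf("g%04d", 1:n),
                                   c(paste0("ctrl_r", 1:3), paste0("ko_r", 1:3))))
    expr[1:20, 4:6] <- expr[1:20, 4:6] + 2
  })
  design <- data.frame(sample_id = colnames(expr),
                       condition = rep(c("CONTROL", "KNOCKOUT"), each = 3),
                       ps = NA_real_)
  ds <- expression_dataset(expr, design)
  de <- differential_expression(ds)
  fit <- limma::eBayes(limma::lmFit(expr, cbind(1, rep(0:1, each = 3))))
  expect_gt(cor(de$t, fit$t[, 2]), 0.9999)
  expect_equal(de$t, unname(fit$t[, 2]), tolerance = 0.02)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 0.02)
  expect_equal(unname(attr(de, "prior")["d0"]), fit$df.prior, tolerance = 0.05)
  expect_true(all(de$significant[1:20]))
})

test_that("welch option matches stats::t.test per gene", {
  ds <- tiny_dataset(noise_sd = 0.3, seed = 6)
  de <- differential_expression(ds, method = "welch")
  a <- ds$expr[, condition_samples(ds, "CONTROL")]
  b <- ds$expr[, condition_samples(ds, "KNOCKOUT")]
  for (g in seq_len(nrow(ds$expr))) {
    tt <- t.test(b[g, ], a[g, ])
    expect_equal(de$p[g], tt$p.value, tolerance = 1e-12)
  }
})

test_that("type-I error of the moderated t is calibrated under the null", {
  ds <- simulate_expression(synth_config(
    n_ca_up = 0, n_ca_down = 0, n_nca = 0, n_fn = 0, n_opp = 0, n_null = 2000,
    seed = 42))
  de <- differential_expression(ds)
  expect_gt(mean(de$p < 0.05), 0.03)
  expect_lt(mean(de$p < 0.05), 0.07)
})

test_that("a 2-log2-unit shift at replicate noise 0.25 is almost always caught", {
  hits <- vapply(1:200, function(s) {
    ds <- simulate_expression(synth_config(
      n_ca_up = 0, n_ca_down = 0, n_nca = 1, n_fn = 0, n_opp = 0, n_null = 9,
      seed = s))
    de <- differential_expression(ds)
    de$significant[match(ds$truth$gene_id[ds$truth$archetype == "NCA"],
                         de$gene_id)]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the exact JT p-value equals exhaustive permutation enumeration", {
  withr::with_seed(7, {
    cases <- list(
      list(x = c(1, 2, 2, 3, 5, 6), g = rep(1:3, each = 2)),
      list(x = c(3, 1, 4, 1, 5, 9, 2, 6), g = rep(1:4, each = 2)),
      list(x = c(2, 2, 2, 2, 2, 2), g = rep(1:3, each = 2))  # fully tied
    )
    for (i in 1:6) {  # randomised small cases with ties
      k <- sample(2:4, 1)
      sizes <- sample(1:3, k, replace = TRUE)
      while (sum(sizes) > 8) sizes <- sample(1:3, k, replace = TRUE)
      cases[[length(cases) + 1]] <-
        list(x = sample(1:4, sum(sizes), replace = TRUE),
             g = rep(seq_len(k), sizes))
    }
    for (cs in cases) {
      o <- jt_oracle(cs$x, cs$g)
      expect_equal(jt_test(cs$x, cs$g, "increasing", exact = TRUE)$p.value,
                   o$inc, tolerance = 1e-12)
      expect_equal(jt_test(cs$x, cs$g, "decreasing", exact = TRUE)$p.value,
                   o$dec, tolerance = 1e-12)
    }
  })
})

test_that("normal approximation approaches the exact JT p-value", {
  x <- c(0.1, 0.5, 0.3, 0.9, 1.1, 0.8, 1.4, 1.9, 1.6)
  g <- rep(1:3, each = 3)
  pe <- jt_test(x, g, "increasing", exact = TRUE)$p.value
  pa <- jt_test(x, g, "increasing", exact = FALSE)$p.value
  expect_equal(pa, pe, tolerance = 0.02)
})

test_that("graded detection calls the constructed shapes", {
  ds <- tiny_dataset()
  g <- detect_graded(ds)
  tr <- ds$truth
  calls <- setNames(g$is_graded, g$gene_id)
  dirs <- setNames(g$direction, g$gene_id)
  expect_true(calls[tr$gene_id[tr$archetype == "CA_UP"]])
  expect_equal(unname(dirs[tr$gene_id[tr$archetype == "CA_UP"]]), "UP")
  expect_true(calls[tr$gene_id[tr$archetype == "CA_DOWN"]])
  expect_equal(unname(dirs[tr$gene_id[tr$archetype == "CA_DOWN"]]), "DOWN")
  expect_false(calls[tr$gene_id[tr$archetype == "NCA"]])   # flat titration
  expect_false(calls[tr$gene_id[tr$archetype == "NULL"]])  # constant gene
  expect_error(detect_graded(tiny_dataset(ps_grid = c(0.5, 0.9))), "3 mutant")
})

test_that("grading thresholds recover the generative midpoints", {
  cfg <- synth_config(n_ca_up = 6, n_ca_down = 6, n_nca = 0, n_fn = 0,
                      n_opp = 0, n_null = 0, noise_sd = 0,
                      k_range = c(0.1, 0.8), seed = 31)
  ds <- simulate_expression(cfg)
  g <- detect_graded(ds)
  thr <- estimate_grading_threshold(g)
  expect_equal(thr$threshold_ps,
               ds$truth$k_g[match(thr$gene_id, ds$truth$gene_id)],
               tolerance = 1e-3)
  expect_error(estimate_grading_threshold(
    detect_graded(tiny_dataset())[c(3, 6), ]), "graded")
})

test_that("a gene saturated from the lowest PS gets a low threshold", {
  cfg <- synth_config(n_ca_up = 1, n_ca_down = 0, n_nca = 0, n_fn = 0,
                      n_opp = 0, n_null = 0, noise_sd = 0,
                      k_range = c(0.004, 0.005), seed = 2)
  ds <- simulate_expression(cfg)
  thr <- estimate_grading_threshold(detect_graded(ds))
  expect_lte(thr$threshold_ps, 0.07)
})

test_that("noisy threshold recovery is accurate to the stated tolerance", {
  errs <- vapply(1:200, function(s) {
    cfg <- synth_config(n_ca_up = 1, n_ca_down = 0, n_nca = 0, n_fn = 0,
                        n_opp = 0, n_null = 0, noise_sd = 0.25,
                        k_range = c(0.8 - 1e-9, 0.8 + 1e-9), seed = s)
    ds <- simulate_expression(cfg)
    g <- detect_graded(ds)
    g <- g[g$is_graded, , drop = FALSE]
    if (!nrow(g)) return(NA_real_)
    ko <- rowMeans(ds$expr[, condition_samples(ds, "KNOCKOUT"), drop = FALSE])
    abs(estimate_grading_threshold(g, ko_level = ko)$threshold_ps - 0.8)
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.15)
})

test_that("classification implements the class definitions and invariants", {
  ds <- tiny_dataset()
  de <- differential_expression(ds)
  g <- detect_graded(ds)
  cl <- classify_genes(de, g)
  tr <- ds$truth
  row <- function(a) cl[cl$gene_id == tr$gene_id[tr$archetype == a], ]
  expect_true(row("CA_UP")$ca_u && !row("CA_UP")$opp && !row("CA_UP")$fn)
  expect_true(row("CA_DOWN")$ca_d)
  expect_true(row("NCA")$nca && !row("NCA")$ca_u && !row("NCA")$ca_d)
  expect_true(row("FN")$fn && row("FN")$ca_u)    # FN implies graded
  expect_true(row("OPP")$opp && row("OPP")$ca_u) # graded UP, knockout DOWN
  # invariants over every gene
  expect_true(all(!cl$fn | (cl$ca_u | cl$ca_d)))
  expect_true(all(!cl$opp | (cl$ca_u | cl$ca_d)))
  expect_true(all(!cl$nca | !(cl$ca_u | cl$ca_d)))
  expect_true(all(!(cl$ca_u & cl$ca_d)))
  expect_error(classify_genes(de[-1, ], g), "universe")
})

test_that("venn arithmetic conserves counts on constructed sets", {
  ds <- tiny_dataset()
  de <- differential_expression(ds)
  g <- detect_graded(ds)
  v <- venn_summary(de, g)
  # graded genes split exactly into common and mutant-only per direction
  expect_equal(v$common_up + v$mutant_only_up +
                 v$common_down + v$mutant_only_down, v$graded_total)
  expect_equal(v$overlap, v$common_up + v$common_down)
  cl <- classify_genes(de, g)
  expect_equal(v$graded_total - v$overlap, sum(cl$fn) + sum(cl$opp))
})

test_that("venn on an empty graded set is flagged, disjoint sets overlap zero", {
  empty <- venn_from_counts(0, 0, 0, 0, ko_total = 5)
  expect_true(empty$empty_graded)
  expect_true(is.na(empty$graded_up_pct))
  disj <- venn_from_counts(0, 3, 0, 0, ko_total = 4)
  expect_equal(disj$overlap, 0)
  expect_equal(disj$ko_only, 4)
  expect_equal(disj$graded_total, 3)
})
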