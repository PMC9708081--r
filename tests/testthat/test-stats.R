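test_that("intercept-only Bernoulli fits match the Wald closed form and
           the glm route", {
  fit <- fit_bernoulli(5, 10)
  expect_equal(fit$estimate, 0.5)
  expect_equal(c(fit$ci_low, fit$ci_high), oracle_wald_ci(5, 10),
               tolerance = 1e-12)
  expect_equal(round(c(fit$ci_low, fit$ci_high), 3), c(0.225, 0.775))
  # scan against the independently coded closed form
  for (n in c(2:12, 50, 67, 137, 200)) for (k in seq_len(n - 1)) {
    f <- fit_bernoulli(k, n)
    expect_equal(c(f$ci_low, f$ci_high), oracle_wald_ci(k, n),
                 tolerance = 1e-12)
    expect_equal(f$estimate, k / n)
  }
  # the glm intercept-only route gives the same estimate and Wald CI
  for (kn in list(c(7, 19), c(52, 67), c(23, 36), c(1, 9))) {
    k <- kn[1]; n <- kn[2]
    g <- stats::glm(c(rep(1, k), rep(0, n - k)) ~ 1, family = binomial,
                    control = stats::glm.control(epsilon = 1e-14))
    f <- fit_bernoulli(k, n)
    expect_equal(f$estimate, unname(plogis(coef(g))), tolerance = 1e-6)
    wald <- suppressMessages(confint.default(g))
    expect_equal(c(f$ci_low, f$ci_high), unname(plogis(wald[1, ])),
                 tolerance = 1e-6)
  }
  # degenerate fits carry no interval but keep the exact estimate
  f1 <- fit_bernoulli(10, 10)
  expect_true(f1$degenerate); expect_equal(f1$estimate, 1)
  expect_true(is.na(f1$ci_low))
  expect_error(fit_bernoulli(3, 0), "at least 1")
  expect_error(fit_bernoulli(5, 4), "k must lie")
})

test_that("binomial tails are exact sums under both conventions", {
  expect_equal(binomial_tail(0, 12, strict = FALSE), 1)
  expect_equal(binomial_tail(12, 12, strict = TRUE), 0)
  # oracle scan over moderate n, both conventions, off-centre p0
  for (n in c(1, 2, 7, 36, 67)) for (k in 0:n) {
    expect_equal(binomial_tail(k, n, strict = TRUE),
                 oracle_binom_tail(k + 1, n), tolerance = 1e-12)
    expect_equal(binomial_tail(k, n, strict = FALSE),
                 oracle_binom_tail(k, n), tolerance = 1e-12)
  }
  expect_equal(binomial_tail(3, 10, p0 = 0.2, strict = FALSE),
               oracle_binom_tail(3, 10, 0.2), tolerance = 1e-12)
  expect_error(binomial_tail(3, 10, p0 = 1), "p0")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.07), 0.07)
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("improvement evaluation counts successes at region and member
           level", {
  d <- matrix(-abs(rnorm(12)), 3, 4,
              dimnames = list(paste0("r", 1:3), NULL))
  out <- evaluate_improvement(d, boot_draws = 500)
  expect_equal(out$overall$estimate, 1)
  expect_true(all(vapply(out$per_region, function(f) f$estimate, 0) == 1))
  # a region with member diffs {-1, +1} has pB = 1/2
  d2 <- rbind(r1 = c(-1, 1), r2 = c(-2, -3))
  out2 <- evaluate_improvement(d2, boot_draws = 500)
  expect_equal(out2$per_region$r1$estimate, 0.5)
  expect_equal(out2$records$n_success, c(1L, 2L))
  # overall fit is the Bernoulli fit of mean-level successes
  set.seed(14)
  d3 <- matrix(rnorm(67 * 5), 67, 5)
  d3[1:52, ] <- -abs(d3[1:52, ]) - 0.1   # 52 regions improve on average
  d3[53:67, ] <- abs(d3[53:67, ]) + 0.1
  out3 <- evaluate_improvement(d3, boot_draws = 500)
  ref <- fit_bernoulli(52, 67)
  expect_equal(out3$overall$estimate, ref$estimate)
  expect_equal(out3$overall$ci_low, ref$ci_low)
  expect_equal(out3$overall$p_null, ref$p_null)
  # bootstrap CI brackets the mean and is seed-stable
  expect_true(all(out3$records$ci_low <= out3$records$mean_diff + 1e-12))
  expect_true(all(out3$records$ci_high >= out3$records$mean_diff - 1e-12))
  rerun <- evaluate_improvement(d3, boot_draws = 500)
  expect_identical(rerun$records$ci_low, out3$records$ci_low)
  expect_error(evaluate_improvement(matrix(numeric(0), 0, 0)), "nrow")
})

test_that("under a symmetric null the success count is Binomial(n, 1/2)", {
  # mid-p transform of the overall success count over 200 null replicates
  set.seed(42)
  midp <- replicate(200, {
    d <- matrix(rnorm(67 * 3), 67, 3)   # diffs symmetric about 0
    k <- evaluate_improvement(d, boot_draws = 2)$overall$k
    pbinom(k, 67, 0.5, lower.tail = FALSE) + 0.5 * dbinom(k, 67, 0.5)
  })
  expect_gt(suppressWarnings(ks.test(midp, "punif"))$p.value, 0.001)
})

test_that("cortex-type contrasts: OLS across regions, paired design
           across members", {
  regions <- paste0("r", 1:8)
  type <- setNames(rep(c("sensorimotor", "supramodal"), each = 4), regions)
  # identical groups: both contrasts give beta = 0
  eq <- matrix(0.5, 8, 6, dimnames = list(regions, NULL))
  eq <- eq + matrix(rep(rnorm(6, sd = 1e-3), each = 8), 8, 6)  # member noise
  out <- cortex_type_contrast(eq, type)
  expect_equal(out$across_regions$beta, 0, tolerance = 1e-9)
  expect_equal(out$across_members$beta, 0, tolerance = 1e-9)
  # constructed shift of -0.05 with no noise is recovered exactly
  sh <- matrix(0.9, 8, 6, dimnames = list(regions, NULL))
  sh[type[regions] == "supramodal", ] <- 0.85
  sh <- sh + matrix(rep(rnorm(6, sd = 1e-4), each = 8), 8, 6)
  out2 <- cortex_type_contrast(sh, type)
  expect_equal(out2$across_regions$beta, -0.05, tolerance = 1e-9)
  expect_equal(out2$across_members$beta, -0.05, tolerance = 1e-9)
  # mixed-model contrast equals the closed-form paired t-test
  set.seed(19)
  mc <- matrix(runif(8 * 20, 0.4, 0.95), 8, 20,
               dimnames = list(regions, NULL))
  out3 <- cortex_type_contrast(mc, type)
  diffs <- colMeans(mc[type[regions] == "supramodal", ]) -
    colMeans(mc[type[regions] == "sensorimotor", ])
  tt <- t.test(diffs)
  expect_equal(out3$across_members$beta, unname(mean(diffs)),
               tolerance = 1e-8)
  expect_equal(out3$across_members$t, unname(tt$statistic),
               tolerance = 1e-6)
  expect_equal(out3$across_members$df, 19, tolerance = 1e-6)
  expect_equal(out3$across_members$p, tt$p.value, tolerance = 1e-6)
  expect_equal(out3$across_regions$df, 6)
  expect_error(cortex_type_contrast(mc, setNames(rep("supramodal", 8),
                                                 regions)), "both")
})

test_that("hypergeometric enrichment enumerates exact tail probabilities", {
  universe <- paste0("g", 1:10)
  modules <- list(hit = paste0("g", 1:4), miss = paste0("g", 9:10))
  query <- paste0("g", 1:5)
  out <- hypergeometric_enrichment(query, modules, universe)
  # C(4,4) C(6,1) / C(10,5) = 6/252
  expect_equal(out$p[out$module == "hit"], 6 / 252)
  expect_equal(out$overlap[out$module == "hit"], 4L)
  # disjoint module: P(X >= 0) = 1
  expect_equal(out$p[out$module == "miss"], 1)
  expect_identical(out$module[1], "hit")   # sorted by p
  # growing overlap at fixed sizes never increases p
  ps <- vapply(1:4, function(ov)
    hypergeometric_enrichment(paste0("g", 1:5),
                              list(m = paste0("g", c(seq_len(ov), 7:10)[1:4])),
                              universe)$p, 0)
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(hypergeometric_enrichment(query, modules, character(0)),
               "empty universe")
  expect_error(hypergeometric_enrichment("zz", modules, universe),
               "outside")
})

test_that("GMT modules feed the enrichment test", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("modA\tdesc\tg1\tg2\tg3",
               "modB\tdesc\tg8\tg9"), path)
  mods <- read_gmt(path)
  expect_identical(names(mods), c("modA", "modB"))
  out <- hypergeometric_enrichment(paste0("g", 1:3), mods, paste0("g", 1:10))
  expect_equal(out$overlap, c(3L, 0L))
})
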