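mk <- function(...) {
  m <- rbind(...)
  rownames(m) <- paste0("r", seq_len(nrow(m)))
  m
}

test_that("pearson similarity matches hand-computed correlations", {
  A <- mk(c(1, 2, 4))
  B <- mk(c(1, 3, 5), c(-1, -2, -4), c(1, 2, 4))
  sim <- pearson_similarity(A, B)
  expect_equal(sim[1, 3], 1)
  expect_equal(sim[1, 2], -1)
  # cov/sd arithmetic: r((1,2,4),(1,3,5)) = 6 / sqrt(42/9 * 8)
  expect_equal(sim[1, 1], 6 / sqrt(42 / 9 * 8))
  expect_equal(round(sim[1, 1], 3), 0.982)
  # self-similarity has a unit diagonal
  set.seed(3)
  M <- matrix(rnorm(40), 5, 8, dimnames = list(paste0("x", 1:5), NULL))
  expect_equal(unname(diag(pearson_similarity(M, M))), rep(1, 5))
  expect_error(pearson_similarity(mk(c(1, 1, 1)), B), "zero-variance")
  expect_error(pearson_similarity(A, B[, 1:2]), "feature dimensions")
})

test_that("profiles scale to [0,1] with stable descending order", {
  p <- c(a = 2, b = 1, c = 0)
  rp <- scale_unit_interval(p)
  expect_equal(rp$scaled, c(1, 0.5, 0))
  expect_identical(rp$targets, c("a", "b", "c"))
  expect_identical(scale_unit_interval(c(u = 1, v = 0))$scaled, c(1, 0))
  expect_error(scale_unit_interval(c(x = 0.3, y = 0.3)), "constant")
  # ties keep input target order
  rp <- scale_unit_interval(c(m = 0.5, n = 0.9, o = 0.9, p = 0.1))
  expect_identical(rp$targets, c("n", "o", "m", "p"))
})

test_that("rank at threshold is the first scaled value at or below tau", {
  rp <- function(scaled) structure(
    list(seed = NULL, targets = paste0("t", seq_along(scaled)),
         scaled = scaled, values = scaled), class = "ranked_profile")
  expect_identical(rank_at_threshold(rp(c(1, 0.5, 0))), 2L)
  # inclusive at the boundary
  expect_identical(rank_at_threshold(rp(c(1, 0.8, 0.75, 0))), 3L)
  expect_identical(rank_at_threshold(rp(c(1, 0))), 2L)
  # monotonicity: raising tau never increases the rank
  set.seed(5)
  for (i in 1:20) {
    v <- setNames(runif(10), paste0("t", 1:10))
    r <- scale_unit_interval(v)
    taus <- sort(runif(5, 0.1, 0.95))
    ranks <- vapply(taus, function(tau) rank_at_threshold(r, tau), 0L)
    expect_true(all(diff(ranks) <= 0))
  }
})

test_that("target ranks follow the descending sort with stable ties", {
  rp <- scale_unit_interval(c(a = 0.2, b = 0.9, c = 0.5, d = 0.9))
  expect_identical(rank_of_target(rp, "b"), 1L)   # first of the tied pair
  expect_identical(rank_of_target(rp, "d"), 2L)
  expect_identical(rank_of_target(rp, "a"), 4L)
  expect_error(rank_of_target(rp, "zz"), "unknown target")
  # the argmax target always has rank 1
  set.seed(9)
  for (i in 1:10) {
    v <- setNames(rnorm(8), paste0("t", 1:8))
    expect_identical(
      rank_of_target(scale_unit_interval(v), names(v)[which.max(v)]), 1L)
  }
})

test_that("ensemble means are entrywise and shape-checked", {
  m1 <- matrix(0.2, 2, 2, dimnames = list(c("a", "b"), c("X", "Y")))
  m2 <- matrix(0.4, 2, 2, dimnames = list(c("a", "b"), c("X", "Y")))
  expect_equal(ensemble_mean_similarity(list(m1)), m1)
  expect_equal(ensemble_mean_similarity(list(m1, m2)),
               (m1 + m2) / 2)
  m3 <- m2; rownames(m3) <- c("a", "zz")
  expect_error(ensemble_mean_similarity(list(m1, m3)), "region sets")
})

test_that("observation similarity records argmax targets", {
  regions <- mk(c(1, 0, 0), c(0, 1, 0))
  rownames(regions) <- c("R1", "R2")
  obs <- rbind(o1 = c(1, 0, 0), o2 = c(0.1, 0.9, 0.2))
  # an observation equal to a region signature matches it exactly
  vs <- observation_similarity(obs, regions)
  expect_equal(vs$r["o1", "R1"], 1)
  expect_identical(unname(vs$argmax["o1"]), "R1")
  # one observation, two orthogonal targets: hand-computed winner
  expect_identical(unname(vs$argmax["o2"]), "R2")
  # permuting targets permutes columns identically
  vs2 <- observation_similarity(obs, regions[c(2, 1), ])
  expect_equal(vs2$r[, c("R1", "R2")], vs$r[, c("R1", "R2")])
  # zero-variance observations are excluded with a warning
  expect_warning(
    out <- observation_similarity(rbind(obs, o3 = c(1, 1, 1)), regions),
    "zero-variance")
  expect_identical(rownames(out$r), c("o1", "o2"))
})

test_that("argmax proportions count ensemble winners with first-wins ties", {
  base <- matrix(0, 2, 2, dimnames = list(c("o1", "o2"), c("A", "B")))
  mkmap <- function(w1, w2) {
    r <- base; r["o1", w1] <- 0.9; r["o2", w2] <- 0.9
    structure(list(r = r, argmax = c(o1 = w1, o2 = w2)),
              class = "voxel_similarity")
  }
  maps <- list(mkmap("A", "B"), mkmap("A", "A"), mkmap("B", "B"))
  prop <- argmax_proportions(maps)
  expect_equal(prop["o1", ], c(A = 2 / 3, B = 1 / 3))
  expect_equal(unname(rowSums(prop)), c(1, 1))
  # single map gives indicator rows
  expect_equal(unname(argmax_proportions(maps[1])["o1", ]), c(1, 0))
  # an exact tie counts once, for the first target in column order
  tie <- base + 0.5
  prop_tie <- argmax_proportions(list(
    structure(list(r = tie), class = "voxel_similarity")))
  expect_equal(unname(prop_tie[, "A"]), c(1, 1))
  # conservation on random fixtures
  set.seed(21)
  rmaps <- lapply(1:5, function(i) {
    r <- matrix(runif(12, -1, 1), 3, 4,
                dimnames = list(paste0("o", 1:3), paste0("t", 1:4)))
    structure(list(r = r), class = "voxel_similarity")
  })
  expect_equal(unname(rowSums(argmax_proportions(rmaps))), rep(1, 3))
})

test_that("dispersion summaries use the n-1 denominator", {
  expect_equal(summarize_dispersion(c(0, 0)),
               list(mean = 0, sd = 0, var = 0))
  d <- summarize_dispersion(c(1, 3))
  expect_equal(d$mean, 2); expect_equal(d$var, 2)
  # shifting values shifts the mean only
  v <- rnorm(20)
  expect_equal(summarize_dispersion(v + 5)$sd, summarize_dispersion(v)$sd)
  expect_equal(summarize_dispersion(v + 5)$mean,
               summarize_dispersion(v)$mean + 5)
  expect_error(summarize_dispersion(0.5), "at least 2")
})

test_that("top-target selection orders by mean correlation", {
  r <- rbind(c(0.5, 0.4), c(0.5, 0.4))
  colnames(r) <- c("X", "Y"); rownames(r) <- c("o1", "o2")
  map <- structure(list(r = r), class = "voxel_similarity")
  expect_identical(select_top_targets(map, 1), "X")
  expect_identical(select_top_targets(map, 2), c("X", "Y"))
  # dominance: a target that wins every row comes first
  r2 <- r; r2[, "Y"] <- 0.9
  expect_identical(
    select_top_targets(list(map, structure(list(r = r2),
                                           class = "voxel_similarity")), 2),
    c("Y", "X"))
  expect_equal(threshold_fraction(map, 0.45), 1)
  expect_equal(threshold_fraction(map, 0.45, target = "Y"), 0)
})

test_that("similarity matrices round-trip through TSV", {
  sim <- matrix(runif(6, -1, 1), 2, 3,
                dimnames = list(c("m1", "m2"), c("h1", "h2", "h3")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity(sim, path)
  expect_equal(read_similarity(path), sim)
})
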