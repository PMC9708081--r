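test_that("architecture has the closed-form parameter count and a
           normalized soft-max head", {
  set.seed(2)
  x <- matrix(rnorm(20 * 50), 20, 50,
              dimnames = list(NULL, paste0("g", 1:50)))
  y <- sample(paste0("r", 1:10), 20, replace = TRUE)
  y[1:10] <- paste0("r", 1:10)   # ensure all 10 labels occur
  fit <- mlp_classifier(x, y, mlp_config(n_hidden = 3, n_units = 200,
                                         n_epochs = 1))
  # (50*200+200) + 2*(200*200+200) + (200*10+10)
  expect_identical(n_parameters(fit), 92610L)
  expect_identical(length(fit$classes), 10L)
  logp <- predict(fit, matrix(0, 1, 50))
  expect_identical(ncol(predict(fit, x, type = "score")), 10L)
  expect_equal(sum(exp(predict(fit, matrix(0, 1, 50), type = "logprob"))),
               1, tolerance = 1e-6)
  expect_error(mlp_classifier(x[, 0, drop = FALSE], y), "dimension")
  expect_error(predict(fit, x[, 1:10]), "features")
})

test_that("training is deterministic in the seed and accurate on
           separable data", {
  fx <- separable_fixture()
  cfg <- fast_cfg(seed = 11)
  fit1 <- mlp_classifier(fx$x, fx$y, cfg)
  fit2 <- mlp_classifier(fx$x, fx$y, cfg)
  expect_identical(fit1$W, fit2$W)   # bitwise-identical weights
  expect_identical(fit1$b, fit2$b)
  fit3 <- mlp_classifier(fx$x, fx$y, fast_cfg(seed = 12))
  expect_false(identical(fit1$W, fit3$W))
  expect_gte(fit1$accuracy, 0.95)
  # a multinomial logistic baseline reaches ~1 on the same fixture
  base <- nnet::multinom(y ~ ., data.frame(fx$x, y = fx$y), trace = FALSE)
  expect_gte(mean(predict(base) == fx$y), 0.99)
  # the fitted RNG leaves the caller's stream untouched
  set.seed(77); before <- runif(1)
  set.seed(77); invisible(mlp_classifier(fx$x, fx$y, cfg))
  expect_identical(runif(1), before)
})

test_that("label problems and divergence are reported", {
  fx <- separable_fixture()
  expect_error(mlp_classifier(fx$x, c(fx$y[-1], NA), fast_cfg()), "NA")
  expect_error(mlp_classifier(fx$x, fx$y[-1], fast_cfg()), "nrow")
  # a non-finite loss reports the epoch at which training diverged
  bad <- fx$x; bad[1, 1] <- Inf
  expect_error(mlp_classifier(bad, fx$y, fast_cfg(n_epochs = 5)),
               "epoch 1")
})

test_that("stripping the output layer preserves the classifier exactly", {
  fx <- separable_fixture()
  fit <- mlp_classifier(fx$x, fx$y, fast_cfg())
  lt <- latent_transform(fit)
  expect_identical(lt$latent_dim, 16L)
  set.seed(31)
  xs <- matrix(rnorm(100 * ncol(fx$x)), 100)
  # reconstruction identity: exact equality on random inputs
  expect_identical(unname(predict(lt, xs, type = "logprob")),
                   unname(predict(fit, xs, type = "logprob")))
  # post-activation latents are non-negative
  lat <- apply_transform(xs, lt)
  expect_true(all(lat >= 0))
  expect_identical(dim(lat), c(100L, 16L))
  # row order is preserved under permutation
  perm <- sample(100)
  expect_equal(apply_transform(xs[perm, ], lt), lat[perm, ],
               ignore_attr = TRUE)
})

test_that("a hand-built single-hidden-layer transform is ReLU of the
           affine map", {
  model <- structure(list(
    W = list(matrix(c(1, -1, 2, 0), 2, 2), diag(2)),
    b = list(c(0.5, -0.5), c(0, 0)),
    config = NULL, input_dim = 2L, classes = c("a", "b"),
    sizes = c(2L, 2L, 2L), features = c("g1", "g2"),
    loss = NA_real_, accuracy = NA_real_, loss_path = numeric(0)),
    class = "mlp_classifier")
  lt <- latent_transform(model)
  x <- rbind(c(1, 1), c(-2, 3))
  manual <- pmax(cbind(x[, 1] - x[, 2] + 0.5, 2 * x[, 1] - 0.5), 0)
  expect_equal(unname(apply_transform(x, lt)), manual)
})

test_that("ensembles are reproducible and members differ", {
  fx <- separable_fixture()
  ens <- latent_ensemble(fx$x, fx$y, fast_cfg(), n_members = 3,
                         base_seed = 100, keep_models = TRUE)
  # single-member ensemble reduces to one train + strip
  one <- latent_ensemble(fx$x, fx$y, fast_cfg(), n_members = 1,
                         base_seed = 100)
  expect_identical(one$transforms[[1]]$W, ens$transforms[[1]]$W)
  solo <- mlp_classifier(fx$x, fx$y, fast_cfg(seed = 101))
  expect_identical(latent_transform(solo)$W, ens$transforms[[1]]$W)
  # different seeds give different weights; same base seed reproduces all
  expect_false(identical(ens$transforms[[1]]$W, ens$transforms[[2]]$W))
  expect_false(identical(ens$transforms[[2]]$W, ens$transforms[[3]]$W))
  ens2 <- latent_ensemble(fx$x, fx$y, fast_cfg(), n_members = 3,
                          base_seed = 100)
  for (i in 1:3)
    expect_identical(ens$transforms[[i]]$W, ens2$transforms[[i]]$W)
})

test_that("weight bundles survive a JSON round trip", {
  fx <- separable_fixture()
  fit <- mlp_classifier(fx$x, fx$y, fast_cfg(n_epochs = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp(fit, path)
  back <- read_mlp(path)
  expect_equal(back$W, fit$W)
  expect_equal(predict(back, fx$x, type = "logprob"),
               predict(fit, fx$x, type = "logprob"))
  expect_identical(back$classes, fit$classes)
})

test_that("classifier methods behave like a fitted model object", {
  fx <- separable_fixture()
  fit <- mlp_classifier(fx$x, fx$y, fast_cfg(n_epochs = 10))
  expect_output(print(fit), "architecture")
  expect_output(print(summary(fit)), "loss path")
  cf <- coef(fit)
  expect_identical(length(cf$weights), 3L)
  sims <- simulate(fit, nsim = 2, seed = 1, newdata = fx$x[1:5, ])
  expect_identical(dim(sims), c(5L, 2L))
  expect_true(all(unlist(sims) %in% fit$classes))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("one-cycle schedule peaks at max_lr and decays far below it", {
  cfg <- mlp_config(max_lr = 0.1, n_epochs = 10)
  lrs <- vapply(1:100, function(s) commonspace:::.one_cycle_lr(s, 100, cfg), 0)
  expect_equal(max(lrs), 0.1, tolerance = 1e-9)
  expect_equal(which.max(lrs), 30)          # warm-up fraction 0.3
  expect_lt(lrs[100], 0.1 / 25 / 1e3)
  expect_equal(lrs[1] <= 0.1 / 25 * 1.2, TRUE)
})
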