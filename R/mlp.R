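#' Supervised latent spaces from a brain-region classifier
#'
#' The latent common space is obtained by training a fully connected
#' multi-layer perceptron to classify observations (mouse voxels) into
#' atlas regions from their homologous-gene expression signatures, then
#' removing the output layer and soft-max: the activations of the last
#' hidden layer become a lower-dimensional embedding that is applied to
#' both species' expression matrices. Training uses the negative
#' log-likelihood loss, ReLU activations, a one-cycle learning-rate
#' policy, and either AdamW or plain SGD. All randomness (initialization,
#' mini-batch shuffling) is governed by the configuration seed, so a fit
#' is exactly reproducible.
#'
#' @name latent_space
NULL

#' Classifier hyperparameter configuration
#'
#' Defaults are the selected model of the reference analysis: 3 hidden
#' layers of 200 units, no weight decay, AdamW with a maximum one-cycle
#' learning rate of 1e-5, 200 epochs, full-batch updates.
#'
#' @param n_hidden number of hidden layers
#' @param n_units hidden units per layer
#' @param weight_decay decoupled weight-decay coefficient
#' @param max_lr peak learning rate of the one-cycle schedule
#' @param optimizer `"AdamW"` or `"SGD"`
#' @param n_epochs training epochs
#' @param batch_size minibatch size; `NULL` = full batch
#' @param seed RNG seed controlling initialization and shuffling
#' @param pct_start,div_factor,final_div one-cycle schedule shape: warm-up
#'   fraction, initial divisor (start lr = max_lr / div_factor) and final
#'   divisor (end lr = start lr / final_div)
#' @return An object of class `"mlp_config"`.
#' @export
mlp_config <- function(n_hidden = 3, n_units = 200, weight_decay = 0,
                       max_lr = 1e-5, optimizer = c("AdamW", "SGD"),
                       n_epochs = 200, batch_size = NULL, seed = 42,
                       pct_start = 0.3, div_factor = 25, final_div = 1e4) {
  optimizer <- match.arg(optimizer)
  stopifnot(n_hidden >= 1, n_units >= 1, n_epochs >= 1, max_lr > 0,
            weight_decay >= 0, is.null(batch_size) || batch_size >= 1,
            pct_start > 0, pct_start < 1, div_factor >= 1, final_div >= 1)
  structure(list(n_hidden = as.integer(n_hidden),
                 n_units = as.integer(n_units),
                 weight_decay = weight_decay, max_lr = max_lr,
                 optimizer = optimizer, n_epochs = as.integer(n_epochs),
                 batch_size = if (is.null(batch_size)) NULL
                              else as.integer(batch_size),
                 seed = as.integer(seed), pct_start = pct_start,
                 div_factor = div_factor, final_div = final_div,
                 init = "fan_in_uniform"),
            class = "mlp_config")
}

#' @export
print.mlp_config <- function(x, ...) {
  cat("MLP config: ", x$n_hidden, " x ", x$n_units, " hidden units, ",
      x$optimizer, " (max_lr ", format(x$max_lr), ", weight decay ",
      format(x$weight_decay), "), ", x$n_epochs, " epochs, batch ",
      if (is.null(x$batch_size)) "full" else x$batch_size,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# fan-in uniform initialization: U(-1/sqrt(fan_in), 1/sqrt(fan_in)) for
# both weights and biases, consumed from the current RNG stream
.init_layers <- function(sizes) {
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    bound <- 1 / sqrt(sizes[l])
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -bound, bound),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- stats::runif(sizes[l + 1L], -bound, bound)
  }
  list(W = W, b = b)
}

# forward pass; returns per-layer pre-activations Z and activations H
# (H[[1]] is the input); output layer linear, log-soft-max applied on top
.forward <- function(W, b, X) {
  L <- length(W)
  H <- vector("list", L + 1L); Z <- vector("list", L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(H[[l]] %*% W[[l]], 2, b[[l]], "+")
    H[[l + 1L]] <- if (l < L) pmax(Z[[l]], 0) else Z[[l]]
  }
  list(Z = Z, H = H, score = Z[[L]])
}

.log_softmax <- function(score) {
  m <- apply(score, 1, max)
  s <- score - m
  s - log(rowSums(exp(s)))
}

.nll <- function(logp, y_idx) {
  -mean(logp[cbind(seq_len(nrow(logp)), y_idx)])
}

# one-cycle schedule: cosine warm-up from max_lr/div_factor to max_lr over
# pct_start of the steps, then cosine annealing down to
# max_lr/div_factor/final_div
.one_cycle_lr <- function(step, total, cfg) {
  lr0 <- cfg$max_lr / cfg$div_factor
  lr_end <- lr0 / cfg$final_div
  warm <- max(1, floor(cfg$pct_start * total))
  if (step <= warm) {
    t <- step / warm
    lr0 + (cfg$max_lr - lr0) * (1 - cos(pi * t)) / 2
  } else {
    t <- (step - warm) / max(1, total - warm)
    lr_end + (cfg$max_lr - lr_end) * (1 + cos(pi * t)) / 2
  }
}

#' Fit a brain-region classifier
#'
#' Trains a fully connected ReLU network with a log-soft-max head by
#' backpropagation on the negative log-likelihood. Deterministic given
#' `(config, x, y)`: the configuration seed drives initialization and
#' shuffling, and the caller's RNG state is left untouched.
#'
#' @param x observations-by-genes numeric matrix (normalized expression)
#' @param y region labels, one per row of `x` (factor or character)
#' @param config an [mlp_config()]
#' @return An object of class `"mlp_classifier"` with weights, the label
#'   set, final training loss and accuracy, and the per-epoch loss path.
#' @export
mlp_classifier <- function(x, y, config = mlp_config()) {
  stopifnot(is.matrix(x), inherits(config, "mlp_config"))
  if (anyNA(x)) stop("training matrix contains missing values")
  y <- factor(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (any(is.na(y))) stop("labels contain NA")
  y_idx <- as.integer(y)
  G <- ncol(x); L_out <- nlevels(y)
  if (G < 1 || L_out < 1) stop("nonpositive input or label dimension")
  sizes <- c(G, rep(config$n_units, config$n_hidden), L_out)

  if (exists(".Random.seed", globalenv()))
    old_seed <- get(".Random.seed", globalenv()) else old_seed <- NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  par <- .init_layers(sizes)
  W <- par$W; b <- par$b
  nL <- length(W)
  opt_m <- opt_v <- NULL
  if (config$optimizer == "AdamW") {
    opt_m <- list(W = lapply(W, function(w) w * 0),
                  b = lapply(b, function(v) v * 0))
    opt_v <- opt_m
  }
  n <- nrow(x)
  bs <- if (is.null(config$batch_size)) n else min(config$batch_size, n)
  n_batches <- ceiling(n / bs)
  total_steps <- config$n_epochs * n_batches
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L; adam_t <- 0L
  loss_path <- numeric(config$n_epochs)

  for (epoch in seq_len(config$n_epochs)) {
    idx <- if (n_batches > 1L) sample.int(n) else seq_len(n)
    epoch_loss <- 0
    for (bt in seq_len(n_batches)) {
      rows <- idx[((bt - 1L) * bs + 1L):min(bt * bs, n)]
      Xb <- x[rows, , drop = FALSE]; yb <- y_idx[rows]
      fw <- .forward(W, b, Xb)
      logp <- .log_softmax(fw$score)
      loss <- .nll(logp, yb)
      if (!is.finite(loss))
        stop("divergent (non-finite) loss at epoch ", epoch)
      epoch_loss <- epoch_loss + loss * length(rows)
      step <- step + 1L
      lr <- .one_cycle_lr(step, total_steps, config)
      # backward
      P <- exp(logp)
      Gz <- P; Gz[cbind(seq_along(yb), yb)] <- Gz[cbind(seq_along(yb), yb)] - 1
      Gz <- Gz / length(rows)
      gW <- vector("list", nL); gb <- vector("list", nL)
      for (l in rev(seq_len(nL))) {
        gW[[l]] <- crossprod(fw$H[[l]], Gz)
        gb[[l]] <- colSums(Gz)
        if (l > 1L) Gz <- (Gz %*% t(W[[l]])) * (fw$Z[[l - 1L]] > 0)
      }
      # parameter update
      if (config$optimizer == "SGD") {
        for (l in seq_len(nL)) {
          W[[l]] <- W[[l]] - lr * (gW[[l]] + config$weight_decay * W[[l]])
          b[[l]] <- b[[l]] - lr * gb[[l]]
        }
      } else {
        adam_t <- adam_t + 1L
        bc1 <- 1 - beta1^adam_t; bc2 <- 1 - beta2^adam_t
        for (l in seq_len(nL)) {
          opt_m$W[[l]] <- beta1 * opt_m$W[[l]] + (1 - beta1) * gW[[l]]
          opt_v$W[[l]] <- beta2 * opt_v$W[[l]] + (1 - beta2) * gW[[l]]^2
          W[[l]] <- W[[l]] -
            lr * (opt_m$W[[l]] / bc1) / (sqrt(opt_v$W[[l]] / bc2) + eps) -
            lr * config$weight_decay * W[[l]]
          opt_m$b[[l]] <- beta1 * opt_m$b[[l]] + (1 - beta1) * gb[[l]]
          opt_v$b[[l]] <- beta2 * opt_v$b[[l]] + (1 - beta2) * gb[[l]]^2
          b[[l]] <- b[[l]] -
            lr * (opt_m$b[[l]] / bc1) / (sqrt(opt_v$b[[l]] / bc2) + eps)
        }
      }
    }
    loss_path[epoch] <- epoch_loss / n
  }

  W <- lapply(W, unname); b <- lapply(b, unname)
  fw <- .forward(W, b, x)
  logp <- .log_softmax(fw$score)
  fit <- structure(
    list(W = W, b = b, config = config, input_dim = G,
         classes = levels(y), sizes = sizes,
         features = colnames(x),
         loss = .nll(logp, y_idx),
         accuracy = mean(max.col(logp, ties.method = "first") == y_idx),
         loss_path = loss_path),
    class = "mlp_classifier"
  )
  fit
}

#' @export
print.mlp_classifier <- function(x, ...) {
  cat("Brain-region MLP classifier\n")
  cat("  architecture:", paste(x$sizes, collapse = " -> "),
      "(ReLU hidden, log-soft-max head)\n")
  cat("  ", length(x$classes), " region labels, ",
      format(n_parameters(x), big.mark = ","), " parameters\n", sep = "")
  cat("  final training NLL ", signif(x$loss, 4), ", accuracy ",
      signif(x$accuracy, 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.mlp_classifier <- function(object, ...) {
  out <- list(config = object$config, sizes = object$sizes,
              n_parameters = n_parameters(object),
              classes = object$classes, loss = object$loss,
              accuracy = object$accuracy, loss_path = object$loss_path)
  class(out) <- "summary.mlp_classifier"
  out
}

#' @export
print.summary.mlp_classifier <- function(x, ...) {
  print(x$config)
  cat("architecture ", paste(x$sizes, collapse = " -> "), "; ",
      format(x$n_parameters, big.mark = ","), " parameters\n", sep = "")
  cat("training NLL", signif(x$loss, 4), "| accuracy",
      signif(x$accuracy, 4), "\n")
  cat("loss path (first/last 3 epochs):",
      paste(signif(utils::head(x$loss_path, 3), 3), collapse = " "), "...",
      paste(signif(utils::tail(x$loss_path, 3), 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.mlp_classifier <- function(object, ...) {
  list(weights = object$W, biases = object$b)
}

#' Total trainable parameter count
#' @param model an `mlp_classifier` or `latent_transform`
#' @return Integer count over all weight matrices and bias vectors.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$W, length, 0L)) + sum(vapply(model$b, length, 0L))
}

.check_newdata <- function(object, newdata) {
  if (!is.matrix(newdata)) newdata <- rbind(newdata)
  if (ncol(newdata) != object$input_dim)
    stop("newdata has ", ncol(newdata), " features; model expects ",
         object$input_dim)
  newdata
}

#' Predict from a fitted region classifier
#'
#' @param object an `mlp_classifier`
#' @param newdata observations-by-genes matrix
#' @param type `"class"` (predicted region), `"prob"`, `"logprob"`,
#'   `"score"` (pre-soft-max) or `"latent"` (last hidden activations)
#' @param ... unused
#' @return Factor of classes or a numeric matrix depending on `type`.
#' @export
predict.mlp_classifier <- function(object, newdata,
                                   type = c("class", "prob", "logprob",
                                            "score", "latent"), ...) {
  type <- match.arg(type)
  newdata <- .check_newdata(object, newdata)
  fw <- .forward(object$W, object$b, newdata)
  if (type == "latent") {
    out <- fw$H[[length(fw$H) - 1L]]
    rownames(out) <- rownames(newdata)
    return(out)
  }
  if (type == "score") {
    out <- fw$score
  } else {
    logp <- .log_softmax(fw$score)
    if (type == "class")
      return(factor(object$classes[max.col(logp, ties.method = "first")],
                    levels = object$classes))
    out <- if (type == "prob") exp(logp) else logp
  }
  dimnames(out) <- list(rownames(newdata), object$classes)
  out
}

#' Simulate labels from the fitted class probabilities
#' @param object an `mlp_classifier`
#' @param nsim number of simulated label vectors
#' @param seed optional seed
#' @param newdata observations-by-genes matrix
#' @param ... unused
#' @return data.frame with `nsim` columns of simulated region labels.
#' @export
simulate.mlp_classifier <- function(object, nsim = 1, seed = NULL,
                                    newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, newdata, type = "prob")
  out <- replicate(nsim, apply(p, 1, function(pr)
    sample(object$classes, 1L, prob = pr)))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Plot the training loss path
#' @param x an `mlp_classifier`
#' @param ... passed to [graphics::plot()]
#' @export
plot.mlp_classifier <- function(x, ...) {
  graphics::plot(seq_along(x$loss_path), x$loss_path, type = "l",
                 xlab = "epoch", ylab = "training NLL", ...)
  invisible(x)
}

#' Strip the output layer into a latent transform
#'
#' Removes the final linear layer and soft-max; the transform maps an
#' expression signature to the (non-negative, post-ReLU) activations of
#' the last hidden layer. The removed layer is retained so the original
#' classifier outputs can be reconstructed exactly.
#'
#' @param model a trained `mlp_classifier`
#' @return An object of class `"latent_transform"`.
#' @export
latent_transform <- function(model) {
  stopifnot(inherits(model, "mlp_classifier"))
  nL <- length(model$W)
  structure(
    list(W = model$W[-nL], b = model$b[-nL],
         final_W = model$W[[nL]], final_b = model$b[[nL]],
         input_dim = model$input_dim,
         latent_dim = ncol(model$W[[nL - 1L]]),
         classes = model$classes, config = model$config),
    class = "latent_transform"
  )
}

#' @export
print.latent_transform <- function(x, ...) {
  cat("Latent transform: ", x$input_dim, " genes -> ", x$latent_dim,
      " latent units (", length(x$W), " hidden layers, output layer removed)\n",
      sep = "")
  invisible(x)
}

#' Apply a latent transform
#'
#' @param object a `latent_transform`
#' @param newdata observations-by-genes matrix
#' @param type `"latent"` (default) or `"logprob"`, which re-attaches the
#'   retained output layer and must reproduce the original classifier
#' @param ... unused
#' @return Numeric matrix with one row per input row.
#' @export
predict.latent_transform <- function(object, newdata,
                                     type = c("latent", "logprob"), ...) {
  type <- match.arg(type)
  newdata <- .check_newdata(object, newdata)
  H <- newdata
  for (l in seq_along(object$W))
    H <- pmax(sweep(H %*% object$W[[l]], 2, object$b[[l]], "+"), 0)
  if (type == "latent") {
    rownames(H) <- rownames(newdata)
    colnames(H) <- paste0("h", seq_len(ncol(H)))
    return(H)
  }
  score <- sweep(H %*% object$final_W, 2, object$final_b, "+")
  out <- .log_softmax(score)
  dimnames(out) <- list(rownames(newdata), object$classes)
  out
}

#' Embed an expression matrix in the latent space
#'
#' Convenience wrapper around [predict.latent_transform()]: rows (regions,
#' voxels or samples) are preserved, columns become the latent units.
#'
#' @param x rows-by-genes numeric matrix
#' @param transform a `latent_transform`
#' @return rows-by-latent-units matrix.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "latent_transform"))
  predict(transform, x, type = "latent")
}

#' Train an ensemble of latent transforms
#'
#' Repeats training with seeds `base_seed + 1, ..., base_seed + n_members`
#' and strips each fit, producing the distribution of latent spaces over
#' which downstream statistics are computed.
#'
#' @param x observations-by-genes matrix
#' @param y region labels
#' @param config an [mlp_config()]; its seed field is overridden per member
#' @param n_members number of repeated trainings
#' @param base_seed base RNG seed
#' @param keep_models keep the full classifiers (needed for attribution)
#' @return An object of class `"latent_ensemble"`: lists `transforms`,
#'   `seeds`, optionally `models`, and the shared `config`.
#' @export
latent_ensemble <- function(x, y, config = mlp_config(), n_members = 20,
                            base_seed = 0, keep_models = FALSE) {
  stopifnot(n_members >= 1)
  seeds <- base_seed + seq_len(n_members)
  transforms <- vector("list", n_members)
  models <- if (keep_models) vector("list", n_members) else NULL
  for (i in seq_len(n_members)) {
    cfg_i <- config; cfg_i$seed <- as.integer(seeds[i])
    fit <- tryCatch(mlp_classifier(x, y, cfg_i), error = function(e)
      stop("ensemble member ", i, " (seed ", seeds[i], ") failed: ",
           conditionMessage(e)))
    transforms[[i]] <- latent_transform(fit)
    if (keep_models) models[[i]] <- fit
  }
  structure(list(transforms = transforms, seeds = seeds, config = config,
                 models = models),
            class = "latent_ensemble")
}

#' @export
print.latent_ensemble <- function(x, ...) {
  cat("Latent ensemble: ", length(x$transforms), " members, latent dim ",
      x$transforms[[1]]$latent_dim, ", seeds ", x$seeds[1], "..",
      x$seeds[length(x$seeds)], "\n", sep = "")
  invisible(x)
}

#' Serialize / restore a classifier as a JSON weight bundle
#'
#' @param model an `mlp_classifier`
#' @param path output path
#' @return `read_mlp` returns an `mlp_classifier`; `write_mlp` returns
#'   `path` invisibly.
#' @export
write_mlp <- function(model, path) {
  bundle <- list(
    config = unclass(model$config), sizes = model$sizes,
    classes = model$classes, features = model$features,
    loss = model$loss, accuracy = model$accuracy,
    loss_path = model$loss_path,
    W = lapply(model$W, function(w) list(dim = dim(w), data = as.vector(w))),
    b = model$b
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  bundle <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE)
  cfg <- bundle$config
  config <- mlp_config(cfg$n_hidden, cfg$n_units, cfg$weight_decay,
                       cfg$max_lr, cfg$optimizer, cfg$n_epochs,
                       cfg$batch_size, cfg$seed, cfg$pct_start,
                       cfg$div_factor, cfg$final_div)
  W <- lapply(bundle$W, function(w) matrix(w$data, w$dim[1], w$dim[2]))
  structure(
    list(W = W, b = lapply(bundle$b, as.numeric), config = config,
         input_dim = bundle$sizes[1],
         classes = bundle$classes, sizes = bundle$sizes,
         features = bundle$features, loss = bundle$loss,
         accuracy = bundle$accuracy, loss_path = bundle$loss_path),
    class = "mlp_classifier"
  )
}
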