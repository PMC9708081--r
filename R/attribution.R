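#' Integrated-gradients gene attribution
#'
#' Attributes a classifier's decision for a target region to its input
#' genes. The attribution of gene i is `(x_i - b_i)` times the average,
#' over a uniform grid on the straight path from baseline `b` to input
#' `x`, of the partial derivative of the target's pre-soft-max score.
#' The method satisfies completeness: attributions sum to
#' `F(x) - F(b)` as the grid is refined, and are exact for linear
#' scorers at any grid size.
#'
#' @name attribution
NULL

# gradient of the target's score (pre-soft-max, or log-soft-max output)
# with respect to each input row; X is rows-by-genes
.input_gradient <- function(model, X, target_idx, score = "presoftmax") {
  fw <- .forward(model$W, model$b, X)
  nL <- length(model$W)
  n <- nrow(X)
  if (score == "presoftmax") {
    Gz <- matrix(0, n, length(model$classes))
    Gz[, target_idx] <- 1
  } else {
    # d log p_t / d z = onehot(t) - softmax(z)
    P <- exp(.log_softmax(fw$score))
    Gz <- -P
    Gz[, target_idx] <- Gz[, target_idx] + 1
  }
  for (l in rev(seq_len(nL))) {
    Gz <- Gz %*% t(model$W[[l]])
    if (l > 1L) Gz <- Gz * (fw$Z[[l - 1L]] > 0)
  }
  Gz
}

# target's scalar score for each row
.target_score <- function(model, X, target_idx, score = "presoftmax") {
  fw <- .forward(model$W, model$b, X)
  out <- if (score == "presoftmax") fw$score else .log_softmax(fw$score)
  out[, target_idx]
}

.resolve_target <- function(model, target) {
  idx <- if (is.character(target)) match(target, model$classes)
         else as.integer(target)
  if (is.na(idx) || idx < 1 || idx > length(model$classes))
    stop("invalid target label: ", target)
  idx
}

#' Integrated gradients for one input
#'
#' Trapezoidal approximation of the path integral on `steps` uniformly
#' spaced points from the baseline to the input (endpoints included).
#'
#' @param model a trained `mlp_classifier`
#' @param x input vector (one expression signature)
#' @param target region label (name or index) whose score is attributed
#' @param baseline baseline vector; default the zero vector, the origin
#'   of centred expression space
#' @param steps grid size `m >= 2`, default 50
#' @param score `"presoftmax"` (default) or `"logprob"`
#' @return An object of class `"attribution"`: named numeric vector of
#'   per-gene scores with metadata attributes `steps`, `baseline`,
#'   `target` and `delta_score` (`F(x) - F(b)`, the completeness
#'   reference).
#' @export
integrated_gradients <- function(model, x, target, baseline = NULL,
                                 steps = 50,
                                 score = c("presoftmax", "logprob")) {
  score <- match.arg(score)
  stopifnot(steps >= 2)
  x <- as.numeric(x)
  if (length(x) != model$input_dim)
    stop("input has ", length(x), " features; model expects ",
         model$input_dim)
  if (is.null(baseline)) baseline <- numeric(length(x))
  stopifnot(length(baseline) == length(x))
  t_idx <- .resolve_target(model, target)

  alphas <- seq(0, 1, length.out = steps)
  path <- outer(alphas, x - baseline) +
    matrix(baseline, steps, length(x), byrow = TRUE)
  grads <- .input_gradient(model, path, t_idx, score)
  w <- c(0.5, rep(1, steps - 2), 0.5) / (steps - 1)   # trapezoid weights
  avg_grad <- colSums(grads * w)
  attr_vec <- (x - baseline) * avg_grad
  names(attr_vec) <- model$features
  delta <- .target_score(model, rbind(x), t_idx, score) -
    .target_score(model, rbind(baseline), t_idx, score)
  structure(attr_vec, class = "attribution", steps = as.integer(steps),
            baseline = baseline, target = model$classes[t_idx],
            score = score, delta_score = unname(delta))
}

#' @export
print.attribution <- function(x, ...) {
  top <- utils::head(order(-abs(unclass(x))), 5)
  cat("Integrated gradients for target '", attr(x, "target"), "' (m = ",
      attr(x, "steps"), ")\n", sep = "")
  cat("  sum = ", signif(sum(x), 4), "; F(x) - F(b) = ",
      signif(attr(x, "delta_score"), 4), "\n", sep = "")
  cat("  top genes:", paste(names(x)[top], signif(unclass(x)[top], 3),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Completeness gap of an attribution
#'
#' @param a an `"attribution"`
#' @return Absolute difference between the attribution sum and
#'   `F(x) - F(b)`.
#' @export
completeness_gap <- function(a) {
  abs(sum(unclass(a)) - attr(a, "delta_score"))
}

#' Region-level gene attribution over voxels and training runs
#'
#' Integrated gradients are computed for every voxel of a region against
#' the same target label, averaged over voxels, and then averaged over an
#' ensemble of independently trained classifiers.
#'
#' @param models list of trained `mlp_classifier` objects (e.g. the
#'   `models` field of a [latent_ensemble()] with `keep_models = TRUE`)
#' @param voxels voxels-by-genes matrix of the region's signatures
#' @param target region label to attribute
#' @param baseline,steps,score as in [integrated_gradients()]
#' @return Named numeric vector of mean per-gene attributions, with
#'   attributes `n_voxels` and `n_runs`.
#' @export
region_attribution <- function(models, voxels, target, baseline = NULL,
                               steps = 50,
                               score = c("presoftmax", "logprob")) {
  score <- match.arg(score)
  stopifnot(is.list(models), length(models) >= 1, is.matrix(voxels),
            nrow(voxels) >= 1)
  per_run <- lapply(models, function(m) {
    per_voxel <- apply(voxels, 1, function(v)
      unclass(integrated_gradients(m, v, target, baseline = baseline,
                                   steps = steps, score = score)))
    rowMeans(per_voxel)   # apply returns genes x voxels
  })
  out <- Reduce(`+`, per_run) / length(per_run)
  attr(out, "n_voxels") <- nrow(voxels)
  attr(out, "n_runs") <- length(models)
  attr(out, "target") <- if (is.character(target)) target
                         else models[[1]]$classes[target]
  out
}

#' Write an attribution table as TSV
#'
#' @param a named attribution vector (from [integrated_gradients()] or
#'   [region_attribution()])
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_attribution <- function(a, path) {
  v <- unclass(a)
  df <- data.frame(gene = names(v), score = as.numeric(v))
  df <- df[order(-df$score), ]
  df$rank <- seq_len(nrow(df))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
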