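#' Hyperparameter selection with per-gene experiment splits
#'
#' Most genes in the coronal in-situ hybridization data are sampled only
#' once brain-wide, so conventional sample-wise cross-validation is not
#' possible. Instead, train/validation pairs are built per gene from
#' replicate experiments: a gene with two or more coronal experiments
#' contributes one to each side; a gene with a single coronal experiment
#' is paired with its sagittal experiment, the assignment randomized.
#' Both sides share the unilateral (sagittal-extent) mask and replicate
#' experiments are deliberately not averaged.
#'
#' @name model_selection
NULL

#' Build an experiment pool for split construction
#'
#' @param records an `experiment_set` (log2 scale, restricted to the
#'   unilateral mask and to the homologous gene set); replicate coronal
#'   experiments must be unaveraged
#' @return An object of class `"experiment_pool"`.
#' @export
experiment_pool <- function(records) {
  stopifnot(inherits(records, "experiment_set"))
  genes <- unique(records$info$gene)
  for (g in genes) {
    sub <- records$info[records$info$gene == g, ]
    n_cor <- sum(sub$plane == "coronal")
    n_sag <- sum(sub$plane == "sagittal")
    if (n_cor + n_sag < 2 || (n_cor == 0 && n_sag >= 1))
      stop("gene ", g, " has no valid split source (",
           n_cor, " coronal, ", n_sag, " sagittal experiments)")
  }
  structure(list(records = records, genes = genes),
            class = "experiment_pool")
}

#' @export
print.experiment_pool <- function(x, ...) {
  cat("Experiment pool:", length(x$genes), "genes,",
      nrow(x$records$info), "experiments\n")
  invisible(x)
}

#' Sample a train/validation split from an experiment pool
#'
#' Per gene, one experiment goes to each side and none to both. Both
#' sides are imputed (when missing values remain) and normalized with
#' [normalize_expression()] before return.
#'
#' @param pool an [experiment_pool()]
#' @param seed RNG seed for the random assignments
#' @param impute_k neighbours for [knn_impute()] when either side still
#'   has missing values
#' @return List with `train` and `validation` (genes-by-voxels matrices,
#'   one row per pooled gene) and `provenance` (data.frame of the chosen
#'   experiment ids per gene).
#' @export
sample_split <- function(pool, seed = 1, impute_k = 5) {
  stopifnot(inherits(pool, "experiment_pool"))
  info <- pool$records$info
  if (exists(".Random.seed", globalenv()))
    old_seed <- get(".Random.seed", globalenv()) else old_seed <- NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  train_id <- val_id <- character(length(pool$genes))
  for (i in seq_along(pool$genes)) {
    g <- pool$genes[i]
    cor_ids <- info$experiment_id[info$gene == g & info$plane == "coronal"]
    sag_ids <- info$experiment_id[info$gene == g & info$plane == "sagittal"]
    if (length(cor_ids) >= 2) {
      train_id[i] <- sample(cor_ids, 1)
      val_id[i] <- sample(setdiff(cor_ids, train_id[i]), 1)
    } else if (length(cor_ids) == 1 && length(sag_ids) >= 1) {
      pair <- c(cor_ids, sample(sag_ids, 1))
      pick <- sample(2, 1)
      train_id[i] <- pair[pick]; val_id[i] <- pair[3 - pick]
    } else {
      stop("gene ", g, " has a single experiment; cannot split")
    }
  }
  build <- function(ids) {
    m <- pool$records$values[ids, , drop = FALSE]
    rownames(m) <- pool$genes
    if (anyNA(m)) m <- knn_impute(m, k = impute_k)
    normalize_expression(m)
  }
  list(train = build(train_id), validation = build(val_id),
       provenance = data.frame(gene = pool$genes, train = train_id,
                               validation = val_id))
}

#' Enumerate a classifier hyperparameter grid
#'
#' Defaults reproduce the reference search grid: 3/4/5 hidden layers,
#' 200/500/1000 units, weight decay 0/1e-6/1e-3, six maximum learning
#' rates from 1e-6 to 1e-1, and SGD vs AdamW -- 324 configurations.
#'
#' @param n_hidden,n_units,weight_decay,max_lr,optimizer vectors of
#'   candidate values
#' @param ... further arguments passed to every [mlp_config()] (e.g.
#'   `n_epochs`)
#' @return List of `mlp_config` objects.
#' @export
classifier_grid <- function(n_hidden = c(3, 4, 5),
                            n_units = c(200, 500, 1000),
                            weight_decay = c(0, 1e-6, 1e-3),
                            max_lr = c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2, 1e-1),
                            optimizer = c("SGD", "AdamW"), ...) {
  combos <- expand.grid(n_hidden = n_hidden, n_units = n_units,
                        weight_decay = weight_decay, max_lr = max_lr,
                        optimizer = optimizer, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i)
    mlp_config(n_hidden = combos$n_hidden[i], n_units = combos$n_units[i],
               weight_decay = combos$weight_decay[i],
               max_lr = combos$max_lr[i], optimizer = combos$optimizer[i],
               ...))
}

#' Read a hyperparameter grid from a YAML specification
#'
#' The file holds one entry per tuned hyperparameter, each a scalar or a
#' list of candidate values (`n_hidden`, `n_units`, `weight_decay`,
#' `max_lr`, `optimizer`), plus optional fixed settings (e.g.
#' `n_epochs`) applied to every configuration.
#'
#' @param path YAML path
#' @return List of `mlp_config` objects, as from [classifier_grid()].
#' @export
read_grid_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  do.call(classifier_grid, spec)
}

#' Write grid-search results as TSV plus a JSON best-config record
#'
#' @param result a `grid_result` from [run_grid_search()]
#' @param dir output directory (created if needed)
#' @return The directory path, invisibly.
#' @export
write_grid_result <- function(result, dir) {
  stopifnot(inherits(result, "grid_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$table, file.path(dir, "grid_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(list(best_index = result$best_index,
           criterion = result$criterion),
      unclass(result$best_config)),
    file.path(dir, "best_config.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' Grid search over classifier configurations
#'
#' Each configuration is trained and validated on `n_repeats` freshly
#' sampled splits. The best configuration minimizes mean validation loss
#' (or maximizes mean validation accuracy with
#' `criterion = "val_accuracy"`). A configuration whose repeats all fail
#' is disqualified; individual failures are recorded as `NA` rows.
#'
#' @param pool an [experiment_pool()]
#' @param labels region label per voxel (column of the pool matrices)
#' @param grid list of `mlp_config`s, e.g. from [classifier_grid()]
#' @param n_repeats splits per configuration, default 5
#' @param seed base seed; split `r` uses `seed + r`, and member training
#'   seeds derive from it
#' @param criterion selection rule
#' @param impute_k passed to [sample_split()]
#' @return An object of class `"grid_result"`: `table` (one row per
#'   config x repeat), `configs`, `best_config`, `best_index`.
#' @export
run_grid_search <- function(pool, labels, grid, n_repeats = 5, seed = 1,
                            criterion = c("val_loss", "val_accuracy"),
                            impute_k = 5) {
  criterion <- match.arg(criterion)
  stopifnot(length(grid) >= 1)
  splits <- lapply(seq_len(n_repeats), function(r)
    sample_split(pool, seed = seed + r, impute_k = impute_k))
  rows <- list()
  for (ci in seq_along(grid)) {
    for (r in seq_len(n_repeats)) {
      cfg <- grid[[ci]]
      cfg$seed <- as.integer(seed * 1000L + ci * 10L + r)
      res <- tryCatch({
        fit <- mlp_classifier(t(splits[[r]]$train), labels, cfg)
        vX <- t(splits[[r]]$validation)
        logp <- predict(fit, vX, type = "logprob")
        y_idx <- as.integer(factor(labels, levels = fit$classes))
        list(train_loss = fit$loss, train_acc = fit$accuracy,
             val_loss = .nll(logp, y_idx),
             val_acc = mean(max.col(logp, ties.method = "first") == y_idx))
      }, error = function(e) list(train_loss = NA_real_, train_acc = NA_real_,
                                  val_loss = NA_real_, val_acc = NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        config = ci, rep = r,
        train_loss = res$train_loss, val_loss = res$val_loss,
        train_accuracy = res$train_acc, val_accuracy = res$val_acc)
    }
  }
  table <- do.call(rbind, rows)
  agg <- if (criterion == "val_loss")
    tapply(table$val_loss, table$config, mean, na.rm = TRUE)
  else -tapply(table$val_accuracy, table$config, mean, na.rm = TRUE)
  agg[is.nan(agg)] <- Inf   # all repeats failed -> disqualified
  if (all(!is.finite(agg))) stop("every configuration failed on all repeats")
  best <- as.integer(names(agg)[which.min(agg)])
  structure(list(table = table, configs = grid,
                 best_config = grid[[best]], best_index = best,
                 criterion = criterion),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("Grid search:", length(x$configs), "configurations x",
      max(x$table$rep), "repeats; criterion", x$criterion, "\n")
  cat("best configuration (index ", x$best_index, "):\n", sep = "")
  print(x$best_config)
  invisible(x)
}
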