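# Shared fixtures, built in code at test time.

# ten-node ontology: root -> {cortex -> {a1, a2, a3}, nuclei -> {n1, n2},
# white_matter -> {wm1, wm2}}
fixture_tree <- function() {
  ontology(data.frame(
    id = c(1L, 2L, 21L, 22L, 23L, 3L, 31L, 32L, 4L, 41L),
    name = c("root", "cortex", "a1", "a2", "a3", "nuclei", "n1", "n2",
             "white_matter", "wm1"),
    acronym = c("root", "CTX", "a1", "a2", "a3", "NUC", "n1", "n2",
                "WM", "wm1"),
    color = "AABBCC",
    parent_id = c(NA, 1L, 2L, 2L, 2L, 1L, 3L, 3L, 1L, 4L)
  ))
}

# reduced synthetic study for fast unit tests: 2 broad x 2 fine regions,
# 96 voxels, 20 genes
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_broad = 2, fine_per_broad = 2, dims = c(4L, 3L, 8L),
                   n_genes = 20, markers_per_region = 2,
                   samples_per_region = 3, seed = 123)
  do.call(synthetic_spec, utils::modifyList(defaults, args))
}

# quick-training classifier configuration for unit tests
fast_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_hidden = 2, n_units = 16, max_lr = 1e-2,
                   n_epochs = 40, batch_size = 64, seed = 1)
  do.call(mlp_config, utils::modifyList(defaults, args))
}

# the desk-scale study conditions used by the end-to-end checks:
# plateau regime (broad effect much larger than the marker effect,
# mimicking within-system homogeneity) and the desk classifier
plateau_spec <- function(seed) {
  synthetic_spec(marker_effect = 0.3, broad_effect = 2, noise_sd = 0.3,
                 seed = seed)
}

desk_cfg <- function(seed = 1) {
  mlp_config(n_hidden = 3, n_units = 64, max_lr = 1e-2, n_epochs = 100,
             batch_size = 128, seed = seed)
}

# well-separated three-region classification fixture: marker effect far
# above noise, used for training sanity checks
separable_fixture <- function(n_per = 40, n_genes = 12, seed = 7) {
  set.seed(seed)
  classes <- rep(c("r1", "r2", "r3"), each = n_per)
  centers <- matrix(0, 3, n_genes)
  centers[1, 1:4] <- 4; centers[2, 5:8] <- 4; centers[3, 9:12] <- 4
  x <- centers[rep(1:3, each = n_per), ] +
    matrix(rnorm(3 * n_per * n_genes, sd = 0.3), 3 * n_per, n_genes)
  colnames(x) <- paste0("g", seq_len(n_genes))
  list(x = x, y = classes)
}

# hand-built linear scorer inside the classifier class: one linear layer
# (no hidden ReLU), score_1 = w . x
linear_model <- function(w) {
  structure(list(
    W = list(cbind(w, 0)), b = list(c(0, 0)),
    config = NULL, input_dim = length(w),
    classes = c("target", "other"),
    sizes = c(length(w), 2L),
    features = paste0("g", seq_along(w)),
    loss = NA_real_, accuracy = NA_real_, loss_path = numeric(0)),
    class = "mlp_classifier")
}
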