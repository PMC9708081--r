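#' Synthetic two-species atlas and expression generator
#'
#' Generates desk-scale data with the statistical structure the analysis
#' assumes, and known ground truth. A hierarchically labelled 3-D atlas
#' (root -> broad regions -> fine regions, contiguous blocks) is paired
#' with per-gene replicate "energy" experiments in two acquisition
#' planes (the sagittal plane restricted to a unilateral mask), missing
#' values, and region-labelled human-style samples. Expression of gene g
#' in fine region f of broad region B is, on the log2 scale,
#' `base + broad(g, B) + marker_effect * [g is a marker of f]` plus
#' Gaussian noise per experiment; human regions share the homologous
#' mouse region means up to a tunable divergence, so cross-species
#' conservation is a single dial. Marker genes planted per fine region
#' are the ground truth for attribution; the region pairing itself is
#' the ground truth for the homology criterion.
#'
#' @name synthetic_data
NULL

#' Parameters of the synthetic study
#'
#' Defaults describe the desk-scale study: 4 broad x 3 fine regions in a
#' 5 x 5 x 60 grid of 200 um voxels (125 voxels per fine region, 1500
#' in total), 60 genes with 2 planted markers per fine region, marker
#' effect twice the noise sd, 5 human samples per region, and mild
#' cross-species divergence.
#'
#' @param n_broad broad regions
#' @param fine_per_broad fine regions per broad region
#' @param dims volume dimensions (x = left-right); fine regions occupy
#'   consecutive slabs along the last axis
#' @param n_genes genes
#' @param markers_per_region planted marker genes per fine region
#' @param marker_effect log2 marker boost
#' @param broad_effect sd of the per-gene broad-region effect
#' @param noise_sd per-experiment voxel noise sd (log2 scale)
#' @param replicate_lambda coronal replicate count is `1 + Poisson(lambda)`
#' @param missing_rate fraction of cells replaced by the missing sentinel
#' @param sagittal generate a unilateral sagittal experiment per gene
#' @param samples_per_region human samples per region
#' @param divergence_sd sd of the per-gene, per-region cross-species
#'   divergence added to human region means
#' @param base_level baseline log2 expression
#' @param seed RNG seed; fixed seed reproduces outputs exactly
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_broad = 4, fine_per_broad = 3,
                           dims = c(5, 5, 60), n_genes = 60,
                           markers_per_region = 2, marker_effect = 1,
                           broad_effect = 1, noise_sd = 0.5,
                           replicate_lambda = 0.3, missing_rate = 0.05,
                           sagittal = TRUE, samples_per_region = 5,
                           divergence_sd = 0.1, base_level = 6,
                           seed = 42) {
  stopifnot(n_broad >= 1, fine_per_broad >= 1, n_genes >= 1,
            markers_per_region >= 0, marker_effect >= 0, broad_effect >= 0,
            noise_sd >= 0, replicate_lambda >= 0,
            missing_rate >= 0, missing_rate <= 1,
            samples_per_region >= 1, divergence_sd >= 0,
            length(dims) == 3, all(dims >= 1))
  n_fine <- n_broad * fine_per_broad
  if (markers_per_region * n_fine > n_genes)
    stop("not enough genes for ", markers_per_region,
         " disjoint markers in each of ", n_fine, " regions")
  structure(list(n_broad = as.integer(n_broad),
                 fine_per_broad = as.integer(fine_per_broad),
                 dims = as.integer(dims), n_genes = as.integer(n_genes),
                 markers_per_region = as.integer(markers_per_region),
                 marker_effect = marker_effect, broad_effect = broad_effect,
                 noise_sd = noise_sd, replicate_lambda = replicate_lambda,
                 missing_rate = missing_rate, sagittal = sagittal,
                 samples_per_region = as.integer(samples_per_region),
                 divergence_sd = divergence_sd, base_level = base_level,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic study spec: ", x$n_broad, " broad x ", x$fine_per_broad,
      " fine regions in a ", paste(x$dims, collapse = "x"), " grid; ",
      x$n_genes, " genes (", x$markers_per_region,
      " markers/region, effect ", x$marker_effect, ", broad sd ",
      x$broad_effect, ", noise sd ", x$noise_sd, "); seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

.fine_names <- function(spec) {
  unlist(lapply(seq_len(spec$n_broad), function(b)
    paste0("B", b, ".F", seq_len(spec$fine_per_broad))))
}

.fine_ids <- function(spec) 10L + seq_len(spec$n_broad * spec$fine_per_broad)

#' Generate the synthetic atlas
#'
#' Fine regions occupy consecutive slabs of equal thickness along the
#' last axis; trailing slices that do not fit are background. The
#' unilateral variant keeps one hemisphere along the first (left-right)
#' axis, excluding the midline plane when that axis has odd size.
#'
#' @param spec a [synthetic_spec()]
#' @return List with `tree` (an [ontology()]), `volume` and
#'   `volume_unilateral` (both [atlas_volume()]).
#' @export
generate_atlas <- function(spec) {
  n_fine <- spec$n_broad * spec$fine_per_broad
  slab <- spec$dims[3] %/% n_fine
  if (slab < 1)
    stop("dims too small: ", spec$dims[3], " slices cannot hold ",
         n_fine, " fine regions")
  fine_names <- .fine_names(spec)
  fine_ids <- .fine_ids(spec)
  broad_ids <- 1L + seq_len(spec$n_broad)
  nodes <- rbind(
    data.frame(id = 1L, name = "root", acronym = "root",
               color = "FFFFFF", parent_id = NA_integer_),
    data.frame(id = broad_ids, name = paste0("B", seq_len(spec$n_broad)),
               acronym = paste0("B", seq_len(spec$n_broad)),
               color = "CCCCCC", parent_id = 1L),
    data.frame(id = fine_ids, name = fine_names, acronym = fine_names,
               color = "999999",
               parent_id = rep(broad_ids, each = spec$fine_per_broad))
  )
  labels <- array(0L, dim = spec$dims)
  for (f in seq_len(n_fine))
    labels[, , ((f - 1L) * slab + 1L):(f * slab)] <- fine_ids[f]
  half <- (spec$dims[1] - spec$dims[1] %% 2L) %/% 2L
  uni_labels <- labels
  if (half >= 1 && half < spec$dims[1])
    uni_labels[(half + 1L):spec$dims[1], , ] <- 0L
  list(tree = ontology(nodes),
       volume = atlas_volume(labels),
       volume_unilateral = atlas_volume(uni_labels))
}

#' Region label of every in-mask voxel
#'
#' Voxels are ordered by `which(mask)` (column-major), the observation
#' order used throughout for voxel-level matrices.
#'
#' @param volume an `atlas_volume`
#' @param tree optional `ontology`; when given, labels are acronyms
#'   rather than ids
#' @return Character (or integer) vector, one entry per in-mask voxel.
#' @export
voxel_labels <- function(volume, tree = NULL) {
  ids <- volume$labels[volume$mask]
  if (is.null(tree)) return(ids)
  acr <- stats::setNames(tree$nodes$acronym, tree$nodes$id)
  unname(acr[as.character(ids)])
}

#' Planted ground truth of the synthetic study
#'
#' @param spec a [synthetic_spec()]
#' @return List with `genes`, `homology_map` (named character vector,
#'   mouse fine region -> human region), `canonical_pairs` (data.frame),
#'   `markers` (named list of marker genes per fine region) and
#'   `homologs` (a one-to-one homolog table).
#' @export
generate_ground_truth <- function(spec) {
  if (exists(".Random.seed", globalenv()))
    old_seed <- get(".Random.seed", globalenv()) else old_seed <- NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  genes <- sprintf("Gene%03d", seq_len(spec$n_genes))
  fine <- .fine_names(spec)
  human <- paste0("H_", fine)
  pool <- sample(genes, spec$markers_per_region * length(fine))
  markers <- split(pool, rep(seq_along(fine),
                             each = spec$markers_per_region))
  names(markers) <- fine
  list(genes = genes,
       homology_map = stats::setNames(human, fine),
       canonical_pairs = data.frame(mouse = fine, human = human),
       markers = markers,
       homologs = data.frame(group_id = seq_along(genes),
                             mouse_symbol = genes,
                             human_symbol = toupper(genes)))
}

#' Generate the paired mouse/human expression data
#'
#' @param spec a [synthetic_spec()]
#' @param atlas result of [generate_atlas()]
#' @param truth result of [generate_ground_truth()]
#' @return List with `mouse_records` (an [experiment_set()] of raw
#'   energies over the bilateral in-mask voxels; sagittal experiments
#'   carry the sentinel outside the unilateral extent), `human` (an
#'   [expr_matrix()] of log2 values with region annotations), and
#'   `region_means` (the noiseless log2 gene-by-fine-region means).
#' @export
generate_expression_pair <- function(spec, atlas, truth) {
  if (exists(".Random.seed", globalenv()))
    old_seed <- get(".Random.seed", globalenv()) else old_seed <- NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed + 1L)
  genes <- truth$genes
  fine <- .fine_names(spec)
  n_fine <- length(fine)
  # per-gene broad effect and marker boost define the regional means
  beta <- matrix(stats::rnorm(spec$n_genes * spec$n_broad,
                              sd = spec$broad_effect),
                 spec$n_genes, spec$n_broad,
                 dimnames = list(genes, NULL))
  mu <- spec$base_level +
    beta[, rep(seq_len(spec$n_broad), each = spec$fine_per_broad)]
  colnames(mu) <- fine
  for (f in fine)
    mu[truth$markers[[f]], f] <- mu[truth$markers[[f]], f] +
      spec$marker_effect

  vox_region <- voxel_labels(atlas$volume, atlas$tree)
  n_vox <- length(vox_region)
  uni_in_bilateral <- atlas$volume_unilateral$mask[atlas$volume$mask]

  make_exp <- function(gene, unilateral) {
    v <- 2^(mu[gene, vox_region] +
              stats::rnorm(n_vox, sd = spec$noise_sd))
    drop <- stats::runif(n_vox) < spec$missing_rate
    v[drop] <- -1
    if (unilateral) v[!uni_in_bilateral] <- -1
    unname(v)
  }

  values <- list(); info <- list()
  for (g in genes) {
    n_cor <- 1L + stats::rpois(1, spec$replicate_lambda)
    for (j in seq_len(n_cor)) {
      values[[length(values) + 1L]] <- make_exp(g, FALSE)
      info[[length(info) + 1L]] <- data.frame(
        experiment_id = paste0("cor_", g, "_", j), gene = g,
        plane = "coronal")
    }
    if (spec$sagittal) {
      values[[length(values) + 1L]] <- make_exp(g, TRUE)
      info[[length(info) + 1L]] <- data.frame(
        experiment_id = paste0("sag_", g), gene = g, plane = "sagittal")
    }
  }
  records <- experiment_set(do.call(rbind, values), do.call(rbind, info))
  colnames(records$values) <- paste0("v", seq_len(n_vox))

  # human samples share the homologous region means up to divergence
  human_regions <- unname(truth$homology_map[fine])
  delta <- matrix(stats::rnorm(spec$n_genes * n_fine,
                               sd = spec$divergence_sd),
                  spec$n_genes, n_fine)
  hv <- matrix(NA_real_, spec$n_genes, n_fine * spec$samples_per_region)
  region_of_sample <- character(ncol(hv))
  col <- 0L
  for (f in seq_len(n_fine)) {
    for (s in seq_len(spec$samples_per_region)) {
      col <- col + 1L
      hv[, col] <- mu[, f] + delta[, f] +
        stats::rnorm(spec$n_genes, sd = spec$noise_sd)
      region_of_sample[col] <- human_regions[f]
    }
  }
  rownames(hv) <- truth$homologs$human_symbol
  colnames(hv) <- paste0("s", seq_len(ncol(hv)))
  human <- expr_matrix(hv, data.frame(id = colnames(hv),
                                      region = region_of_sample,
                                      donor = "d1"))
  list(mouse_records = records, human = human, region_means = mu)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: atlas, ground truth and expression pair under a
#' single spec.
#'
#' @param spec a [synthetic_spec()]
#' @return List with `spec`, `tree`, `volume`, `volume_unilateral`,
#'   `truth`, `mouse_records`, `human`, `region_means` and `voxel_region`
#'   (region label per bilateral in-mask voxel).
#' @export
simulate_study <- function(spec = synthetic_spec()) {
  atlas <- generate_atlas(spec)
  truth <- generate_ground_truth(spec)
  pair <- generate_expression_pair(spec, atlas, truth)
  c(list(spec = spec), atlas, list(truth = truth),
    pair, list(voxel_region = voxel_labels(atlas$volume, atlas$tree)))
}
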