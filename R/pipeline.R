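#' End-to-end workflow
#'
#' Orchestrates the stages of the common-space analysis on synthetic (or
#' pre-assembled) data: simulate -> preprocess -> similarity -> latent
#' ensemble -> evaluation -> clustering / attribution. Every run records
#' its seed and a hash of its configuration next to the outputs so that
#' identical configuration and seed reproduce identical numbers.
#'
#' @name workflow
NULL

#' Preprocess raw mouse experiment records
#'
#' The fixed preprocessing order: log2 transform, replicate averaging,
#' missingness filter, K-nearest-neighbour imputation.
#'
#' @param records an [experiment_set()] of raw energies
#' @param knn_k neighbours for imputation
#' @param max_missing missingness filter threshold
#' @param pseudocount optional log2 pseudocount
#' @return A complete (no missing values) `expr_matrix`, genes by voxels.
#' @export
preprocess_mouse <- function(records, knn_k = 5, max_missing = 0.2,
                             pseudocount = NULL) {
  em <- average_replicate_experiments(log2_transform(records, pseudocount))
  em <- filter_genes_by_missingness(em, max_missing)
  knn_impute(em, k = knn_k)
}

#' Build the homologous-gene common space
#'
#' Aligns the two species on homologous genes, applies the two-step
#' normalization to each matrix, and aggregates to gene-by-region means.
#'
#' @param mouse genes-by-voxels `expr_matrix` (complete)
#' @param human genes-by-samples `expr_matrix` with `region` annotations
#' @param homologs homolog table (`group_id`, `mouse_symbol`,
#'   `human_symbol`)
#' @param mouse_regions region label per mouse voxel
#' @return List with `mouse_region` / `human_region` (regions-by-genes
#'   matrices), `mouse_norm` / `human_norm` (normalized observation-level
#'   matrices) and the resolved homolog `table`.
#' @export
build_common_space <- function(mouse, human, homologs, mouse_regions) {
  inter <- intersect_homologous_genes(mouse, human, homologs)
  m_norm <- normalize_expression(inter$mouse)
  h_norm <- normalize_expression(inter$human)
  list(
    mouse_region = aggregate_by_region(m_norm, regions = mouse_regions),
    human_region = aggregate_by_region(h_norm),
    mouse_norm = m_norm, human_norm = h_norm,
    table = inter$table
  )
}

#' Locality ranks of every seed region
#'
#' For each row (seed region) of a similarity matrix, the rank at which
#' its scaled, rank-ordered profile first reaches `tau`.
#'
#' @param sim similarity matrix (seeds in rows)
#' @param tau scaled-similarity threshold, default 0.75
#' @return Named integer vector.
#' @export
locality_ranks <- function(sim, tau = 0.75) {
  vapply(rownames(sim), function(r)
    rank_at_threshold(scale_unit_interval(sim[r, ], seed = r), tau),
    0L)
}

#' Canonical-pair ranks of every seed region
#'
#' @param sim similarity matrix (mouse seeds in rows, human targets in
#'   columns)
#' @param pairs data.frame with columns `mouse`, `human`
#' @return Named integer vector of the canonical human match's rank per
#'   mouse seed.
#' @export
homology_ranks <- function(sim, pairs) {
  stats::setNames(vapply(seq_len(nrow(pairs)), function(i)
    rank_of_target(scale_unit_interval(sim[pairs$mouse[i], ],
                                       seed = pairs$mouse[i]),
                   pairs$human[i]),
    0L), pairs$mouse)
}

#' Latent-space similarity matrices of an ensemble
#'
#' Embeds both species' region matrices with every ensemble member and
#' correlates them.
#'
#' @param ensemble a [latent_ensemble()]
#' @param mouse_region,human_region regions-by-genes matrices (same gene
#'   order as the training features)
#' @return List of similarity matrices, one per member.
#' @export
ensemble_similarities <- function(ensemble, mouse_region, human_region) {
  lapply(ensemble$transforms, function(tr)
    pearson_similarity(apply_transform(mouse_region, tr),
                       apply_transform(human_region, tr)))
}

#' Rank-improvement evaluation of a latent ensemble
#'
#' Computes, per region and ensemble member, the latent-minus-gene-space
#' difference of the locality rank (and, when canonical pairs are given,
#' of the canonical match's rank) and summarises them with
#' [evaluate_improvement()].
#'
#' @param gene_sim gene-space similarity matrix
#' @param latent_sims list of latent-space similarity matrices
#' @param pairs optional canonical pair data.frame (`mouse`, `human`)
#' @param tau locality threshold
#' @param boot_draws,boot_seed bootstrap settings for
#'   [evaluate_improvement()]
#' @return List with `locality` and (optionally) `homology` improvement
#'   summaries, plus the underlying rank matrices.
#' @export
evaluate_latent_benefit <- function(gene_sim, latent_sims, pairs = NULL,
                                    tau = 0.75, boot_draws = 10000,
                                    boot_seed = 1) {
  loc_gene <- locality_ranks(gene_sim, tau)
  loc_lat <- vapply(latent_sims, function(s) locality_ranks(s, tau),
                    integer(nrow(gene_sim)))
  loc_diff <- loc_lat - loc_gene
  out <- list(
    locality = evaluate_improvement(loc_diff, boot_draws, boot_seed),
    locality_ranks_gene = loc_gene, locality_diffs = loc_diff
  )
  if (!is.null(pairs)) {
    hom_gene <- homology_ranks(gene_sim, pairs)
    hom_lat <- vapply(latent_sims, function(s) homology_ranks(s, pairs),
                      integer(nrow(pairs)))
    hom_diff <- hom_lat - hom_gene
    out$homology <- evaluate_improvement(hom_diff, boot_draws, boot_seed)
    out$homology_ranks_gene <- hom_gene
    out$homology_diffs <- hom_diff
  }
  out
}

#' Default desk-scale pipeline configuration
#'
#' The classifier used on the synthetic study is narrower than the
#' reference model (3 hidden layers of 64 units, AdamW, max learning
#' rate 1e-3, 100 epochs, full batch), sized to the 60-gene,
#' 12-region problem.
#'
#' @return Nested configuration list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    stages = c("simulate", "preprocess", "similarity", "latent",
               "evaluate", "cluster", "attribute"),
    synthetic = list(),
    prep = list(knn_k = 5, max_missing = 0.2),
    similarity = list(tau = 0.75),
    latent = list(n_hidden = 3, n_units = 64, max_lr = 1e-3,
                  optimizer = "AdamW", n_epochs = 100, weight_decay = 0,
                  n_members = 20, base_seed = 0),
    evaluate = list(boot_draws = 10000),
    cluster = list(k = NULL),
    attribute = list(steps = 50, n_runs = 5, max_voxels = 20)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

.require_stage <- function(state, field, stage, needs) {
  if (is.null(state[[field]]))
    stop("stage '", stage, "' requires results from stage '", needs,
         "'; include it in the run or provide its outputs")
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages in dependency order on a synthetic
#' study, writing TSV/JSON artifacts and run metadata (seed,
#' configuration hash) to `out_dir`.
#'
#' @param config configuration list (see [default_pipeline_config()]) or
#'   path to a YAML file with the same structure; partial configurations
#'   are merged over the defaults
#' @param seed study seed; overrides the synthetic spec seed and derives
#'   the ensemble base seed
#' @param out_dir output directory, created if needed
#' @return Invisibly, the list of in-memory stage results.
#' @export
run_pipeline <- function(config = NULL, seed = 42, out_dir = tempfile()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_pipeline_config(), if (is.null(config))
    list() else config)
  known <- c("simulate", "preprocess", "similarity", "latent", "evaluate",
             "cluster", "attribute")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- known[known %in% cfg$stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  meta <- list(seed = seed, stages = stages,
               config_md5 = unname(tools::md5sum(cfg_path)),
               package = as.character(utils::packageVersion("commonspace")))
  state <- list()

  if ("simulate" %in% stages) {
    spec <- do.call(synthetic_spec,
                    .merge_config(list(seed = seed), cfg$synthetic))
    state$study <- simulate_study(spec)
  }

  if ("preprocess" %in% stages) {
    .require_stage(state, "study", "preprocess", "simulate")
    st <- state$study
    mouse <- preprocess_mouse(st$mouse_records, cfg$prep$knn_k,
                              cfg$prep$max_missing)
    state$common <- build_common_space(mouse, st$human,
                                       st$truth$homologs,
                                       st$voxel_region)
    write_expression(state$common$mouse_region |> t(),
                     file.path(out_dir, "mouse_region_expression.tsv"))
    write_expression(state$common$human_region |> t(),
                     file.path(out_dir, "human_region_expression.tsv"))
  }

  if ("similarity" %in% stages) {
    .require_stage(state, "common", "similarity", "preprocess")
    state$gene_sim <- pearson_similarity(state$common$mouse_region,
                                         state$common$human_region)
    write_similarity(state$gene_sim,
                     file.path(out_dir, "similarity_gene_space.tsv"))
  }

  if ("latent" %in% stages) {
    .require_stage(state, "common", "latent", "preprocess")
    .require_stage(state, "study", "latent", "simulate")
    lc <- cfg$latent
    mlp_cfg <- mlp_config(n_hidden = lc$n_hidden, n_units = lc$n_units,
                          weight_decay = lc$weight_decay,
                          max_lr = lc$max_lr, optimizer = lc$optimizer,
                          n_epochs = lc$n_epochs)
    x <- t(.em_values(state$common$mouse_norm))
    y <- state$study$voxel_region
    state$ensemble <- latent_ensemble(x, y, mlp_cfg,
                                      n_members = lc$n_members,
                                      base_seed = seed + lc$base_seed,
                                      keep_models = TRUE)
    state$latent_sims <- ensemble_similarities(state$ensemble,
                                               state$common$mouse_region,
                                               state$common$human_region)
    state$latent_sim_mean <- ensemble_mean_similarity(state$latent_sims)
    write_similarity(state$latent_sim_mean,
                     file.path(out_dir, "similarity_latent_mean.tsv"))
    utils::write.table(
      data.frame(member = seq_along(state$ensemble$seeds),
                 seed = state$ensemble$seeds,
                 train_loss = vapply(state$ensemble$models,
                                     function(m) m$loss, 0),
                 train_accuracy = vapply(state$ensemble$models,
                                         function(m) m$accuracy, 0)),
      file.path(out_dir, "ensemble_training.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("evaluate" %in% stages) {
    .require_stage(state, "gene_sim", "evaluate", "similarity")
    .require_stage(state, "latent_sims", "evaluate", "latent")
    pairs <- state$study$truth$canonical_pairs
    state$benefit <- evaluate_latent_benefit(
      state$gene_sim, state$latent_sims, pairs,
      tau = cfg$similarity$tau, boot_draws = cfg$evaluate$boot_draws,
      boot_seed = seed)
    utils::write.table(state$benefit$locality$records,
                       file.path(out_dir, "locality_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(state$benefit$homology$records,
                       file.path(out_dir, "homology_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ov <- function(f) list(k = f$k, n = f$n, pB = f$estimate,
                           ci = c(f$ci_low, f$ci_high), p_null = f$p_null)
    jsonlite::write_json(
      list(locality = ov(state$benefit$locality$overall),
           homology = ov(state$benefit$homology$overall)),
      file.path(out_dir, "evaluation_overall.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
  }

  if ("cluster" %in% stages) {
    .require_stage(state, "latent_sim_mean", "cluster", "latent")
    sim <- state$latent_sim_mean
    for (side in c("mouse", "human")) {
      rows <- if (side == "mouse") sim else t(sim)
      scree <- scree_wss(rows)
      k <- elbow_select(scree, override = cfg$cluster$k)
      sol <- cut_tree(hierarchical_cluster(rows), k)
      utils::write.table(
        data.frame(region = names(sol$labels), cluster = sol$labels),
        file.path(out_dir, paste0("clusters_", side, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(scree,
                         file.path(out_dir, paste0("scree_", side, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      state[[paste0("clusters_", side)]] <- sol
    }
  }

  if ("attribute" %in% stages) {
    .require_stage(state, "ensemble", "attribute", "latent")
    ac <- cfg$attribute
    region <- rownames(state$common$mouse_region)[1]
    x <- t(.em_values(state$common$mouse_norm))
    vox <- x[state$study$voxel_region == region, , drop = FALSE]
    vox <- vox[seq_len(min(nrow(vox), ac$max_voxels)), , drop = FALSE]
    models <- state$ensemble$models[seq_len(min(ac$n_runs,
                                                length(state$ensemble$models)))]
    state$attribution <- region_attribution(models, vox, region,
                                            steps = ac$steps)
    write_attribution(state$attribution,
                      file.path(out_dir, paste0("attribution_", region,
                                                ".tsv")))
  }

  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(state)
}
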