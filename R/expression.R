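#' Expression matrices and preprocessing
#'
#' The pipeline's universal carrier is a genes-by-observations matrix of
#' log2 expression, where observations are mouse voxels or human microarray
#' samples, each annotated with an atlas region. Raw in-situ hybridization
#' "energy" grids arrive as per-experiment voxel vectors; preprocessing is
#' log2 transform, replicate averaging, missingness filtering, K-nearest-
#' neighbour imputation, homolog intersection, two-step normalization and
#' regional aggregation, in that order.
#'
#' @name expression
NULL

#' Construct a genes-by-observations expression matrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   observations in columns (colnames = observation ids). `NA` encodes
#'   missing values prior to imputation.
#' @param obs data.frame of per-observation annotations with at least an
#'   `id` column matching `colnames(values)`; typically also `region` and
#'   `source` (plane or donor). Defaults to the bare ids.
#' @return An object of class `"expr_matrix"`.
#' @export
expr_matrix <- function(values, obs = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(rownames(values))) stop("values must have gene rownames")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("obs", seq_len(ncol(values)))
  if (is.null(obs)) obs <- data.frame(id = colnames(values))
  stopifnot(is.data.frame(obs), "id" %in% names(obs))
  if (!identical(as.character(obs$id), colnames(values)))
    stop("observation annotations must cover all observations in order")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  structure(list(values = values, obs = obs), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " observations (", sum(is.na(x$values)), " missing)\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# accept either an expr_matrix or a bare genes x observations matrix
.em_values <- function(x) if (inherits(x, "expr_matrix")) x$values else x
.em_rewrap <- function(x, values, obs = NULL) {
  if (inherits(x, "expr_matrix")) {
    if (is.null(obs)) obs <- x$obs[match(colnames(values), x$obs$id), ,
                                   drop = FALSE]
    rownames(obs) <- NULL
    expr_matrix(values, obs)
  } else values
}

#' A set of per-gene expression experiments
#'
#' One row per in-situ hybridization experiment, one column per in-mask
#' voxel. A gene may be measured by several experiments (replicates), in
#' one of two acquisition planes; the sagittal plane covers only a
#' unilateral extent, so its out-of-extent voxels are missing.
#'
#' @param values experiments-by-voxels numeric matrix; negative values are
#'   treated as the missing-data sentinel of raw energy grids
#' @param info data.frame with columns `experiment_id`, `gene`, `plane`
#'   (`"coronal"` or `"sagittal"`), one row per row of `values`
#' @return An object of class `"experiment_set"`.
#' @export
experiment_set <- function(values, info) {
  stopifnot(is.matrix(values), is.data.frame(info),
            all(c("experiment_id", "gene", "plane") %in% names(info)),
            nrow(info) == nrow(values))
  if (anyDuplicated(info$experiment_id)) stop("experiment ids must be unique")
  if (!all(info$plane %in% c("coronal", "sagittal")))
    stop("plane must be 'coronal' or 'sagittal'")
  rownames(values) <- info$experiment_id
  structure(list(values = values, info = info), class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat("Experiment set: ", nrow(x$values), " experiments (",
      sum(x$info$plane == "coronal"), " coronal, ",
      sum(x$info$plane == "sagittal"), " sagittal), ",
      length(unique(x$info$gene)), " genes, ", ncol(x$values),
      " voxels\n", sep = "")
  invisible(x)
}

#' Subset an experiment set by plane or gene
#' @param x an `experiment_set`
#' @param plane,genes optional filters
#' @return An `experiment_set`.
#' @export
subset_experiments <- function(x, plane = NULL, genes = NULL) {
  keep <- rep(TRUE, nrow(x$info))
  if (!is.null(plane)) keep <- keep & x$info$plane %in% plane
  if (!is.null(genes)) keep <- keep & x$info$gene %in% genes
  experiment_set(x$values[keep, , drop = FALSE],
                 x$info[keep, , drop = FALSE])
}

#' Log2-transform raw expression energies
#'
#' Positive values become `log2(value)`. Non-positive values -- including
#' the negative sentinel used by raw energy grids for unsampled voxels --
#' become missing, unless a pseudocount is supplied, in which case
#' `log2(value + pseudocount)` is used for values `>= 0` and only the
#' negative sentinel becomes missing.
#'
#' @param x an `expr_matrix`, `experiment_set`, or bare numeric matrix
#' @param pseudocount optional non-negative offset; default none
#' @return Same class as `x`, log2 scale.
#' @export
log2_transform <- function(x, pseudocount = NULL) {
  v <- if (inherits(x, "experiment_set")) x$values else .em_values(x)
  out <- v
  if (is.null(pseudocount)) {
    out[!is.na(v) & v <= 0] <- NA_real_
    pos <- !is.na(out)
    out[pos] <- log2(out[pos])
  } else {
    stopifnot(pseudocount >= 0)
    out[!is.na(v) & v < 0] <- NA_real_
    pos <- !is.na(out)
    out[pos] <- log2(out[pos] + pseudocount)
  }
  if (inherits(x, "experiment_set")) experiment_set(out, x$info)
  else .em_rewrap(x, out)
}

#' Average replicate experiments per gene
#'
#' Genes measured by more than one experiment get the voxel-wise mean over
#' experiments, ignoring missing values; a voxel missing in all replicates
#' stays missing. Gene order follows first appearance.
#'
#' @param records an `experiment_set` (typically log2-transformed)
#' @return An `expr_matrix` with one row per gene.
#' @export
average_replicate_experiments <- function(records) {
  stopifnot(inherits(records, "experiment_set"))
  if (nrow(records$values) == 0L) stop("empty experiment set")
  genes <- unique(records$info$gene)
  g <- factor(records$info$gene, levels = genes)
  obs <- !is.na(records$values)
  v0 <- records$values; v0[!obs] <- 0
  sums <- rowsum(v0, g)
  counts <- rowsum(obs + 0, g)
  out <- sums / counts        # 0/0 -> NaN where all replicates missing
  out[counts == 0] <- NA_real_
  if (is.null(colnames(out)))
    colnames(out) <- paste0("v", seq_len(ncol(out)))
  expr_matrix(out[genes, , drop = FALSE])
}

#' Drop genes with too many missing voxels
#'
#' A gene is removed when its fraction of missing observations is strictly
#' greater than `max_frac` ("more than" the threshold).
#'
#' @param x an `expr_matrix` or bare matrix
#' @param max_frac maximum tolerated missing fraction, default 0.2
#' @return Same class as `x`, with offending genes removed.
#' @export
filter_genes_by_missingness <- function(x, max_frac = 0.2) {
  stopifnot(max_frac >= 0, max_frac <= 1)
  v <- .em_values(x)
  frac <- rowMeans(is.na(v))
  .em_rewrap(x, v[frac <= max_frac, , drop = FALSE])
}

# pairwise observation distances over co-observed genes:
# d(i,j) = sqrt(mean over shared genes of squared difference)
.co_observed_dist <- function(v) {
  m <- !is.na(v)
  v0 <- v; v0[!m] <- 0
  mm <- m + 0
  sq <- crossprod(v0 * v0, mm)     # sum_g m_i m_j x_i^2  (i rows)
  cp <- crossprod(v0)              # sum_g m_i m_j x_i x_j
  shared <- crossprod(mm)
  d2 <- sq + t(sq) - 2 * cp
  d2[d2 < 0] <- 0                  # numerical noise
  d <- sqrt(d2 / shared)           # NaN where no shared genes
  diag(d) <- Inf
  d
}

#' Impute missing values by K nearest observations
#'
#' Distances between observations are root-mean-square differences over the
#' genes observed in both. A missing (gene, observation) cell is imputed as
#' the mean of that gene's value in the `k` nearest observations where it
#' is observed.
#'
#' @param x an `expr_matrix` or bare matrix with `NA`s
#' @param k number of neighbours, default 5
#' @return Same class as `x` with no missing values; observed entries are
#'   untouched.
#' @export
knn_impute <- function(x, k = 5) {
  stopifnot(k >= 1)
  v <- .em_values(x)
  if (!anyNA(v)) return(x)
  if (any(colSums(!is.na(v)) == 0))
    stop("observation(s) with no observed genes: ",
         paste(colnames(v)[colSums(!is.na(v)) == 0], collapse = ", "))
  all_missing <- rowSums(!is.na(v)) == 0
  if (any(all_missing))
    stop("gene(s) with no observed values: ",
         paste(rownames(v)[all_missing], collapse = ", "))
  d <- .co_observed_dist(v)
  out <- v
  for (g in which(rowSums(is.na(v)) > 0)) {
    miss <- which(is.na(v[g, ]))
    donors <- which(!is.na(v[g, ]))
    if (length(donors) < k)
      stop("gene ", rownames(v)[g], ": only ", length(donors),
           " observations carry a value, fewer than k = ", k)
    for (o in miss) {
      dd <- d[o, donors]
      nn <- donors[order(dd)[seq_len(k)]]
      out[g, o] <- mean(v[g, nn])
    }
  }
  .em_rewrap(x, out)
}

#' Resolve a homolog table to one-to-one pairs
#'
#' Homology groups in which either species contributes more than one
#' symbol are dropped, leaving an unambiguous mouse-human pairing.
#'
#' @param table data.frame with columns `group_id`, `mouse_symbol`,
#'   `human_symbol`
#' @return The table restricted to one-to-one groups.
#' @export
resolve_homologs <- function(table) {
  stopifnot(all(c("group_id", "mouse_symbol", "human_symbol") %in%
                  names(table)))
  tab <- unique(table[c("group_id", "mouse_symbol", "human_symbol")])
  n_mouse <- tapply(tab$mouse_symbol, tab$group_id,
                    function(s) length(unique(s)))
  n_human <- tapply(tab$human_symbol, tab$group_id,
                    function(s) length(unique(s)))
  keep_groups <- names(n_mouse)[n_mouse == 1 & n_human == 1]
  out <- tab[tab$group_id %in% keep_groups, , drop = FALSE]
  out <- out[!duplicated(out$mouse_symbol) & !duplicated(out$human_symbol), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align two species' matrices on homologous genes
#'
#' Rows are restricted to homolog pairs present in both matrices and
#' reordered so row `i` of the mouse output is the homolog of row `i` of
#' the human output.
#'
#' @param mouse,human `expr_matrix` objects (or bare matrices)
#' @param table homolog table, resolved to one-to-one via
#'   [resolve_homologs()]
#' @return List with elements `mouse` and `human`.
#' @export
intersect_homologous_genes <- function(mouse, human, table) {
  tab <- resolve_homologs(table)
  mv <- .em_values(mouse); hv <- .em_values(human)
  tab <- tab[tab$mouse_symbol %in% rownames(mv) &
               tab$human_symbol %in% rownames(hv), , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("no homologous genes present in both matrices")
  list(
    mouse = .em_rewrap(mouse, mv[tab$mouse_symbol, , drop = FALSE]),
    human = .em_rewrap(human, hv[tab$human_symbol, , drop = FALSE]),
    table = tab
  )
}

#' Two-step normalization of expression signatures
#'
#' Step 1 z-scores each observation across genes (each voxel/sample
#' signature gets mean 0, sd 1). Step 2 then centres gene space by
#' subtracting each gene's mean over all observations. The step order is
#' normative: after step 2 every gene's mean is exactly 0, while step 1's
#' property holds only approximately.
#'
#' @param x an `expr_matrix` or bare matrix without missing values
#' @return Same class as `x`, normalized.
#' @export
normalize_expression <- function(x) {
  v <- .em_values(x)
  if (anyNA(v)) stop("normalize_expression requires imputed (complete) data")
  mu <- colMeans(v)
  sd <- apply(v, 2, stats::sd)
  zero <- sd == 0
  if (any(zero))
    stop("zero-variance observation signature(s): ",
         paste(colnames(v)[zero], collapse = ", "))
  z <- sweep(sweep(v, 2, mu, "-"), 2, sd, "/")
  z <- sweep(z, 1, rowMeans(z), "-")
  .em_rewrap(x, z)
}

#' Average expression over atlas regions
#'
#' @param x an `expr_matrix` whose observations carry a `region`
#'   annotation, or a bare matrix together with `regions`
#' @param regions optional character vector of per-observation region
#'   labels (required for bare matrices)
#' @param expected optional region set that must each have at least one
#'   observation
#' @return A regions-by-genes numeric matrix (rows ordered by first
#'   appearance, or by `expected` when given).
#' @export
aggregate_by_region <- function(x, regions = NULL, expected = NULL) {
  v <- .em_values(x)
  if (is.null(regions)) {
    if (!inherits(x, "expr_matrix") || is.null(x$obs$region))
      stop("observations carry no region annotation")
    regions <- as.character(x$obs$region)
  }
  stopifnot(length(regions) == ncol(v))
  levels <- if (is.null(expected)) unique(regions) else as.character(expected)
  empty <- setdiff(levels, regions)
  if (length(empty))
    stop("region(s) with zero observations: ", paste(empty, collapse = ", "))
  f <- factor(regions, levels = levels)
  out <- rowsum(t(v), f)
  out <- out / as.vector(table(f)[rownames(out)])
  out[levels, , drop = FALSE]
}

#' Read / write expression matrices as TSV
#'
#' Values are stored genes-by-observations with gene symbols in the first
#' column; annotations (if any) go to a sibling `<path>.obs.tsv`.
#'
#' @param x an `expr_matrix` or bare matrix
#' @param path output path
#' @return `read_expression` returns an `expr_matrix`; `write_expression`
#'   returns `path` invisibly.
#' @export
write_expression <- function(x, path) {
  v <- .em_values(x)
  df <- data.frame(gene = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (inherits(x, "expr_matrix") && ncol(x$obs) > 1)
    utils::write.table(x$obs, paste0(path, ".obs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  obs_path <- paste0(path, ".obs.tsv")
  obs <- if (file.exists(obs_path)) utils::read.delim(obs_path) else NULL
  expr_matrix(v, obs)
}

#' Read a HomoloGene-style homolog table from TSV
#'
#' Expects columns `group_id`, `taxon_id`, `symbol` (long format; mouse
#' taxon 10090, human taxon 9606) or the already-wide `group_id`,
#' `mouse_symbol`, `human_symbol`.
#'
#' @param path TSV path
#' @return Wide homolog table (`group_id`, `mouse_symbol`, `human_symbol`).
#' @export
read_homolog_table <- function(path) {
  df <- utils::read.delim(path)
  if (all(c("mouse_symbol", "human_symbol") %in% names(df)))
    return(df[c("group_id", "mouse_symbol", "human_symbol")])
  stopifnot(all(c("group_id", "taxon_id", "symbol") %in% names(df)))
  mouse <- df[df$taxon_id == 10090, c("group_id", "symbol")]
  human <- df[df$taxon_id == 9606, c("group_id", "symbol")]
  names(mouse)[2] <- "mouse_symbol"; names(human)[2] <- "human_symbol"
  merge(mouse, human, by = "group_id")
}
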