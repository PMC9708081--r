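#' Cross-species similarity matrices and rank-based criteria
#'
#' Regional correspondence between species is quantified by Pearson
#' correlation between region signatures in a common feature space
#' (homologous genes or latent units). A seed region's similarity profile
#' is its vector of correlations to all target regions in the other
#' species; two rank-based criteria summarise it. Locality: the rank at
#' which the scaled, rank-ordered profile first reaches a threshold (0.75)
#' -- fast decay means the signal concentrates on few targets. Homology:
#' the rank of the seed's canonical counterpart -- rank 1 means the known
#' homolog is the best match.
#'
#' @name similarity
NULL

#' Pearson similarity between all region pairs of two species
#'
#' @param A,B numeric matrices with regions in rows and a shared, equally
#'   ordered feature dimension in columns
#' @return Matrix of Pearson correlations, rows = rows of `A`, columns =
#'   rows of `B`.
#' @export
pearson_similarity <- function(A, B) {
  stopifnot(is.matrix(A), is.matrix(B))
  if (ncol(A) != ncol(B))
    stop("feature dimensions differ: ", ncol(A), " vs ", ncol(B))
  .check_row_var(A, "A"); .check_row_var(B, "B")
  stats::cor(t(A), t(B))
}

.check_row_var <- function(m, label) {
  v <- apply(m, 1, stats::sd)
  if (any(v == 0))
    stop("zero-variance region signature(s) in ", label, ": ",
         paste(rownames(m)[v == 0], collapse = ", "))
}

#' Extract a seed region's similarity profile
#'
#' @param sim similarity matrix from [pearson_similarity()]
#' @param seed row (region) name or index
#' @return Named numeric vector of correlations to all targets.
#' @export
similarity_profile <- function(sim, seed) {
  if (is.character(seed) && !seed %in% rownames(sim))
    stop("unknown seed region: ", seed)
  sim[seed, ]
}

#' Scale a similarity profile to the unit interval and rank-order it
#'
#' Values are mapped affinely so the maximum is 1 and the minimum 0, then
#' sorted in descending order. Ties keep their input (target) order.
#'
#' @param profile named numeric vector of correlations
#' @param seed optional seed region name carried as metadata
#' @return An object of class `"ranked_profile"` with elements `targets`
#'   (in rank order), `scaled`, `values` (original correlations, same
#'   order) and `seed`.
#' @export
scale_unit_interval <- function(profile, seed = NULL) {
  v <- profile
  if (length(v) < 2 || diff(range(v)) == 0)
    stop("profile is constant; cannot scale to the unit interval")
  ord <- order(-v)  # radix order: stable for ties
  scaled <- (v[ord] - min(v)) / (max(v) - min(v))
  structure(list(seed = seed,
                 targets = names(v)[ord],
                 scaled = unname(scaled),
                 values = unname(v[ord])),
            class = "ranked_profile")
}

#' @export
print.ranked_profile <- function(x, ...) {
  cat("Ranked similarity profile", if (!is.null(x$seed)) paste("of", x$seed),
      "over", length(x$targets), "targets; top:",
      paste(utils::head(x$targets, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Locality criterion: rank at which a scaled profile reaches a threshold
#'
#' The smallest 1-based rank whose scaled similarity is less than or equal
#' to `tau`. Always defined since the scaled minimum is 0.
#'
#' @param profile a `ranked_profile`
#' @param tau threshold in (0, 1), default 0.75
#' @return Integer rank.
#' @export
rank_at_threshold <- function(profile, tau = 0.75) {
  stopifnot(inherits(profile, "ranked_profile"))
  which(profile$scaled <= tau)[1L]
}

#' Homology criterion: rank of a given target in a profile
#'
#' @param profile a `ranked_profile`
#' @param target target region name
#' @return 1-based position of `target` in the descending-sorted profile
#'   (stable tie order).
#' @export
rank_of_target <- function(profile, target) {
  stopifnot(inherits(profile, "ranked_profile"))
  r <- match(target, profile$targets)
  if (is.na(r)) stop("unknown target region: ", target)
  r
}

#' Entrywise mean of an ensemble of similarity matrices
#'
#' @param matrices list of similarity matrices with identical dimnames
#' @return Matrix of the same shape.
#' @export
ensemble_mean_similarity <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  ref <- matrices[[1]]
  for (m in matrices[-1])
    if (!identical(dim(m), dim(ref)) || !identical(dimnames(m), dimnames(ref)))
      stop("similarity matrices must share region sets")
  Reduce(`+`, matrices) / length(matrices)
}

#' Observation-level similarity to target regions
#'
#' Correlates every observation (voxel or sample) signature with every
#' target region signature and records the most similar target per
#' observation (ties broken by first target in column order).
#' Zero-variance observations are dropped with a warning.
#'
#' @param obs_matrix observations-by-features matrix
#' @param region_matrix regions-by-features matrix (same feature order)
#' @return An object of class `"voxel_similarity"`: list with `r`
#'   (observations x targets correlation matrix) and `argmax` (named
#'   character vector of best targets).
#' @export
observation_similarity <- function(obs_matrix, region_matrix) {
  stopifnot(is.matrix(obs_matrix), is.matrix(region_matrix),
            ncol(obs_matrix) == ncol(region_matrix))
  .check_row_var(region_matrix, "region_matrix")
  sd0 <- apply(obs_matrix, 1, stats::sd) == 0
  if (any(sd0)) {
    warning("excluding ", sum(sd0), " zero-variance observation(s)")
    obs_matrix <- obs_matrix[!sd0, , drop = FALSE]
  }
  r <- stats::cor(t(obs_matrix), t(region_matrix))
  am <- colnames(r)[apply(r, 1, which.max)]
  names(am) <- rownames(r)
  structure(list(r = r, argmax = am), class = "voxel_similarity")
}

#' @export
print.voxel_similarity <- function(x, ...) {
  cat("Observation similarity map: ", nrow(x$r), " observations x ",
      ncol(x$r), " targets\n", sep = "")
  invisible(x)
}

#' Ensemble proportions of maximal similarity
#'
#' For each observation, the fraction of ensemble members in which each
#' target attains the row maximum (ties counted once, first target wins).
#'
#' @param maps list of `voxel_similarity` objects over identical
#'   observation and target sets
#' @return Observations-by-targets matrix of fractions; rows sum to 1.
#' @export
argmax_proportions <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1)
  ref <- maps[[1]]$r
  out <- matrix(0, nrow(ref), ncol(ref), dimnames = dimnames(ref))
  for (m in maps) {
    if (!identical(dimnames(m$r), dimnames(ref)))
      stop("maps must share observation and target sets")
    idx <- apply(m$r, 1, which.max)
    out[cbind(seq_len(nrow(out)), idx)] <-
      out[cbind(seq_len(nrow(out)), idx)] + 1
  }
  out / length(maps)
}

#' Mean and dispersion of a set of correlations
#'
#' @param values numeric vector (length >= 2)
#' @return List with `mean`, `sd`, `var` (n-1 denominator).
#' @export
summarize_dispersion <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  list(mean = mean(values), sd = stats::sd(values), var = stats::var(values))
}

#' Select the targets with highest mean correlation
#'
#' Aggregates over observations (rows) and, when a list of maps is given,
#' over ensemble members, then returns the `n` top targets.
#'
#' @param x a `voxel_similarity`, a list of them, or a bare correlation
#'   matrix
#' @param n number of targets to return
#' @return Character vector of target names, best first.
#' @export
select_top_targets <- function(x, n) {
  r <- if (inherits(x, "voxel_similarity")) x$r
  else if (is.list(x)) Reduce(`+`, lapply(x, function(m) m$r)) / length(x)
  else x
  stopifnot(n <= ncol(r))
  means <- colMeans(r)
  names(sort(means, decreasing = TRUE))[seq_len(n)]
}

#' Fraction of observations with correlation at or above a threshold
#'
#' A reporting utility over observation-level similarity maps: the share
#' of observations whose correlation to `target` (or whose row maximum,
#' when `target` is `NULL`) reaches `threshold`.
#'
#' @param map a `voxel_similarity`
#' @param threshold correlation threshold
#' @param target optional target region name
#' @return Fraction in \[0, 1\].
#' @export
threshold_fraction <- function(map, threshold, target = NULL) {
  v <- if (is.null(target)) apply(map$r, 1, max) else map$r[, target]
  mean(v >= threshold)
}

#' Read / write similarity matrices as TSV
#' @param sim similarity matrix
#' @param path output path
#' @return `read_similarity` returns a matrix; `write_similarity` returns
#'   `path` invisibly.
#' @export
write_similarity <- function(sim, path) {
  df <- data.frame(region = rownames(sim), sim, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
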