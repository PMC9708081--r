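#' Brain atlas ontologies and label aggregation
#'
#' A neuroanatomical ontology is a rooted tree of labelled structures
#' (e.g. the Allen Institute structure graphs). Atlas volumes carry leaf
#' labels; analyses usually work at a coarser granularity, obtained by
#' aggregating leaves up the hierarchy to a chosen set of target structures
#' and pruning excluded subtrees (white matter, ventricles) entirely.
#'
#' @name ontology
NULL

#' Construct an ontology tree from a node table
#'
#' @param nodes data.frame with columns `id` (integer), `name`, `acronym`,
#'   `color` (hex triplet, optional), `parent_id` (integer, `NA` for the
#'   root).
#' @return An object of class `"ontology"`: the validated node table plus a
#'   children index.
#' @export
ontology <- function(nodes) {
  stopifnot(is.data.frame(nodes), all(c("id", "parent_id") %in% names(nodes)))
  nodes$id <- as.integer(nodes$id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (!"name" %in% names(nodes)) nodes$name <- as.character(nodes$id)
  if (!"acronym" %in% names(nodes)) nodes$acronym <- nodes$name
  if (!"color" %in% names(nodes)) nodes$color <- NA_character_
  if (anyDuplicated(nodes$id))
    stop("duplicate ontology ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  root <- nodes$id[is.na(nodes$parent_id)]
  if (length(root) != 1L)
    stop("ontology must have exactly one root, found ", length(root),
         if (length(root) > 0) paste0(" (ids ", paste(root, collapse = ", "), ")"))
  self_parent <- nodes$id[!is.na(nodes$parent_id) & nodes$parent_id == nodes$id]
  if (length(self_parent))
    stop("node(s) listing themselves as parent: ",
         paste(self_parent, collapse = ", "))
  bad_parent <- setdiff(nodes$parent_id[!is.na(nodes$parent_id)], nodes$id)
  if (length(bad_parent))
    stop("parent ids not present in ontology: ",
         paste(bad_parent, collapse = ", "))
  tree <- structure(
    list(nodes = nodes[order(nodes$id), , drop = FALSE], root = root),
    class = "ontology"
  )
  # cycle check: every node must reach the root
  for (id in tree$nodes$id) {
    path <- ontology_ancestors(tree, id)
    if (path[length(path)] != root)
      stop("cycle detected in ontology involving id ", id)
  }
  tree
}

#' @export
print.ontology <- function(x, ...) {
  cat("Ontology tree:", nrow(x$nodes), "nodes,",
      length(ontology_leaves(x)), "leaves, root id", x$root, "\n")
  invisible(x)
}

#' Walk from a node to the root
#'
#' @param tree an `ontology`
#' @param id node id
#' @return Integer vector of ids from `id` (inclusive) up to the root.
#' @export
ontology_ancestors <- function(tree, id) {
  nodes <- tree$nodes
  parent <- stats::setNames(nodes$parent_id, nodes$id)
  if (!as.character(id) %in% names(parent)) stop("unknown ontology id: ", id)
  path <- integer(0)
  cur <- as.integer(id)
  n <- nrow(nodes)
  while (!is.na(cur)) {
    if (length(path) > n) stop("cycle detected in ontology involving id ", id)
    path <- c(path, cur)
    cur <- parent[[as.character(cur)]]
  }
  path
}

#' Leaf ids of an ontology
#' @param tree an `ontology`
#' @return Integer vector of ids with no children.
#' @export
ontology_leaves <- function(tree) {
  nodes <- tree$nodes
  setdiff(nodes$id, nodes$parent_id[!is.na(nodes$parent_id)])
}

#' Read an ontology from structure-graph JSON
#'
#' Accepts the Allen structure-graph dialect: a nested object with fields
#' `id`, `name`, `acronym`, `color_hex_triplet` and a `children` array,
#' optionally wrapped in a top-level `msg` array.
#'
#' @param path path to a JSON file
#' @return An `ontology`.
#' @export
load_ontology <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(raw$msg)) raw <- raw$msg
  # either a single root object or a list holding one
  if (!is.null(raw$id)) roots <- list(raw) else roots <- raw
  if (length(roots) != 1L)
    stop("ontology must have exactly one root, found ", length(roots))
  rows <- list()
  walk <- function(node, parent_id) {
    if (is.null(node$id)) stop("ontology node without an id field")
    rows[[length(rows) + 1L]] <<- data.frame(
      id = as.integer(node$id),
      name = if (is.null(node$name)) NA_character_ else node$name,
      acronym = if (is.null(node$acronym)) NA_character_ else node$acronym,
      color = if (is.null(node$color_hex_triplet)) NA_character_
              else node$color_hex_triplet,
      parent_id = parent_id,
      stringsAsFactors = FALSE
    )
    for (ch in node$children) walk(ch, as.integer(node$id))
  }
  walk(roots[[1L]], NA_integer_)
  ontology(do.call(rbind, rows))
}

#' Write an ontology as structure-graph JSON
#'
#' Inverse of [load_ontology()]: children are emitted in increasing id
#' order, giving a canonical serialization.
#'
#' @param tree an `ontology`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_ontology <- function(tree, path) {
  nodes <- tree$nodes
  build <- function(id) {
    row <- nodes[nodes$id == id, ]
    kids <- sort(nodes$id[!is.na(nodes$parent_id) & nodes$parent_id == id])
    list(
      id = row$id,
      name = row$name,
      acronym = row$acronym,
      color_hex_triplet = row$color,
      children = lapply(kids, build)
    )
  }
  jsonlite::write_json(build(tree$root), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Sentinel marking pruned leaves in a label mapping
#' @export
EXCLUDED <- 0L

#' Aggregate atlas leaves to a target granularity
#'
#' Each leaf is mapped to its nearest ancestor-or-self among `targets`,
#' walking leaf to root. Leaves whose walk first hits a node in `excluded`
#' are pruned ([EXCLUDED], coded 0). A leaf hitting neither is an error:
#' the target set must cover the tree.
#'
#' @param tree an `ontology`
#' @param targets integer ids of aggregation targets
#' @param excluded integer ids of subtrees to prune (e.g. white matter)
#' @return Named integer vector (`"label_mapping"`): leaf id -> aggregate
#'   id, with 0 for excluded leaves.
#' @export
aggregate_labels <- function(tree, targets, excluded = integer(0)) {
  targets <- as.integer(targets); excluded <- as.integer(excluded)
  if (length(intersect(targets, excluded)))
    stop("targets and excluded sets must be disjoint")
  unknown <- setdiff(c(targets, excluded), tree$nodes$id)
  if (length(unknown))
    stop("ids not in ontology: ", paste(unknown, collapse = ", "))
  leaves <- ontology_leaves(tree)
  map <- integer(length(leaves))
  orphans <- integer(0)
  for (i in seq_along(leaves)) {
    path <- ontology_ancestors(tree, leaves[i])
    hit <- NA_integer_
    for (p in path) {
      if (p %in% excluded) { hit <- EXCLUDED; break }
      if (p %in% targets) { hit <- p; break }
    }
    if (is.na(hit)) orphans <- c(orphans, leaves[i]) else map[i] <- hit
  }
  if (length(orphans))
    stop("leaves with no target ancestor and not excluded: ",
         paste(orphans, collapse = ", "))
  structure(stats::setNames(map, leaves), class = "label_mapping")
}

#' Construct a labelled atlas volume
#'
#' @param labels 3-D integer array of ontology ids (0 = background)
#' @param mask logical array of the same shape; defaults to `labels != 0`
#' @param voxel_size voxel edge length in micrometres
#' @param orientation orientation tag (stored, not interpreted)
#' @return An object of class `"atlas_volume"`.
#' @export
atlas_volume <- function(labels, mask = NULL, voxel_size = 200,
                         orientation = "RAS") {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  if (is.null(mask)) mask <- labels != 0L
  stopifnot(is.logical(mask), identical(dim(mask), dim(labels)))
  if (any(labels[!mask] != 0L)) labels[!mask] <- 0L
  structure(list(labels = labels, mask = mask, voxel_size = voxel_size,
                 orientation = orientation),
            class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  cat("Atlas volume ", paste(dim(x$labels), collapse = " x "),
      " (", x$voxel_size, " um, ", x$orientation, "), ",
      sum(x$mask), " in-mask voxels, ",
      length(setdiff(unique(x$labels[x$mask]), 0L)), " labels\n", sep = "")
  invisible(x)
}

#' Relabel an atlas volume under a label mapping
#'
#' Voxels mapping to [EXCLUDED] are set to background and removed from the
#' mask; all other in-mask labels are replaced by their aggregate id.
#'
#' @param volume an `atlas_volume`
#' @param mapping a `label_mapping` from [aggregate_labels()] (or any named
#'   integer vector leaf id -> aggregate id)
#' @return A relabelled `atlas_volume`.
#' @export
relabel_volume <- function(volume, mapping) {
  labs <- volume$labels
  present <- setdiff(unique(labs[volume$mask]), 0L)
  unmapped <- setdiff(present, as.integer(names(mapping)))
  if (length(unmapped)) {
    counts <- vapply(unmapped, function(l) sum(labs == l & volume$mask), 0L)
    stop("labels absent from mapping: ",
         paste(sprintf("%d (%d voxels)", unmapped, counts), collapse = ", "))
  }
  idx <- which(volume$mask & labs != 0L)
  new <- unname(mapping[as.character(labs[idx])])
  labs[idx] <- new
  mask <- volume$mask
  mask[idx[new == EXCLUDED]] <- FALSE
  atlas_volume(labs, mask, volume$voxel_size, volume$orientation)
}

#' Read / write label volumes as NIfTI-1
#'
#' @param volume an `atlas_volume`
#' @param path file path (`.nii` or `.nii.gz`)
#' @return `read_volume` returns an `atlas_volume`; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$labels,
                         pixdim = rep(volume$voxel_size / 1000, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param voxel_size voxel size in micrometres for the returned volume
#' @export
read_volume <- function(path, voxel_size = 200) {
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(round(img)), dim = dim(img))
  atlas_volume(arr, voxel_size = voxel_size)
}
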