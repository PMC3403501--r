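#' Weighted co-splicing network
#'
#' A symmetric nonnegative adjacency matrix over exons, with zero diagonal,
#' derived from one dataset.
#'
#' @param weights symmetric numeric matrix with values in \eqn{[0, 1]}, zero
#'   diagonal, and node ids as dimnames.
#' @param dataset_id identifier of the originating dataset.
#' @return An object of class \code{weighted_network}.
#' @export
weighted_network <- function(weights, dataset_id) {
  weights <- as.matrix(weights)
  if (is.null(rownames(weights))) stop("weights must carry node ids as dimnames")
  if (nrow(weights) != ncol(weights) ||
      !isTRUE(all.equal(weights, t(weights), check.attributes = FALSE)))
    stop("weights must be a symmetric matrix")
  if (any(diag(weights) != 0)) stop("diagonal must be zero")
  if (anyNA(weights) || min(weights) < 0 || max(weights) > 1)
    stop("weights must lie in [0, 1]")
  structure(list(node_ids = rownames(weights), weights = weights,
                 dataset_id = as.character(dataset_id)),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network '%s': %d nodes, mean weight %.4f\n",
              x$dataset_id, length(x$node_ids),
              mean(x$weights[upper.tri(x$weights)])))
  invisible(x)
}

#' Pearson co-splicing network from inclusion profiles
#'
#' Edge weights are Pearson correlations between the inclusion-rate profiles
#' of two exons over pairwise-complete samples. Negative correlations are
#' clamped to zero by default, targeting positively co-spliced exon pairs
#' (the heaviness objective presumes nonnegative weights);
#' \code{edge_transform = "abs"} takes absolute values instead. Pairs with
#' fewer than \code{min_overlap} shared defined samples, and pairs involving
#' a zero-variance profile, get weight zero.
#'
#' @param profiles an [inclusion_matrix()] (or plain exon x sample matrix).
#' @param min_overlap minimum number of pairwise-complete samples.
#' @param edge_transform \code{"clamp"} (default) or \code{"abs"}.
#' @param dataset_id identifier recorded in the network.
#' @return A [weighted_network()].
#' @export
correlation_network <- function(profiles, min_overlap = 4L,
                                edge_transform = c("clamp", "abs"),
                                dataset_id = "dataset") {
  edge_transform <- match.arg(edge_transform)
  vals <- if (inherits(profiles, "inclusion_matrix")) profiles$values
          else as.matrix(profiles)
  if (nrow(vals) < 2) stop("need at least 2 exons to build a network")
  # suppressWarnings: cor() warns on zero-variance profiles, which map to 0
  cm <- suppressWarnings(
    stats::cor(t(vals), use = "pairwise.complete.obs", method = "pearson"))
  cm[is.na(cm)] <- 0
  defined <- !is.na(vals)
  overlap <- tcrossprod(defined * 1)
  cm[overlap < min_overlap] <- 0
  cm <- if (edge_transform == "clamp") pmax(cm, 0) else abs(cm)
  diag(cm) <- 0
  weighted_network(cm, dataset_id)
}

#' Union / intersection of network node sets
#'
#' Helpers to form the shared exon universe before stacking networks into a
#' tensor.
#'
#' @param networks list of [weighted_network()].
#' @return Character vector of node ids (union keeps first-seen order).
#' @rdname node_universe
#' @export
node_union <- function(networks) {
  unique(unlist(lapply(networks, function(w) w$node_ids)))
}

#' @rdname node_universe
#' @export
node_intersection <- function(networks) {
  Reduce(intersect, lapply(networks, function(w) w$node_ids))
}

#' Stack networks into a shared-universe tensor
#'
#' Each network is re-indexed to the given node universe; node pairs absent
#' from a network get weight zero. Slices keep the symmetry and zero
#' diagonal of their networks.
#'
#' @param networks non-empty list of [weighted_network()] with distinct
#'   \code{dataset_id}s.
#' @param universe node ids (no duplicates); defaults to the union of the
#'   networks' node sets.
#' @return A [network_tensor()].
#' @export
assemble_tensor <- function(networks, universe = node_union(networks)) {
  if (length(networks) == 0) stop("no networks to assemble")
  if (length(universe) == 0) stop("empty node universe")
  if (anyDuplicated(universe)) stop("duplicate ids in universe")
  ids <- vapply(networks, function(w) w$dataset_id, "")
  if (anyDuplicated(ids)) stop("duplicate dataset_id among networks")
  n <- length(universe)
  ent <- array(0, dim = c(n, n, length(networks)))
  for (k in seq_along(networks)) {
    w <- networks[[k]]
    idx <- match(w$node_ids, universe)
    present <- !is.na(idx)
    ent[idx[present], idx[present], k] <-
      w$weights[present, present, drop = FALSE]
  }
  network_tensor(ent, node_ids = universe, network_ids = ids)
}

#' Read / write a weighted network
#'
#' Two plain-text forms are supported and auto-detected: a full symmetric
#' matrix (TSV with row and column headers) or a 3-column edge list
#' \code{node_a<TAB>node_b<TAB>weight} (absent edges are zero).
#'
#' @param path file path.
#' @param dataset_id identifier for the network; defaults to the file name.
#' @rdname network_io
#' @export
read_network <- function(path, dataset_id = NULL) {
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (identical(tolower(header[1:2]), c("node_a", "node_b"))) {
    el <- utils::read.delim(path, stringsAsFactors = FALSE)
    nodes <- sort(unique(c(el$node_a, el$node_b)))
    w <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (r in seq_len(nrow(el))) {
      w[el$node_a[r], el$node_b[r]] <- el$weight[r]
      w[el$node_b[r], el$node_a[r]] <- el$weight[r]
    }
    diag(w) <- 0
    return(weighted_network(w, dataset_id))
  }
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  weighted_network(m, dataset_id)
}

#' @param network a [weighted_network()].
#' @param format \code{"matrix"} or \code{"edgelist"}.
#' @rdname network_io
#' @export
write_network <- function(network, path, format = c("matrix", "edgelist")) {
  format <- match.arg(format)
  if (format == "matrix") {
    df <- data.frame(network$weights, check.names = FALSE)
    utils::write.table(cbind(node = network$node_ids, df), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    iu <- which(upper.tri(network$weights) & network$weights > 0,
                arr.ind = TRUE)
    df <- data.frame(node_a = network$node_ids[iu[, 1]],
                     node_b = network$node_ids[iu[, 2]],
                     weight = network$weights[iu])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a tensor manifest
#'
#' A tensor is persisted as one network file per slice plus a two-column
#' manifest \code{network_id<TAB>path} (paths relative to the manifest).
#'
#' @param path manifest path.
#' @rdname tensor_io
#' @export
read_tensor_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("network_id", "path") %in% colnames(man)))
    stop("manifest needs columns network_id and path")
  base <- dirname(path)
  nets <- lapply(seq_len(nrow(man)), function(i)
    read_network(file.path(base, man$path[i]), man$network_id[i]))
  assemble_tensor(nets)
}

#' @param tensor a [network_tensor()].
#' @param dir output directory (created if needed).
#' @rdname tensor_io
#' @export
write_tensor_manifest <- function(tensor, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- tensor_networks(tensor)
  files <- sprintf("%s.tsv", ids)
  for (k in seq_along(ids)) {
    w <- unclass(tensor)[, , k]
    rownames(w) <- colnames(w) <- tensor_nodes(tensor)
    write_network(weighted_network(w, ids[k]), file.path(dir, files[k]))
  }
  man <- data.frame(network_id = ids, path = files)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}
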