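#' Construct a network tensor
#'
#' Stacks a collection of symmetric weighted networks sharing a node universe
#' into a third-order array \code{a[i, j, k]}: the weight of the edge between
#' exons \code{i} and \code{j} in network \code{k}. Each slice is symmetric
#' with a zero diagonal, and all entries lie in \eqn{[0, 1]}.
#'
#' @param entries numeric array of dimension \code{n x n x m}.
#' @param node_ids character vector of length \code{n}; exon identifiers.
#' @param network_ids character vector of length \code{m}; dataset identifiers.
#' @return A \code{network_tensor}: the array with dimnames set and class
#'   attached.
#' @export
network_tensor <- function(entries, node_ids = NULL, network_ids = NULL) {
  if (!is.array(entries) || length(dim(entries)) != 3L)
    stop("'entries' must be a 3-dimensional array")
  d <- dim(entries)
  if (d[1] != d[2]) stop("slices must be square (n x n x m)")
  if (is.null(node_ids)) node_ids <- dimnames(entries)[[1]]
  if (is.null(node_ids)) node_ids <- sprintf("exon%03d", seq_len(d[1]))
  if (is.null(network_ids)) network_ids <- dimnames(entries)[[3]]
  if (is.null(network_ids)) network_ids <- sprintf("net%02d", seq_len(d[3]))
  if (length(node_ids) != d[1]) stop("node_ids length does not match tensor")
  if (length(network_ids) != d[3]) stop("network_ids length does not match tensor")
  if (anyDuplicated(node_ids)) stop("duplicate node ids")
  if (anyDuplicated(network_ids)) stop("duplicate network ids")
  dimnames(entries) <- list(node_ids, node_ids, network_ids)
  validate_network_tensor(structure(entries, class = "network_tensor"))
}

validate_network_tensor <- function(x) {
  if (anyNA(x)) stop("tensor entries must not be NA")
  if (min(x) < 0 || max(x) > 1) stop("tensor entries must lie in [0, 1]")
  for (k in seq_len(dim(x)[3])) {
    s <- unclass(x)[, , k]
    if (!isTRUE(all.equal(s, t(s), check.attributes = FALSE)))
      stop("slice ", k, " is not symmetric")
    if (any(diag(s) != 0)) stop("slice ", k, " has nonzero diagonal")
  }
  x
}

#' @export
print.network_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("network_tensor: %d exons x %d networks\n", d[1], d[3]))
  cat(sprintf("  mean off-diagonal weight: %.4f\n", mean_offdiag(x)))
  invisible(x)
}

mean_offdiag <- function(tensor) {
  n <- dim(tensor)[1]
  m <- dim(tensor)[3]
  denom <- n * (n - 1) * m
  if (denom == 0) return(NA_real_)
  sum(tensor) / denom
}

#' @export
dim.network_tensor <- function(x) dim(unclass(x))

n_nodes <- function(tensor) dim(tensor)[1]
n_networks <- function(tensor) dim(tensor)[3]
tensor_nodes <- function(tensor) dimnames(tensor)[[1]]
tensor_networks <- function(tensor) dimnames(tensor)[[3]]

# n^2 x m unfolding used for fast contractions against x and y
unfold_tensor <- function(tensor) {
  d <- dim(tensor)
  matrix(unclass(tensor), nrow = d[1] * d[2], ncol = d[3])
}

#' Heaviness objective of membership vectors
#'
#' Evaluates \eqn{H_A(x, y) = \frac12 \sum_{ijk} a_{ijk} x_i x_j y_k}, the
#' summed weight of the edges selected by the exon membership vector \code{x}
#' and the network membership vector \code{y}. For binary indicator vectors
#' this is the total edge weight of the cluster across its networks.
#'
#' @param tensor a [network_tensor()].
#' @param x nonnegative numeric vector, one entry per exon.
#' @param y nonnegative numeric vector, one entry per network.
#' @return A single number, the objective value.
#' @export
objective_heaviness <- function(tensor, x, y) {
  d <- dim(tensor)
  if (length(x) != d[1]) stop("length(x) must equal the number of exons")
  if (length(y) != d[3]) stop("length(y) must equal the number of networks")
  if (any(x < 0) || any(y < 0)) stop("membership vectors must be nonnegative")
  W <- slice_mix(tensor, y)
  0.5 * sum(x * (W %*% x))
}

# W = sum_k y_k A_k as an n x n matrix
slice_mix <- function(tensor, y) {
  d <- dim(tensor)
  matrix(unfold_tensor(tensor) %*% y, nrow = d[1], ncol = d[2])
}

# w_k = (1/2) x' A_k x for every slice k
slice_weights <- function(tensor, x) {
  xx <- as.vector(outer(x, x))
  drop(0.5 * crossprod(unfold_tensor(tensor), xx))
}

#' Average edge weight of a pattern
#'
#' The heaviness of a pattern is the mean weight over all unordered exon
#' pairs and all selected networks; clusters are retained when this average
#' meets the heaviness threshold (0.4 by default in mining).
#'
#' @param tensor a [network_tensor()].
#' @param exon_ids character or integer vector selecting at least two exons.
#' @param network_ids character or integer vector selecting at least one
#'   network.
#' @return Mean weight of the \eqn{|E|(|E|-1)/2 \cdot |N|} selected edges.
#' @export
pattern_heaviness <- function(tensor, exon_ids, network_ids) {
  ei <- resolve_ids(exon_ids, tensor_nodes(tensor), "exon")
  ni <- resolve_ids(network_ids, tensor_networks(tensor), "network")
  if (length(ei) < 2) stop("a pattern needs at least 2 exons")
  if (length(ni) < 1) stop("a pattern needs at least 1 network")
  sub <- unclass(tensor)[ei, ei, ni, drop = FALSE]
  n_e <- length(ei)
  sum(sub) / 2 / (length(ni) * n_e * (n_e - 1) / 2)
}

resolve_ids <- function(ids, universe, what) {
  if (is.character(ids)) {
    idx <- match(ids, universe)
    if (anyNA(idx)) stop("unknown ", what, " id(s): ",
                         paste(ids[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(ids)
    if (any(idx < 1) || any(idx > length(universe)))
      stop(what, " index out of range")
  }
  unique(idx)
}

#' Mask a discovered cluster in the tensor
#'
#' Zeroes every intra-cluster edge in the networks where the cluster occurs,
#' so that re-optimising the heaviness objective discovers the next cluster.
#' Entries outside the cluster's exon pairs or networks are untouched;
#' masking is idempotent.
#'
#' @param tensor a [network_tensor()].
#' @param cluster a [fs_cluster()] (or any list with \code{exon_ids} and
#'   \code{network_ids}).
#' @return The masked \code{network_tensor}.
#' @export
mask_pattern <- function(tensor, cluster) {
  ei <- resolve_ids(cluster$exon_ids, tensor_nodes(tensor), "exon")
  ni <- resolve_ids(cluster$network_ids, tensor_networks(tensor), "network")
  ent <- unclass(tensor)
  sub <- ent[ei, ei, ni, drop = FALSE]
  sub[] <- 0
  ent[ei, ei, ni] <- sub
  structure(ent, class = "network_tensor")
}

#' Frequent co-splicing cluster
#'
#' A cluster is a set of exons forming a heavy subgraph simultaneously in a
#' set of networks; its recurrence is the number of networks.
#'
#' @param exon_ids character vector of member exons.
#' @param network_ids character vector of networks where the cluster is heavy.
#' @param heaviness average intra-cluster edge weight over those networks.
#' @param objective optional objective value of the relaxation solution that
#'   produced the cluster.
#' @return An object of class \code{fs_cluster}.
#' @export
fs_cluster <- function(exon_ids, network_ids, heaviness, objective = NA_real_) {
  structure(list(exon_ids = as.character(exon_ids),
                 network_ids = as.character(network_ids),
                 heaviness = heaviness,
                 recurrence = length(network_ids),
                 objective = objective),
            class = "fs_cluster")
}

#' @export
print.fs_cluster <- function(x, ...) {
  cat(sprintf("fs_cluster: %d exons x %d networks, heaviness %.3f\n",
              length(x$exon_ids), x$recurrence, x$heaviness))
  invisible(x)
}
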