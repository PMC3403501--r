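#' Random background network collection
#'
#' Draws \code{m} symmetric networks over \code{n} exons with i.i.d. edge
#' weights uniform on \code{[0, 2 * background_mean]} (so the expected edge
#' weight is \code{background_mean}), zero diagonal. This emulates a
#' collection of unstructured co-splicing networks into which clusters are
#' planted by [plant_cluster()].
#'
#' @param n number of exons (>= 2).
#' @param m number of networks (>= 1).
#' @param background_mean expected edge weight; must be <= 0.5 so that the
#'   uniform range stays inside \eqn{[0, 1]}.
#' @param seed integer seed; the same seed reproduces the same tensor.
#' @return A [network_tensor()].
#' @export
generate_background <- function(n, m, background_mean = 0.1, seed = 1L) {
  stopifnot(n >= 2, m >= 1)
  if (background_mean > 0.5)
    stop("background_mean must be <= 0.5 to keep weights in [0, 1]")
  if (background_mean < 0) stop("background_mean must be nonnegative")
  set.seed(seed)
  ent <- array(0, dim = c(n, n, m))
  iu <- upper.tri(matrix(0, n, n))
  n_edges <- sum(iu)
  for (k in seq_len(m)) {
    s <- matrix(0, n, n)
    s[iu] <- stats::runif(n_edges, 0, 2 * background_mean)
    ent[, , k] <- s + t(s)
  }
  network_tensor(ent)
}

#' Specification of a planted cluster
#'
#' @param n_exons_planted number of member exons (>= 2).
#' @param n_networks_planted number of networks the cluster recurs in (>= 1).
#' @param target_heaviness average intra-cluster edge weight to plant, in
#'   (0, 1].
#' @param noise_sd standard deviation of Gaussian noise added to the planted
#'   weights (clipped to \eqn{[0, 1]}).
#' @return A list of class \code{planted_spec}.
#' @export
planted_spec <- function(n_exons_planted, n_networks_planted,
                         target_heaviness, noise_sd = 0) {
  stopifnot(n_exons_planted >= 2, n_networks_planted >= 1,
            target_heaviness > 0, target_heaviness <= 1, noise_sd >= 0)
  structure(list(n_exons_planted = as.integer(n_exons_planted),
                 n_networks_planted = as.integer(n_networks_planted),
                 target_heaviness = target_heaviness,
                 noise_sd = noise_sd),
            class = "planted_spec")
}

#' Plant a cluster into a network collection
#'
#' Uniformly samples an exon subset and a network subset of the sizes given
#' in \code{spec} and overwrites every intra-subset edge in the selected
#' networks with \code{target_heaviness} plus Gaussian noise, clipped to
#' \eqn{[0, 1]}. Overwriting (rather than adding) makes the planted heaviness
#' exact at zero noise. Ground truth is recorded for recovery scoring.
#'
#' @param collection a [network_tensor()] or an existing
#'   \code{benchmark_collection} (to plant several clusters).
#' @param spec a [planted_spec()].
#' @param seed integer seed for the subset sampling and noise.
#' @return A \code{benchmark_collection}: list with the modified
#'   \code{tensor} and a \code{planted} list of \code{(spec, exon_ids,
#'   network_ids)} records.
#' @export
plant_cluster <- function(collection, spec, seed = 1L) {
  if (inherits(collection, "network_tensor")) {
    collection <- structure(list(tensor = collection, planted = list(),
                                 seed = as.integer(seed)),
                            class = "benchmark_collection")
  }
  tensor <- collection$tensor
  n <- n_nodes(tensor)
  m <- n_networks(tensor)
  if (spec$n_exons_planted > n || spec$n_networks_planted > m)
    stop("planted cluster does not fit within the tensor dimensions")
  set.seed(seed)
  ex <- sort(sample.int(n, spec$n_exons_planted))
  nw <- sort(sample.int(m, spec$n_networks_planted))
  for (prev in collection$planted) {
    prev_idx <- match(prev$exon_ids, tensor_nodes(tensor))
    ov <- length(intersect(ex, prev_idx))
    if (ov > 0.5 * length(prev_idx))
      stop("planted exon subset overlaps a previous cluster by more than 50%")
  }
  ent <- unclass(tensor)
  n_e <- spec$n_exons_planted
  iu <- upper.tri(matrix(0, n_e, n_e))
  for (k in nw) {
    s <- ent[ex, ex, k]
    w <- spec$target_heaviness +
      stats::rnorm(sum(iu), 0, spec$noise_sd)
    s[iu] <- pmin(1, pmax(0, w))
    s[lower.tri(s)] <- t(s)[lower.tri(s)]
    diag(s) <- 0
    ent[ex, ex, k] <- s
  }
  collection$tensor <- structure(ent, class = "network_tensor")
  collection$planted <- c(collection$planted,
                          list(list(spec = spec,
                                    exon_ids = tensor_nodes(tensor)[ex],
                                    network_ids = tensor_networks(tensor)[nw])))
  collection
}

#' @export
print.benchmark_collection <- function(x, ...) {
  cat(sprintf("benchmark_collection: %d exons x %d networks, %d planted cluster(s)\n",
              n_nodes(x$tensor), n_networks(x$tensor), length(x$planted)))
  invisible(x)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Score recovery of planted clusters
#'
#' Matches each planted cluster to the mined cluster with maximal exon-set
#' Jaccard index and reports exon and network Jaccard indices per planted
#' cluster, a detection flag (both indices at or above their cutoffs), and
#' the overall detection fraction.
#'
#' @param found list of [fs_cluster()] from [mine_all()].
#' @param truth a \code{benchmark_collection} from [plant_cluster()].
#' @param exon_cut,net_cut Jaccard cutoffs declaring a planted cluster
#'   detected.
#' @return A list with a per-planted-cluster data frame and the summary
#'   detection fraction.
#' @export
score_recovery <- function(found, truth, exon_cut = 0.8, net_cut = 0.8) {
  rows <- lapply(seq_along(truth$planted), function(i) {
    p <- truth$planted[[i]]
    if (length(found) == 0) {
      return(data.frame(planted = i, matched = NA_integer_,
                        exon_jaccard = 0, network_jaccard = 0,
                        detected = FALSE))
    }
    ej <- vapply(found, function(cl) jaccard(cl$exon_ids, p$exon_ids), 0)
    best <- which.max(ej)
    nj <- jaccard(found[[best]]$network_ids, p$network_ids)
    data.frame(planted = i, matched = best,
               exon_jaccard = ej[best], network_jaccard = nj,
               detected = ej[best] >= exon_cut && nj >= net_cut)
  })
  per_planted <- do.call(rbind, rows)
  list(per_planted = per_planted,
       detection_rate = mean(per_planted$detected))
}

#' Default planted-cluster benchmark scenario
#'
#' One run of the standard recovery experiment: a background collection of
#' 200 exons by 20 networks with mean edge weight 0.1, one planted cluster of
#' 10 exons recurring in 8 networks at heaviness 0.7 with noise sd 0.02,
#' mined with the default configuration. Returns the recovery report for the
#' first mined cluster.
#'
#' @param seed integer seed (drives background, planting and mining restarts).
#' @param n,m,background_mean,n_exons,n_networks,heaviness,noise_sd scenario
#'   parameters; defaults are the standard scenario.
#' @param cfg a [mining_config()]; its seed is replaced by \code{seed}.
#' @return List with the \code{collection}, mined \code{clusters} and the
#'   [score_recovery()] \code{report} (cutoffs 0.9 exon / 0.8 network).
#' @export
benchmark_run <- function(seed, n = 200, m = 20, background_mean = 0.1,
                          n_exons = 10, n_networks = 8, heaviness = 0.7,
                          noise_sd = 0.02, cfg = mining_config()) {
  cfg$seed <- as.integer(seed)
  bg <- generate_background(n, m, background_mean, seed = seed)
  coll <- plant_cluster(bg, planted_spec(n_exons, n_networks, heaviness,
                                         noise_sd),
                        seed = seed + 1L)
  # one pass is enough to judge recovery of the single planted cluster
  cfg$max_patterns <- 1L
  clusters <- mine_all(coll$tensor, cfg)
  first <- if (length(clusters) >= 1) clusters[1] else list()
  report <- score_recovery(first, coll, exon_cut = 0.9, net_cut = 0.8)
  list(collection = coll, clusters = clusters, report = report)
}
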