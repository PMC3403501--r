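#' Mining configuration
#'
#' Bundles every tunable of the tensor miner. The defaults are the parameter
#' combination selected by simulation on random network collections with
#' planted clusters: \code{p = 0.8}, \code{alpha = 0.2}, \code{q = 10},
#' together with the empirical pattern criteria of heaviness >= 0.4 and at
#' least 5 exons in at least 3 networks.
#'
#' The exon constraint \eqn{f(x) = \alpha\|x\|_p + (1-\alpha)\|x\|_2} with
#' \eqn{p < 1} favours a sparse exon membership vector whose nonzero entries
#' are smooth (close in magnitude); the network constraint
#' \eqn{g(y) = \|y\|_q} with large \eqn{q} pushes network memberships towards
#' each other so clusters recur in as many networks as possible.
#'
#' @param p exponent of the sparsifying Lp term of the exon norm, in (0, 1).
#' @param alpha mixing weight of the Lp term against the L2 term, in (0, 1).
#' @param q exponent of the network Lq norm, > 1.
#' @param heaviness_threshold minimum average intra-cluster edge weight.
#' @param min_exons minimum cluster size in exons (>= 2).
#' @param min_networks minimum recurrence in networks (>= 1).
#' @param max_patterns cap on the number of clusters mined.
#' @param max_stages cap on convex-relaxation stages per optimisation.
#' @param max_inner_iters cap on alternating updates within a stage.
#' @param tol convergence tolerance on the objective.
#' @param epsilon_smooth smoothing constant keeping relaxation weights finite
#'   at zero memberships.
#' @param n_restarts random restarts per optimisation in addition to the
#'   deterministic uniform start; the best solution is kept.
#' @param seed integer seed controlling random restarts.
#' @return A list of class \code{mining_config}.
#' @export
mining_config <- function(p = 0.8, alpha = 0.2, q = 10,
                          heaviness_threshold = 0.4,
                          min_exons = 5L, min_networks = 3L,
                          max_patterns = 100L, max_stages = 20L,
                          max_inner_iters = 500L, tol = 1e-7,
                          epsilon_smooth = 1e-10, n_restarts = 2L,
                          seed = 1L) {
  stopifnot(p > 0, p < 1, alpha > 0, alpha < 1, q > 1,
            heaviness_threshold >= 0, heaviness_threshold <= 1,
            min_exons >= 2, min_networks >= 1, max_patterns >= 1,
            max_stages >= 1, max_inner_iters >= 1, tol > 0,
            epsilon_smooth >= 0, n_restarts >= 0)
  structure(list(p = p, alpha = alpha, q = q,
                 heaviness_threshold = heaviness_threshold,
                 min_exons = as.integer(min_exons),
                 min_networks = as.integer(min_networks),
                 max_patterns = as.integer(max_patterns),
                 max_stages = as.integer(max_stages),
                 max_inner_iters = as.integer(max_inner_iters),
                 tol = tol, epsilon_smooth = epsilon_smooth,
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "mining_config")
}

#' Mixed exon-membership norm
#'
#' \eqn{f(x) = \alpha (\sum_i x_i^p)^{1/p} + (1-\alpha) (\sum_i x_i^2)^{1/2}}.
#' The Lp term (p < 1) drives most components to zero; the L2 term keeps the
#' surviving components close to each other in magnitude.
#'
#' @param x nonnegative numeric vector.
#' @param p,alpha see [mining_config()].
#' @export
norm_f <- function(x, p = 0.8, alpha = 0.2) {
  if (any(x < 0)) stop("norm_f is defined for nonnegative vectors")
  alpha * sum(x^p)^(1 / p) + (1 - alpha) * sqrt(sum(x^2))
}

#' Network-membership norm
#'
#' \eqn{g(y) = (\sum_k y_k^q)^{1/q}} with \eqn{q > 1}; large \eqn{q}
#' approximates the max norm, so memberships of participating networks are
#' pushed towards a common value.
#'
#' @param y nonnegative numeric vector.
#' @param q see [mining_config()].
#' @export
norm_g <- function(y, q = 10) {
  if (any(y < 0)) stop("norm_g is defined for nonnegative vectors")
  sum(y^q)^(1 / q)
}

#' Closed-form network membership update
#'
#' Given exon memberships \code{x}, the per-network weights are
#' \eqn{w_k = \frac12 x' A_k x}. The maximiser of \eqn{\sum_k w_k y_k}
#' over \eqn{\{y \ge 0, \|y\|_q = 1\}} is, by Hoelder's inequality,
#' \eqn{y_k \propto w_k^{1/(q-1)}} normalised to unit Lq norm. When every
#' slice weight is zero the uniform feasible vector is returned.
#'
#' @param tensor a [network_tensor()].
#' @param x nonnegative exon membership vector.
#' @param q network norm exponent.
#' @return Network membership vector with \code{norm_g(y, q) == 1}.
#' @export
update_network_memberships <- function(tensor, x, q = 10) {
  if (length(x) != n_nodes(tensor)) stop("length(x) must match tensor")
  w <- slice_weights(tensor, x)
  if (all(w <= 0)) {
    m <- length(w)
    return(rep(m^(-1 / q), m))
  }
  y <- (w / max(w))^(1 / (q - 1))
  y / norm_g(y, q)
}

#' Relaxation weights from concave duality
#'
#' The non-convex constraint function \eqn{f(x)} is rewritten through
#' \eqn{h(x) = x^2}: with \eqn{u_i = x_i^2},
#' \eqn{\bar f(u) = \alpha (\sum u_i^{p/2})^{1/p} + (1-\alpha)(\sum u_i)^{1/2}}
#' is concave in \eqn{u}, and each convex stage replaces \eqn{f} by its
#' tangent \eqn{v' h(x) + const} at the current iterate, where
#' \eqn{v = \nabla \bar f(u)}. A small smoothing constant keeps the weights
#' finite when components hit zero.
#'
#' @param x current (nonnegative) exon membership vector.
#' @param p,alpha,epsilon_smooth see [mining_config()].
#' @return Strictly positive weight vector \code{v}, one entry per exon.
#' @export
refresh_relaxation_weights <- function(x, p = 0.8, alpha = 0.2,
                                       epsilon_smooth = 1e-10) {
  if (any(x < 0)) stop("x must be nonnegative")
  u <- x^2 + epsilon_smooth
  s_p <- sum(u^(p / 2))
  s_2 <- sum(u)
  alpha * 0.5 * s_p^((1 - p) / p) * u^((p - 2) / 2) +
    (1 - alpha) * 0.5 * s_2^(-0.5)
}

#' One reweighted power step for the exon memberships
#'
#' Within a convex stage the subproblem is to maximise \eqn{\frac12 x' W x}
#' with \eqn{W_{ij} = \sum_k a_{ijk} y_k}, subject to the stage's quadratic
#' surrogate of the norm constraint. The ascent step rescales the gradient by
#' the relaxation weights, projects onto the nonnegative orthant, and
#' renormalises to \code{norm_f(x) == 1}:
#' \eqn{x_i' = \max(0, (Wx)_i / v_i)}.
#'
#' @param tensor a [network_tensor()].
#' @param x current exon membership vector.
#' @param y current network membership vector.
#' Components whose square falls below the smoothing constant are
#' indistinguishable from zero under the smoothed norm, so they are truncated
#' to exact zero (completing the collapse the sparse Lp term drives) and the
#' vector is renormalised.
#'
#' @param v positive relaxation weight vector of the current stage.
#' @param cfg a [mining_config()].
#' @return Updated feasible \code{x}, or \code{NULL} to signal a degenerate
#'   (zero-gradient) step, in which case the caller restarts from a random
#'   feasible point.
#' @export
update_exon_memberships <- function(tensor, x, y, v, cfg) {
  W <- slice_mix(tensor, y)
  g <- drop(W %*% x)
  x_new <- pmax(0, g / v)
  if (all(x_new == 0)) return(NULL)
  x_new <- x_new / norm_f(x_new, cfg$p, cfg$alpha)
  x_new[x_new < sqrt(cfg$epsilon_smooth)] <- 0
  if (all(x_new == 0)) return(NULL)
  x_new / norm_f(x_new, cfg$p, cfg$alpha)
}

uniform_start <- function(tensor, cfg) {
  n <- n_nodes(tensor)
  m <- n_networks(tensor)
  x <- rep(1, n)
  x <- x / norm_f(x, cfg$p, cfg$alpha)
  y <- rep(m^(-1 / cfg$q), m)
  list(x = x, y = y)
}

random_start <- function(tensor, cfg) {
  n <- n_nodes(tensor)
  m <- n_networks(tensor)
  x <- stats::runif(n, 0.1, 1)
  x <- x / norm_f(x, cfg$p, cfg$alpha)
  y <- stats::runif(m, 0.1, 1)
  y <- y / norm_g(y, cfg$q)
  list(x = x, y = y)
}

# One full multi-stage optimisation from a given start point. The n^2 x m
# unfolding is computed once and reused, so each alternating step costs two
# BLAS passes over the tensor; the updates mirror update_exon_memberships()
# and update_network_memberships() exactly.
run_relaxation <- function(tensor, cfg, start) {
  n <- n_nodes(tensor)
  U <- unfold_tensor(tensor)
  zero_tol <- sqrt(cfg$epsilon_smooth)
  x <- start$x
  y <- start$y
  W <- matrix(U %*% y, n, n)
  obj <- 0.5 * sum(x * (W %*% x))
  trace <- obj
  degenerate <- FALSE
  for (stage in seq_len(cfg$max_stages)) {
    v <- refresh_relaxation_weights(x, cfg$p, cfg$alpha, cfg$epsilon_smooth)
    stage_start_obj <- obj
    for (it in seq_len(cfg$max_inner_iters)) {
      x_new <- pmax(0, drop(W %*% x) / v)
      if (all(x_new == 0)) { degenerate <- TRUE; break }
      x_new <- x_new / norm_f(x_new, cfg$p, cfg$alpha)
      x_new[x_new < zero_tol] <- 0
      if (all(x_new == 0)) { degenerate <- TRUE; break }
      x_new <- x_new / norm_f(x_new, cfg$p, cfg$alpha)
      w <- drop(0.5 * crossprod(U, as.vector(outer(x_new, x_new))))
      if (all(w <= 0)) {
        y_new <- rep(length(w)^(-1 / cfg$q), length(w))
      } else {
        y_new <- (w / max(w))^(1 / (cfg$q - 1))
        y_new <- y_new / norm_g(y_new, cfg$q)
      }
      obj_new <- sum(w * y_new)
      if (obj_new < obj - cfg$tol) break  # reject non-ascent step
      accepted_gain <- obj_new - obj
      x <- x_new; y <- y_new
      W <- matrix(U %*% y, n, n)
      obj <- max(obj, obj_new)
      trace <- c(trace, obj)
      if (accepted_gain < cfg$tol) break
    }
    if (degenerate) break
    if (obj - stage_start_obj < cfg$tol) break
  }
  list(x = x, y = y, objective = obj, trace = trace, stage = stage,
       degenerate = degenerate)
}

#' Solve the continuous relaxation for one cluster
#'
#' Maximises the heaviness objective over nonnegative membership vectors
#' under \code{norm_f(x) = 1} and \code{norm_g(y) = 1} by multi-stage convex
#' relaxation: within a stage, reweighted power steps on \code{x} alternate
#' with the closed-form \code{y} update; between stages the relaxation
#' weights are refreshed at the current iterate, giving an increasingly
#' accurate convex surrogate of the non-convex exon norm. Only ascent steps
#' are accepted, so the recorded objective trace is non-decreasing.
#'
#' The deterministic uniform start is always tried; \code{cfg$n_restarts}
#' additional seeded random starts are run and the best solution kept.
#'
#' @param tensor a [network_tensor()].
#' @param cfg a [mining_config()].
#' @return A \code{membership_solution}: list with feasible vectors \code{x},
#'   \code{y}, the \code{objective}, the accepted-step \code{trace}, and a
#'   \code{no_signal} flag for an all-zero tensor.
#' @export
optimize_memberships <- function(tensor, cfg = mining_config()) {
  if (all(unclass(tensor) == 0)) {
    st <- uniform_start(tensor, cfg)
    return(structure(list(x = st$x, y = st$y, objective = 0,
                          trace = numeric(0), no_signal = TRUE),
                     class = "membership_solution"))
  }
  starts <- list(uniform_start(tensor, cfg))
  if (cfg$n_restarts > 0) {
    set.seed(cfg$seed)
    for (r in seq_len(cfg$n_restarts)) starts <- c(starts, list(random_start(tensor, cfg)))
  }
  best <- NULL
  for (s in starts) {
    res <- run_relaxation(tensor, cfg, s)
    if (res$degenerate) {
      # zero gradient: retry once from a seeded random point
      res <- run_relaxation(tensor, cfg, random_start(tensor, cfg))
      if (res$degenerate) next
    }
    if (is.null(best) || res$objective > best$objective) best <- res
  }
  if (is.null(best)) {
    st <- uniform_start(tensor, cfg)
    return(structure(list(x = st$x, y = st$y, objective = 0,
                          trace = numeric(0), no_signal = TRUE),
                     class = "membership_solution"))
  }
  structure(list(x = best$x, y = best$y, objective = best$objective,
                 trace = best$trace, no_signal = FALSE),
            class = "membership_solution")
}

#' @export
print.membership_solution <- function(x, ...) {
  cat(sprintf("membership_solution: objective %.4f (%d accepted steps)\n",
              x$objective, length(x$trace)))
  invisible(x)
}

# descending order of membership, ties broken by id (index) order
rank_desc <- function(values) order(-values, seq_along(values))

#' Fixed-size pattern from ranked memberships
#'
#' Takes the top \code{n_exons} exons and top \code{n_networks} networks by
#' membership value (ties broken by id order) and returns them as a cluster
#' with their measured heaviness. With \code{refine = TRUE} the ranked
#' pattern is polished by [refine_pattern()], which solves the fixed-size
#' discrete problem locally; this recovers the heaviest fixed-size pattern
#' on instances where the continuous solution is not sharply sparse.
#'
#' @param tensor a [network_tensor()].
#' @param sol a solution from [optimize_memberships()].
#' @param n_exons,n_networks prefix sizes.
#' @param refine polish the ranked pattern by discrete hill climbing.
#' @return An [fs_cluster()].
#' @export
top_pattern <- function(tensor, sol, n_exons, n_networks, refine = FALSE) {
  ex <- rank_desc(sol$x)[seq_len(n_exons)]
  nw <- rank_desc(sol$y)[seq_len(n_networks)]
  if (refine)
    return(refine_pattern(tensor, ex, n_networks))
  fs_cluster(tensor_nodes(tensor)[ex], tensor_networks(tensor)[nw],
             pattern_heaviness(tensor, ex, nw), sol$objective)
}

#' Polish a fixed-size pattern by discrete hill climbing
#'
#' Local search for the heaviest pattern of exactly \code{|exon_ids|} exons
#' and \code{k_networks} networks, starting from the given exon set. Because
#' heaviness is additive over network slices, the optimal network set for a
#' fixed exon set is simply the \code{k_networks} slices with the heaviest
#' induced subgraph; the search therefore only explores single-exon swaps,
#' accepting any swap that increases the (network-optimised) heaviness until
#' a local optimum is reached. Cost grows with
#' \code{k_exons^2 * (n - k_exons) * m} per sweep, so this is intended for
#' moderate instance sizes.
#'
#' @param tensor a [network_tensor()].
#' @param exon_ids starting exon set (ids or indices).
#' @param k_networks number of networks in the pattern.
#' @return An [fs_cluster()] at a local optimum of the swap neighbourhood.
#' @export
refine_pattern <- function(tensor, exon_ids, k_networks) {
  n <- n_nodes(tensor)
  m <- n_networks(tensor)
  stopifnot(k_networks >= 1, k_networks <= m)
  E <- resolve_ids(exon_ids, tensor_nodes(tensor), "exon")
  slice_h <- function(E) {
    vapply(seq_len(m), function(k) pattern_heaviness(tensor, E, k), 0)
  }
  eval_E <- function(E) {
    hs <- slice_h(E)
    N <- order(-hs, seq_len(m))[seq_len(k_networks)]
    list(N = N, h = mean(hs[N]))
  }
  cur <- eval_E(E)
  repeat {
    improved <- FALSE
    for (i in E) {
      for (j in setdiff(seq_len(n), E)) {
        cand_E <- c(setdiff(E, i), j)
        cand <- eval_E(cand_E)
        if (cand$h > cur$h + 1e-12) {
          E <- cand_E
          cur <- cand
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  fs_cluster(tensor_nodes(tensor)[sort(E)], tensor_networks(tensor)[cur$N],
             cur$h)
}

# Largest y-ranked network prefix in which the exon set is heavy slice by
# slice (per-slice average edge weight >= threshold). A pattern "occurs" in
# a network when its subgraph is heavy there; those are also the networks
# later masked.
occurrence_prefix <- function(tensor, exon_idx, nw_rank, m_support, threshold) {
  t_max <- 0L
  for (t in seq_len(m_support)) {
    h <- pattern_heaviness(tensor, exon_idx, nw_rank[t])
    if (h < threshold) break
    t_max <- t
  }
  t_max
}

#' Extract the representative clusters of a solution
#'
#' Exons and networks are ranked by decreasing membership value (ties broken
#' by id order) and patterns are read off nested prefixes, restricted to
#' components with strictly positive membership. A pattern of top-ranking
#' exons \emph{occurs} in a network when its subgraph is heavy there
#' (per-slice average edge weight at or above the heaviness threshold);
#' occurrence networks are taken in membership order. Two representatives
#' are extracted: (a) the pattern occurring in the most networks while
#' having at least \code{min_exons} top-ranking exons (ties resolved towards
#' more exons), and (b) the pattern with the largest number of top-ranking
#' exons while occurring in at least \code{min_networks} networks. Identical
#' representatives are collapsed; an empty list is returned when no prefix
#' pattern reaches the threshold.
#'
#' @param tensor a [network_tensor()].
#' @param sol a solution from [optimize_memberships()].
#' @param cfg a [mining_config()].
#' @return List of 0, 1 or 2 [fs_cluster()] objects.
#' @export
extract_representative_patterns <- function(tensor, sol, cfg = mining_config()) {
  if (isTRUE(sol$no_signal)) return(list())
  n <- sum(sol$x > 0)
  m <- sum(sol$y > 0)
  if (cfg$min_exons > n || cfg$min_networks > m) return(list())
  ex_rank <- rank_desc(sol$x)
  nw_rank <- rank_desc(sol$y)
  sizes <- seq(cfg$min_exons, n)
  occ <- vapply(sizes, function(s)
    occurrence_prefix(tensor, ex_rank[seq_len(s)], nw_rank, m,
                      cfg$heaviness_threshold), 0L)
  keep <- occ >= cfg$min_networks
  if (!any(keep)) return(list())
  out <- list()
  make_pat <- function(s, t) {
    ex <- ex_rank[seq_len(s)]
    nw <- nw_rank[seq_len(t)]
    fs_cluster(tensor_nodes(tensor)[ex], tensor_networks(tensor)[nw],
               pattern_heaviness(tensor, ex, nw), sol$objective)
  }
  # (a) most occurrence networks; among ties, the largest exon prefix
  i_a <- max(which(occ == max(occ[keep]) & keep))
  out <- c(out, list(make_pat(sizes[i_a], occ[i_a])))
  # (b) most exons with at least min_networks occurrences
  i_b <- max(which(keep))
  out <- c(out, list(make_pat(sizes[i_b], occ[i_b])))
  dedup_clusters(out)
}

cluster_key <- function(cl) {
  paste(paste(sort(cl$exon_ids), collapse = ","),
        paste(sort(cl$network_ids), collapse = ","), sep = "|")
}

dedup_clusters <- function(clusters) {
  if (length(clusters) < 2) return(clusters)
  clusters[!duplicated(vapply(clusters, cluster_key, ""))]
}

#' Mine all frequent co-splicing clusters
#'
#' Repeats optimise -> extract representatives -> mask their edges until an
#' iteration yields no pattern meeting the heaviness threshold or
#' \code{max_patterns} clusters have been found. Both representatives of a
#' round (when two are returned) are masked before re-optimising, so no
#' cluster is rediscovered.
#'
#' @param tensor a [network_tensor()].
#' @param cfg a [mining_config()].
#' @param verbose print a line per mined cluster.
#' @return List of [fs_cluster()] in discovery order.
#' @export
mine_all <- function(tensor, cfg = mining_config(), verbose = FALSE) {
  clusters <- list()
  seen <- character(0)
  while (length(clusters) < cfg$max_patterns) {
    sol <- optimize_memberships(tensor, cfg)
    if (isTRUE(sol$no_signal)) break
    found <- extract_representative_patterns(tensor, sol, cfg)
    found <- found[!vapply(found, cluster_key, "") %in% seen]
    if (length(found) == 0) break
    for (cl in found) {
      if (length(clusters) >= cfg$max_patterns) break
      clusters <- c(clusters, list(cl))
      seen <- c(seen, cluster_key(cl))
      tensor <- mask_pattern(tensor, cl)
      if (verbose)
        message(sprintf("cluster %d: %d exons x %d networks, heaviness %.3f",
                        length(clusters), length(cl$exon_ids),
                        cl$recurrence, cl$heaviness))
    }
  }
  clusters
}

#' Exhaustive heaviest fixed-size pattern (small instances)
#'
#' Brute-force solution of the discrete problem: among all patterns of
#' exactly \code{k_exons} exons and \code{k_networks} networks, find the one
#' with maximal heaviness. Enumerates every combination, so it is only usable
#' as a reference on small instances (it is exponential in \code{k_exons}).
#'
#' @param tensor a [network_tensor()].
#' @param k_exons,k_networks exact pattern dimensions.
#' @return An [fs_cluster()] with the maximal heaviness.
#' @export
heaviest_fixed_size_pattern <- function(tensor, k_exons, k_networks) {
  n <- n_nodes(tensor)
  m <- n_networks(tensor)
  stopifnot(k_exons >= 2, k_exons <= n, k_networks >= 1, k_networks <= m)
  ex_sets <- utils::combn(n, k_exons, simplify = FALSE)
  nw_sets <- utils::combn(m, k_networks, simplify = FALSE)
  best <- NULL
  best_h <- -Inf
  for (es in ex_sets) {
    for (ns in nw_sets) {
      h <- pattern_heaviness(tensor, es, ns)
      if (h > best_h) {
        best_h <- h
        best <- list(es, ns)
      }
    }
  }
  fs_cluster(tensor_nodes(tensor)[best[[1]]], tensor_networks(tensor)[best[[2]]],
             best_h)
}
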