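test_that("mixed norms evaluate to their closed forms", {
  # any unit basis vector has norm 1 under both f and g
  e1 <- c(1, 0, 0)
  expect_equal(norm_f(e1, p = 0.8, alpha = 0.2), 1)
  expect_equal(norm_f(e1, p = 0.5, alpha = 0.7), 1)
  expect_equal(norm_g(e1, q = 10), 1)

  expect_equal(norm_f(c(1, 1), 0.8, 0.2), 0.2 * 2^1.25 + 0.8 * sqrt(2))
  expect_equal(norm_f(c(1, 1), 0.8, 0.2), 1.60705, tolerance = 1e-5)
  expect_equal(norm_g(c(1, 1), 10), 2^0.1)
  expect_equal(norm_g(c(1, 1), 10), 1.07177, tolerance = 1e-5)
  expect_error(norm_f(c(-1, 1)), "nonnegative")
  expect_error(norm_g(c(-1, 1)), "nonnegative")
})

# tensor with chosen slice weights w_k: one edge per slice of weight
# min(1, ...) scaled so that (1/2) x' A_k x at x = (1,1) equals w_k
weights_tensor <- function(w) {
  ent <- array(0, dim = c(2, 2, length(w)))
  for (k in seq_along(w)) ent[1, 2, k] <- ent[2, 1, k] <- w[k]
  network_tensor(ent)
}

test_that("closed-form network update maximises the Lq-constrained objective", {
  tn <- weights_tensor(c(1, 0))
  y <- update_network_memberships(tn, c(1, 1), q = 10)
  expect_equal(y, c(1, 0))

  y2 <- update_network_memberships(weights_tensor(c(1, 1)), c(1, 1), q = 10)
  expect_equal(y2, rep(2^(-0.1), 2))
  expect_equal(y2, c(0.93303, 0.93303), tolerance = 1e-5)

  y3 <- update_network_memberships(weights_tensor(c(1, 0.5)), c(1, 1), q = 10)
  expect_equal(y3, c(2^(1 / 9), 1) / sum(c(2^(10 / 9), 1))^0.1,
               tolerance = 1e-12)

  # feasibility and optimality against numeric constrained maximisation
  set.seed(21)
  for (i in 1:10) {
    w <- runif(4)
    tnw <- weights_tensor(w)
    y <- update_network_memberships(tnw, c(1, 1), q = 10)
    expect_equal(norm_g(y, 10), 1, tolerance = 1e-9)
    expect_equal(sum(w * y), numeric_y_optimum(w, 10), tolerance = 1e-6)
  }

  # all-zero slice weights fall back to the uniform feasible vector
  y0 <- update_network_memberships(weights_tensor(c(0, 0, 0)), c(1, 1), 10)
  expect_equal(y0, rep(3^(-0.1), 3))
})

test_that("relaxation weights equal the gradient of the concave reparameterisation", {
  # permutation symmetry: equal components give equal weights
  v <- refresh_relaxation_weights(rep(0.3, 4))
  expect_equal(v, rep(v[1], 4))

  # smoothing keeps weights finite at exact zeros
  v0 <- refresh_relaxation_weights(c(1, 0), epsilon_smooth = 1e-10)
  expect_true(all(is.finite(v0)) && all(v0 > 0))
  expect_equal(v0[1], 0.5, tolerance = 1e-5)

  # finite-difference oracle on the smoothed concave function of u = x^2
  p <- 0.8; alpha <- 0.2; eps <- 1e-4
  fbar <- function(u) {
    alpha * sum((u + eps)^(p / 2))^(1 / p) + (1 - alpha) * sqrt(sum(u + eps))
  }
  set.seed(33)
  x <- runif(5, 0.1, 1)
  u <- x^2
  v_ana <- refresh_relaxation_weights(x, p, alpha, epsilon_smooth = eps)
  h <- 1e-7
  v_num <- vapply(seq_along(u), function(i) {
    up <- u; up[i] <- up[i] + h
    um <- u; um[i] <- um[i] - h
    (fbar(up) - fbar(um)) / (2 * h)
  }, 0)
  expect_equal(v_ana, v_num, tolerance = 1e-5)
})

test_that("exon update preserves symmetry, signals degeneracy, and finds heavy blocks", {
  cfg <- mining_config()
  # symmetric W keeps a symmetric x symmetric
  tn <- weights_tensor(1)
  v <- refresh_relaxation_weights(c(1, 1) / norm_f(c(1, 1)), cfg$p, cfg$alpha)
  x0 <- c(1, 1) / norm_f(c(1, 1))
  x1 <- update_exon_memberships(tn, x0, 1, v, cfg)
  expect_equal(x1[1], x1[2])
  expect_equal(norm_f(x1, cfg$p, cfg$alpha), 1, tolerance = 1e-9)

  # all-zero W signals a degenerate step
  tn0 <- network_tensor(array(0, dim = c(2, 2, 1)))
  expect_null(update_exon_memberships(tn0, x0, 1, v, cfg))

  # block-diagonal W: iteration concentrates on the heavy block
  ent <- array(0, dim = c(6, 6, 1))
  ent[1:3, 1:3, 1] <- 0.9
  ent[4:6, 4:6, 1] <- 0.1
  s <- ent[, , 1]; diag(s) <- 0; ent[, , 1] <- s
  tnb <- network_tensor(ent)
  sol <- optimize_memberships(tnb, mining_config(min_exons = 3,
                                                 min_networks = 1))
  expect_true(min(sol$x[1:3]) > max(sol$x[4:6]))
})

test_that("optimiser returns feasible solutions with a non-decreasing trace", {
  cfg <- mining_config(min_exons = 4, min_networks = 2)
  tn <- random_tensor(10, 4, seed = 17)
  sol <- optimize_memberships(tn, cfg)
  expect_lte(abs(norm_f(sol$x, cfg$p, cfg$alpha) - 1), 1e-6)
  expect_lte(abs(norm_g(sol$y, cfg$q) - 1), 1e-6)
  expect_true(all(diff(sol$trace) >= -1e-9))
  expect_equal(sol$objective, objective_heaviness(tn, sol$x, sol$y),
               tolerance = 1e-7)

  # determinism: identical runs under the same configuration
  sol2 <- optimize_memberships(tn, cfg)
  expect_identical(sol$x, sol2$x)
  expect_identical(sol$y, sol2$y)

  # all-zero tensor: no-signal flag, zero objective
  tn0 <- network_tensor(array(0, dim = c(4, 4, 2)))
  sol0 <- optimize_memberships(tn0, cfg)
  expect_true(sol0$no_signal)
  expect_equal(sol0$objective, 0)
})

test_that("planted clique dominates the membership ranking", {
  cfg <- mining_config(min_exons = 5, min_networks = 2)
  tn <- clique_tensor(12, 3, 1:5, 1:2, weight = 0.9)
  sol <- optimize_memberships(tn, cfg)
  expect_setequal(order(-sol$x)[1:5], 1:5)
  expect_setequal(order(-sol$y)[1:2], 1:2)
})

test_that("representative extraction returns the planted pattern and respects thresholds", {
  cfg <- mining_config(min_exons = 5, min_networks = 2)
  tn <- clique_tensor(12, 3, 1:5, 1:2, weight = 0.9)
  sol <- optimize_memberships(tn, cfg)
  pats <- extract_representative_patterns(tn, sol, cfg)
  # both representatives coincide and are deduplicated
  expect_length(pats, 1)
  expect_setequal(pats[[1]]$exon_ids, tensor_nodes(tn)[1:5])
  expect_setequal(pats[[1]]$network_ids, tensor_networks(tn)[1:2])
  expect_equal(pats[[1]]$heaviness, 0.9)

  # nothing meets a 0.4 threshold on a uniformly light tensor
  ent <- array(0.1, dim = c(8, 8, 3))
  for (k in 1:3) { s <- ent[, , k]; diag(s) <- 0; ent[, , k] <- s }
  tn_light <- network_tensor(ent)
  sol_l <- optimize_memberships(tn_light, cfg)
  expect_length(extract_representative_patterns(tn_light, sol_l, cfg), 0)
})

test_that("mining recovers disjoint planted cliques heavier-first and respects caps", {
  ent <- array(0.05, dim = c(20, 20, 4))
  ent[1:5, 1:5, 1:3] <- 0.9
  ent[6:11, 6:11, 2:4] <- 0.7
  for (k in 1:4) {
    s <- ent[, , k]; s[lower.tri(s)] <- t(s)[lower.tri(s)]; diag(s) <- 0
    ent[, , k] <- s
  }
  tn <- network_tensor(ent)
  cfg <- mining_config(min_exons = 5, min_networks = 3)
  cls <- mine_all(tn, cfg)
  expect_gte(length(cls), 2)
  first_ex <- match(cls[[1]]$exon_ids, tensor_nodes(tn))
  expect_true(all(first_ex %in% 1:5))
  hit2 <- vapply(cls, function(cl)
    length(intersect(match(cl$exon_ids, tensor_nodes(tn)), 6:11)) >= 5, FALSE)
  expect_true(any(hit2))
  # discovery order follows heaviness of the planted structures
  expect_gt(cls[[1]]$heaviness, cls[[which(hit2)[1]]]$heaviness)
  # no duplicated (exon set, network set) pairs
  keys <- vapply(cls, function(cl)
    paste(paste(sort(cl$exon_ids), collapse = ","),
          paste(sort(cl$network_ids), collapse = ",")), "")
  expect_equal(anyDuplicated(keys), 0L)

  # pattern cap
  expect_length(mine_all(tn, mining_config(min_exons = 5, min_networks = 3,
                                           max_patterns = 1)), 1)
  # background-only tensor yields nothing
  ent0 <- array(0.05, dim = c(10, 10, 3))
  for (k in 1:3) { s <- ent0[, , k]; diag(s) <- 0; ent0[, , k] <- s }
  expect_length(mine_all(network_tensor(ent0), cfg), 0)
})

test_that("relabeling exons and networks permutes the solution identically", {
  tn <- clique_tensor(10, 3, 2:6, c(1, 3), weight = 0.8, background = 0.05)
  cfg <- mining_config(min_exons = 5, min_networks = 2)
  sol <- optimize_memberships(tn, cfg)

  perm_e <- sample(10)
  perm_n <- sample(3)
  ent_p <- unclass(tn)[perm_e, perm_e, perm_n, drop = FALSE]
  tn_p <- network_tensor(ent_p,
                         node_ids = tensor_nodes(tn)[perm_e],
                         network_ids = tensor_networks(tn)[perm_n])
  sol_p <- optimize_memberships(tn_p, cfg)
  expect_equal(sol_p$x, sol$x[perm_e], tolerance = 1e-8)
  expect_equal(sol_p$y, sol$y[perm_n], tolerance = 1e-8)
})

test_that("exhaustive search certifies small heaviest patterns and refinement reaches them", {
  tn <- clique_tensor(6, 2, c(2, 4, 5), 2, weight = 0.9, background = 0.1)
  best <- heaviest_fixed_size_pattern(tn, 3, 1)
  expect_setequal(best$exon_ids, tensor_nodes(tn)[c(2, 4, 5)])
  expect_equal(best$network_ids, tensor_networks(tn)[2])
  expect_equal(best$heaviness, 0.9)

  cfg <- mining_config(min_exons = 3, min_networks = 1,
                       heaviness_threshold = 0.2)
  sol <- optimize_memberships(tn, cfg)
  top <- top_pattern(tn, sol, 3, 1, refine = TRUE)
  expect_equal(top$heaviness, best$heaviness)
})
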