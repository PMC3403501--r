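# Fixture builders shared across test files. Everything is generated in code;
# no fixture is read from disk unless a test writes it first.

# symmetric tensor with a constant-weight clique planted on exons `clique`
# in networks `nets`, zero (or `background`) elsewhere
clique_tensor <- function(n, m, clique, nets, weight = 0.9, background = 0) {
  ent <- array(background, dim = c(n, n, m))
  for (k in nets) ent[clique, clique, k] <- weight
  for (k in seq_len(m)) {
    s <- ent[, , k]
    s[lower.tri(s)] <- t(s)[lower.tri(s)]
    diag(s) <- 0
    ent[, , k] <- s
  }
  network_tensor(ent)
}

# i.i.d. symmetric U(0, max_w) tensor
random_tensor <- function(n, m, seed, max_w = 1) {
  set.seed(seed)
  ent <- array(0, dim = c(n, n, m))
  iu <- upper.tri(matrix(0, n, n))
  for (k in seq_len(m)) {
    s <- matrix(0, n, n)
    s[iu] <- runif(sum(iu), 0, max_w)
    ent[, , k] <- s + t(s)
  }
  network_tensor(ent)
}

# two-gene toy transcript table: gene G1 with an including (FPKM 6) and a
# skipping (FPKM 4) transcript for exon E1; gene G2 fully covered
toy_transcripts <- function(samples = c("s1", "s2")) {
  ab <- matrix(rep(c(6, 4, 5), length(samples)), ncol = length(samples),
               dimnames = list(NULL, samples))
  transcript_quant(c("t1", "t2", "t3"), c("G1", "G1", "G2"),
                   list("E1", character(0), "E2"), ab)
}

# hypergeometric upper tail by direct combinatorial enumeration
hyper_tail_enum <- function(overlap, term, cluster, universe) {
  js <- overlap:min(term, cluster)
  sum(choose(term, js) * choose(universe - term, cluster - js)) /
    choose(universe, cluster)
}

# numeric maximization of sum(w * y) over {y >= 0, ||y||_q = 1} via a
# normalised absolute-value parameterisation and multi-start BFGS
numeric_y_optimum <- function(w, q, n_starts = 5, seed = 1) {
  set.seed(seed)
  obj <- function(z) {
    y <- abs(z)
    nz <- sum(y^q)^(1 / q)
    if (nz == 0) return(0)
    -sum(w * y / nz)
  }
  best <- -Inf
  for (s in seq_len(n_starts)) {
    z0 <- if (s == 1) rep(1, length(w)) else runif(length(w), 0.1, 1)
    r <- optim(z0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- max(best, -r$value)
  }
  best
}
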