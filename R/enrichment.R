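#' Annotation collection
#'
#' A named collection of gene sets (e.g. functional terms, splicing-factor
#' targets, regulatory-factor targets, protein complexes) over a stated gene
#' universe, with the per-collection significance threshold applied to raw
#' hypergeometric p-values and an optional specificity filter removing very
#' large terms (for functional terms, those with more than 300 genes).
#'
#' @param name collection label.
#' @param terms named list: term id -> character vector of gene ids.
#' @param universe character vector of gene ids; every term must be a subset.
#' @param p_threshold per-collection significance threshold in (0, 1).
#' @param max_term_size drop terms with more member genes than this
#'   (\code{NULL} keeps all terms).
#' @return An object of class \code{annotation_collection}.
#' @export
annotation_collection <- function(name, terms, universe, p_threshold = 0.05,
                                  max_term_size = NULL) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  universe <- unique(as.character(universe))
  terms <- lapply(terms, function(g) unique(as.character(g)))
  bad <- vapply(terms, function(g) !all(g %in% universe), FALSE)
  if (any(bad))
    stop("terms with genes outside the universe: ",
         paste(utils::head(names(terms)[bad], 3), collapse = ", "))
  structure(list(name = name, terms = terms, universe = universe,
                 p_threshold = p_threshold,
                 max_term_size = max_term_size),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat(sprintf("annotation_collection '%s': %d terms over %d genes (p < %g)\n",
              x$name, length(x$terms), length(x$universe), x$p_threshold))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One term per line: \code{term_id<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param path GMT file path.
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 3
  if (any(bad)) stop("GMT lines need term_id, description and >= 1 gene")
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, "", 1))
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing an overlap at least as large as \code{overlap}
#' between a term of \code{term_size} genes and a cluster of
#' \code{cluster_size} genes drawn without replacement from a universe of
#' \code{universe_size} genes.
#'
#' @param overlap observed overlap.
#' @param term_size,cluster_size,universe_size set sizes.
#' @return P(X >= overlap) under the hypergeometric law.
#' @export
hypergeometric_pvalue <- function(overlap, term_size, cluster_size,
                                  universe_size) {
  if (overlap < 0 || term_size > universe_size ||
      cluster_size > universe_size ||
      overlap > min(term_size, cluster_size))
    stop("inconsistent hypergeometric counts")
  stats::phyper(overlap - 1, term_size, universe_size - term_size,
                cluster_size, lower.tail = FALSE)
}

cluster_genes <- function(cluster, exon_to_gene) {
  genes <- exon_to_gene[cluster$exon_ids]
  unmapped <- is.na(genes)
  if (any(unmapped))
    warning(sum(unmapped), " exon(s) without gene mapping excluded")
  unique(unname(genes[!unmapped]))
}

#' Hypergeometric enrichment of clusters in an annotation collection
#'
#' Each cluster's exons are collapsed to their distinct host genes (an exon
#' without a mapping is dropped with a warning), terms larger than the
#' collection's \code{max_term_size} are removed, and every remaining term
#' is tested. Genes outside the collection's universe are ignored for
#' testing, as the hypergeometric draw is from that universe. A cluster is
#' \emph{homogeneous} for the collection when any term passes the
#' collection's p-value threshold. Raw p-values are compared to the
#' threshold; optional Benjamini-Hochberg adjustment is available but off by
#' default, matching the per-collection raw thresholds of the validation
#' protocol.
#'
#' @param clusters list of [fs_cluster()].
#' @param exon_to_gene named character vector mapping exon id -> gene id.
#' @param collection an [annotation_collection()].
#' @param adjust apply Benjamini-Hochberg within each cluster before
#'   thresholding.
#' @return Data frame with one row per cluster x tested term: cluster_id,
#'   term_id, overlap, cluster_genes, term_genes, universe, p_value,
#'   enriched.
#' @export
enrich_clusters <- function(clusters, exon_to_gene, collection,
                            adjust = FALSE) {
  terms <- collection$terms
  if (!is.null(collection$max_term_size))
    terms <- terms[vapply(terms, length, 0L) <= collection$max_term_size]
  uni_n <- length(collection$universe)
  out <- list()
  for (ci in seq_along(clusters)) {
    genes <- cluster_genes(clusters[[ci]], exon_to_gene)
    genes <- intersect(genes, collection$universe)
    if (length(genes) == 0 || length(terms) == 0) next
    p <- vapply(seq_along(terms), function(ti) {
      ov <- length(intersect(genes, terms[[ti]]))
      hypergeometric_pvalue(ov, length(terms[[ti]]), length(genes), uni_n)
    }, 0)
    ov <- vapply(terms, function(tg) length(intersect(genes, tg)), 0L)
    p_cmp <- if (adjust) stats::p.adjust(p, "BH") else p
    out[[length(out) + 1]] <- data.frame(
      cluster_id = ci, term_id = names(terms), overlap = ov,
      cluster_genes = length(genes),
      term_genes = vapply(terms, length, 0L),
      universe = uni_n, p_value = p,
      enriched = p_cmp < collection$p_threshold,
      row.names = NULL)
  }
  if (length(out) == 0)
    return(data.frame(cluster_id = integer(0), term_id = character(0),
                      overlap = integer(0), cluster_genes = integer(0),
                      term_genes = integer(0), universe = integer(0),
                      p_value = numeric(0), enriched = logical(0)))
  do.call(rbind, out)
}

#' Is a cluster homogeneous for a collection?
#'
#' @param enrichments result of [enrich_clusters()].
#' @param n_clusters total number of clusters tested.
#' @return Logical vector, one entry per cluster.
#' @export
homogeneous_clusters <- function(enrichments, n_clusters) {
  flag <- rep(FALSE, n_clusters)
  if (nrow(enrichments) > 0) {
    agg <- tapply(enrichments$enriched, enrichments$cluster_id, any)
    flag[as.integer(names(agg))] <- as.logical(agg)
  }
  flag
}

#' Enrichment fold ratio against a random size-matched baseline
#'
#' Draws \code{reps} random gene sets for each observed cluster size
#' (uniformly without replacement from the universe), computes the fraction
#' of real and random sets that are homogeneous for the collection, and
#' reports their ratio: the percentage of enriched real clusters divided by
#' the percentage of enriched random clusters. When no random set is
#' enriched the fold is undefined and flagged rather than divided.
#'
#' @param cluster_gene_sets list of character vectors: the host-gene sets of
#'   the real clusters.
#' @param collection an [annotation_collection()].
#' @param reps random sets drawn per real cluster.
#' @param seed integer seed for the baseline draws.
#' @return List with \code{pct_real}, \code{pct_random} (percentages),
#'   \code{fold}, and \code{fold_defined}.
#' @export
baseline_fold_ratio <- function(cluster_gene_sets, collection, reps = 1000L,
                                seed = 1L) {
  stopifnot(reps >= 1)
  universe <- collection$universe
  if (length(universe) == 0) stop("empty gene universe")
  terms <- collection$terms
  if (!is.null(collection$max_term_size))
    terms <- terms[vapply(terms, length, 0L) <= collection$max_term_size]
  uni_n <- length(universe)
  homogeneous <- function(genes) {
    genes <- intersect(genes, universe)
    if (length(genes) == 0) return(FALSE)
    for (tg in terms) {
      ov <- length(intersect(genes, tg))
      if (hypergeometric_pvalue(ov, length(tg), length(genes), uni_n) <
          collection$p_threshold) return(TRUE)
    }
    FALSE
  }
  real <- vapply(cluster_gene_sets, homogeneous, FALSE)
  set.seed(seed)
  rand <- vapply(cluster_gene_sets, function(gs) {
    size <- length(intersect(gs, universe))
    if (size == 0) return(0)
    mean(vapply(seq_len(reps), function(r)
      homogeneous(sample(universe, size)), FALSE))
  }, 0)
  pct_real <- 100 * mean(real)
  pct_random <- 100 * mean(rand)
  list(pct_real = pct_real, pct_random = pct_random,
       fold = if (pct_random > 0) pct_real / pct_random else NA_real_,
       fold_defined = pct_random > 0)
}

#' Fold ratio from enrichment percentages
#'
#' The enrichment fold ratio as reported in validation summaries: percentage
#' of enriched real clusters divided by the percentage of enriched random
#' size-matched clusters, rounded to one decimal.
#'
#' @param pct_real,pct_random percentages (0-100).
#' @param digits decimals kept in the reported ratio.
#' @return The rounded fold ratio; \code{NA} when \code{pct_random} is zero.
#' @export
fold_ratio <- function(pct_real, pct_random, digits = 1) {
  if (pct_random == 0) return(NA_real_)
  round(pct_real / pct_random, digits)
}

#' Mean pairwise expression correlation of a gene set
#'
#' Mean Pearson correlation over all unordered gene pairs
#' (pairwise-complete samples). Clusters of exons whose host genes fall at
#' or below 0.2 are flagged as low-correlation: co-splicing without
#' co-expression.
#'
#' @param gene_ids gene set (>= 2 genes with profiles).
#' @param expression gene x sample numeric matrix with gene ids as rownames.
#' @param low_cut flag threshold.
#' @return List with \code{mean_correlation} and \code{low_correlation}.
#' @export
mean_pairwise_profile_correlation <- function(gene_ids, expression,
                                              low_cut = 0.2) {
  gene_ids <- unique(gene_ids)
  present <- gene_ids[gene_ids %in% rownames(expression)]
  if (length(present) < 2) stop("need at least 2 profiled genes")
  cm <- suppressWarnings(
    stats::cor(t(expression[present, , drop = FALSE]),
               use = "pairwise.complete.obs"))
  m <- mean(cm[upper.tri(cm)], na.rm = TRUE)
  list(mean_correlation = m, low_correlation = m <= low_cut)
}

#' Fraction of exons in several functionally distinct clusters
#'
#' Among clusters with recurrence at or above \code{min_recurrence}, the
#' fraction of distinct member exons that belong to at least two clusters
#' whose sets of enriched terms are not identical, i.e. exons participating
#' in different functional contexts depending on which other exons they are
#' co-spliced with.
#'
#' @param clusters list of [fs_cluster()].
#' @param enrichments result of [enrich_clusters()] on those clusters.
#' @param min_recurrence recurrence filter.
#' @return Fraction in \eqn{[0, 1]}.
#' @export
multi_membership_fraction <- function(clusters, enrichments,
                                      min_recurrence = 3L) {
  keep <- which(vapply(clusters, function(cl) cl$recurrence, 0L) >=
                  min_recurrence)
  if (length(keep) == 0) return(0)
  term_sets <- lapply(keep, function(ci) {
    e <- enrichments[enrichments$cluster_id == ci & enrichments$enriched, ]
    sort(unique(e$term_id))
  })
  exons <- unique(unlist(lapply(clusters[keep], function(cl) cl$exon_ids)))
  multi <- vapply(exons, function(ex) {
    inn <- which(vapply(clusters[keep], function(cl) ex %in% cl$exon_ids,
                        FALSE))
    if (length(inn) < 2) return(FALSE)
    keys <- unique(vapply(term_sets[inn], paste, "", collapse = "|"))
    length(keys) > 1
  }, FALSE)
  mean(multi)
}
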