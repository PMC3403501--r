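#' Write / read mined clusters
#'
#' Clusters are persisted as a JSON list of objects with fields
#' \code{cluster_id}, \code{exon_ids}, \code{network_ids}, \code{heaviness},
#' \code{recurrence}, \code{objective}; a companion TSV (one row per
#' exon-cluster membership) is written next to the JSON when
#' \code{tsv = TRUE}.
#'
#' @param clusters list of [fs_cluster()].
#' @param path JSON output path.
#' @param tsv also write \code{<path>.tsv} with columns cluster_id, exon_id.
#' @rdname cluster_io
#' @export
write_clusters <- function(clusters, path, tsv = TRUE) {
  recs <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    list(cluster_id = i, exon_ids = cl$exon_ids,
         network_ids = cl$network_ids, heaviness = cl$heaviness,
         recurrence = cl$recurrence, objective = cl$objective)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (tsv && length(clusters) > 0) {
    df <- do.call(rbind, lapply(seq_along(clusters), function(i)
      data.frame(cluster_id = i, exon_id = clusters[[i]]$exon_ids)))
    utils::write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname cluster_io
#' @export
read_clusters <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r)
    fs_cluster(unlist(r$exon_ids), unlist(r$network_ids),
               r$heaviness, r$objective %||% NA_real_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
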