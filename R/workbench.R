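#' Run configuration
#'
#' Collects everything a reproducible run needs: the mode, the input paths
#' it requires, the mining configuration, the expression-filter parameters,
#' the seed and the output directory. A configuration can also be loaded
#' from a YAML file whose keys mirror these arguments (values given here
#' override the file).
#'
#' @param mode one of \code{"build-networks"}, \code{"mine"},
#'   \code{"simulate"}, \code{"enrich"}, \code{"full"}.
#' @param out output directory.
#' @param seed integer seed recorded in the manifest and used for every
#'   random step.
#' @param transcript_paths transcript tables (one per dataset) for the
#'   inclusion stage.
#' @param exon_table path to a TSV with columns exon_id, gene_id (the
#'   cassette-exon universe).
#' @param inclusion_paths precomputed inclusion matrices (alternative to
#'   transcript tables).
#' @param tensor_manifest path to a tensor manifest for mine mode.
#' @param clusters_json mined clusters for enrich mode.
#' @param gmt_path,universe_path annotation collection inputs.
#' @param mining a [mining_config()].
#' @param percentile,min_samples expression-filter parameters.
#' @param min_overlap,edge_transform correlation-network parameters.
#' @param p_threshold,max_term_size,baseline_reps enrichment parameters.
#' @param simulate list of simulation parameters (n, m, background_mean and
#'   a list of [planted_spec()]) for simulate mode.
#' @param config_file optional YAML file supplying defaults.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(mode = c("full", "build-networks", "mine", "simulate",
                                "enrich"),
                       out = "fscmine-run", seed = 1L,
                       transcript_paths = NULL, exon_table = NULL,
                       inclusion_paths = NULL, tensor_manifest = NULL,
                       clusters_json = NULL, gmt_path = NULL,
                       universe_path = NULL, mining = mining_config(),
                       percentile = 80, min_samples = 6L,
                       min_overlap = 4L, edge_transform = "clamp",
                       p_threshold = 0.05, max_term_size = NULL,
                       baseline_reps = 100L, simulate = NULL,
                       config_file = NULL) {
  if (!is.null(config_file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the 'yaml' package")
    defaults <- yaml::read_yaml(config_file)
    call <- as.list(match.call())[-1]
    for (key in setdiff(names(defaults), names(call))) {
      if (key == "mining") {
        mining <- do.call(mining_config, defaults$mining)
      } else assign(key, defaults[[key]])
    }
  }
  mode <- match.arg(mode)
  cfg <- list(mode = mode, out = out, seed = as.integer(seed),
              transcript_paths = transcript_paths, exon_table = exon_table,
              inclusion_paths = inclusion_paths,
              tensor_manifest = tensor_manifest,
              clusters_json = clusters_json, gmt_path = gmt_path,
              universe_path = universe_path, mining = mining,
              percentile = percentile, min_samples = min_samples,
              min_overlap = min_overlap, edge_transform = edge_transform,
              p_threshold = p_threshold, max_term_size = max_term_size,
              baseline_reps = baseline_reps, simulate = simulate)
  class(cfg) <- "run_config"
  cfg
}

config_paths <- function(config) {
  as.character(unlist(config[c("transcript_paths", "exon_table",
                               "inclusion_paths", "tensor_manifest",
                               "clusters_json", "gmt_path",
                               "universe_path")]))
}

#' Validate the inputs of a run without mutating them
#'
#' Checks path existence for the chosen mode, matrix shape consistency,
#' value ranges, symmetry of provided networks and id cross-references, and
#' returns machine-readable diagnostics (one row each: severity, stage,
#' message) rather than stopping at the first problem.
#'
#' @param config a [run_config()].
#' @return Data frame of diagnostics; zero rows means all checks passed.
#' @export
validate_inputs <- function(config) {
  diag <- list()
  note <- function(severity, stage, message)
    diag[[length(diag) + 1]] <<- data.frame(severity = severity,
                                            stage = stage, message = message)
  for (p in config_paths(config))
    if (!file.exists(p)) note("error", "paths", paste("missing input:", p))
  if (config$mode == "mine" && is.null(config$tensor_manifest))
    note("error", "mine", "mine mode requires a tensor manifest")
  if (config$mode == "enrich" &&
      (is.null(config$clusters_json) || is.null(config$gmt_path)))
    note("error", "enrich", "enrich mode requires clusters JSON and a GMT file")
  for (p in config$inclusion_paths) {
    if (!file.exists(p)) next
    im <- tryCatch(read_inclusion_matrix(p), error = function(e) e)
    if (inherits(im, "error")) {
      note("error", "inclusion", conditionMessage(im))
    } else {
      v <- im$values[!is.na(im$values)]
      if (length(v) && (min(v) < 0 || max(v) > 1))
        note("error", "inclusion", paste("values outside [0,1] in", p))
    }
  }
  if (!is.null(config$tensor_manifest) && file.exists(config$tensor_manifest)) {
    man <- utils::read.delim(config$tensor_manifest, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(man))) {
      np <- file.path(dirname(config$tensor_manifest), man$path[i])
      if (!file.exists(np)) {
        note("error", "tensor", paste("missing network file:", np))
        next
      }
      w <- tryCatch(read_network(np, man$network_id[i]),
                    error = function(e) e)
      if (inherits(w, "error"))
        note("error", "tensor",
             paste0(man$network_id[i], ": ", conditionMessage(w)))
    }
  }
  if (length(diag) == 0)
    return(data.frame(severity = character(0), stage = character(0),
                      message = character(0)))
  do.call(rbind, diag)
}

#' Execute a configured run end to end
#'
#' Chains the stages the mode asks for: inclusion-rate computation from
#' transcript tables, correlation-network construction, tensor assembly,
#' mining, and (when annotations are given) enrichment; \code{simulate} mode
#' generates a planted benchmark collection instead, mines it, and scores
#' recovery. All outputs land in \code{config$out} together with a JSON
#' manifest capturing the mode, every parameter, the seed and the md5
#' checksum of each input, which suffices to reproduce the run: the same
#' configuration and seed give identical cluster output.
#'
#' @param config a [run_config()].
#' @return The manifest (invisibly), as a list.
#' @export
run_full <- function(config) {
  diagnostics <- validate_inputs(config)
  if (any(diagnostics$severity == "error"))
    stop("invalid inputs:\n",
         paste(sprintf("  [%s] %s", diagnostics$stage, diagnostics$message),
               collapse = "\n"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(mode = config$mode, seed = config$seed,
                   mining = unclass(config$mining),
                   parameters = config[c("percentile", "min_samples",
                                         "min_overlap", "edge_transform",
                                         "p_threshold", "baseline_reps")],
                   inputs = as.list(tools::md5sum(config_paths(config))))
  tensor <- NULL
  truth <- NULL

  if (config$mode %in% c("build-networks", "full") &&
      (!is.null(config$transcript_paths) || !is.null(config$inclusion_paths))) {
    mats <- list()
    if (!is.null(config$transcript_paths)) {
      exons <- utils::read.delim(config$exon_table, stringsAsFactors = FALSE)
      mats <- lapply(config$transcript_paths, function(p)
        build_inclusion_matrix(read_transcript_quant(p), exons,
                               percentile = config$percentile,
                               min_samples = config$min_samples))
    }
    if (!is.null(config$inclusion_paths))
      mats <- c(mats, lapply(config$inclusion_paths, read_inclusion_matrix))
    nets <- lapply(seq_along(mats), function(i)
      correlation_network(mats[[i]], min_overlap = config$min_overlap,
                          edge_transform = config$edge_transform,
                          dataset_id = sprintf("dataset%02d", i)))
    tensor <- assemble_tensor(nets)
    write_tensor_manifest(tensor, file.path(config$out, "tensor"))
    if (config$mode == "build-networks") {
      manifest$networks <- length(nets)
      return(write_manifest(manifest, config$out))
    }
  }

  if (config$mode == "simulate") {
    sim <- config$simulate
    if (is.null(sim)) stop("simulate mode requires config$simulate")
    bg <- generate_background(sim$n, sim$m, sim$background_mean %||% 0.1,
                              seed = config$seed)
    coll <- bg
    for (i in seq_along(sim$plants)) {
      coll <- plant_cluster(coll, sim$plants[[i]], seed = config$seed + i)
    }
    truth <- coll
    tensor <- coll$tensor
    write_tensor_manifest(tensor, file.path(config$out, "tensor"))
    jsonlite::write_json(lapply(coll$planted, function(p)
      list(exon_ids = p$exon_ids, network_ids = p$network_ids,
           target_heaviness = p$spec$target_heaviness)),
      file.path(config$out, "ground_truth.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }

  if (config$mode == "mine" && !is.null(config$tensor_manifest))
    tensor <- read_tensor_manifest(config$tensor_manifest)

  clusters <- NULL
  if (config$mode %in% c("mine", "simulate", "full") && !is.null(tensor)) {
    cfg <- config$mining
    cfg$seed <- config$seed
    clusters <- mine_all(tensor, cfg)
    write_clusters(clusters, file.path(config$out, "clusters.json"))
    manifest$n_clusters <- length(clusters)
  }

  if (!is.null(truth) && !is.null(clusters)) {
    rec <- score_recovery(clusters, truth)
    utils::write.table(rec$per_planted,
                       file.path(config$out, "recovery.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$detection_rate <- rec$detection_rate
  }

  if (config$mode == "enrich" ||
      (config$mode == "full" && !is.null(config$gmt_path))) {
    if (is.null(clusters)) clusters <- read_clusters(config$clusters_json)
    universe <- readLines(config$universe_path)
    collection <- annotation_collection("annotations",
                                        read_gmt(config$gmt_path), universe,
                                        p_threshold = config$p_threshold,
                                        max_term_size = config$max_term_size)
    # host gene = exon id prefix before the last ":" when no map is given
    exon_ids <- unique(unlist(lapply(clusters, function(cl) cl$exon_ids)))
    exon_to_gene <- stats::setNames(sub(":[^:]*$", "", exon_ids), exon_ids)
    enr <- enrich_clusters(clusters, exon_to_gene, collection)
    utils::write.table(enr, file.path(config$out, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gene_sets <- lapply(clusters, cluster_genes, exon_to_gene = exon_to_gene)
    base <- baseline_fold_ratio(gene_sets, collection,
                                reps = config$baseline_reps,
                                seed = config$seed)
    manifest$enrichment <- base
  }

  write_manifest(manifest, config$out)
}

write_manifest <- function(manifest, out) {
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
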