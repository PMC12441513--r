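# Orchestration of the four-step integrated strategy as composable stage
# functions over a run directory: simulate (or import), feature finding,
# molecular networking, rule-engine annotation, in-vivo identification, and
# a merged report. Each stage writes its outputs plus a JSON manifest with
# input checksums so deterministic stages reproduce bit-for-bit.

#' Pipeline configuration
#'
#' Collects the per-stage parameter objects and paths; serializes to YAML and
#' back unchanged. Defaults are the published workflow settings.
#'
#' @param dir Run directory.
#' @param seed Seed for the synthetic stages.
#' @param feature_params [feature_finder_params()].
#' @param net_params [network_params()].
#' @param ppm_tol In-vivo matching tolerance, ppm.
#' @param min_height XIC detection threshold.
#' @param blank_fraction Maximum blank/dosed apex ratio.
#' @param max_depth Metabolite chain depth.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(dir, seed = 1L,
                            feature_params = feature_finder_params(),
                            net_params = network_params(),
                            ppm_tol = 5, min_height = 7000,
                            blank_fraction = 0.05, max_depth = 2) {
  structure(list(dir = dir, seed = as.integer(seed),
                 feature_params = unclass(feature_params),
                 net_params = unclass(net_params), ppm_tol = ppm_tol,
                 min_height = min_height, blank_fraction = blank_fraction,
                 max_depth = max_depth),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` (for writing).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(dir = raw$dir, seed = raw$seed,
                         feature_params = do.call(feature_finder_params,
                                                  raw$feature_params),
                         net_params = do.call(network_params, raw$net_params),
                         ppm_tol = raw$ppm_tol, min_height = raw$min_height,
                         blank_fraction = raw$blank_fraction,
                         max_depth = raw$max_depth)
  cfg
}

write_manifest <- function(dir, stage, inputs, outputs) {
  manifest <- list(
    stage = stage,
    timestamp = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("herbnet")),
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    output_md5 = as.list(tools::md5sum(outputs[file.exists(outputs)]))
  )
  jsonlite::write_json(manifest, file.path(dir, paste0("manifest_", stage,
                                                       ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a study acquisition into a run directory
#'
#' @param config [pipeline_config()].
#' @param library Compound table (default: the packaged prototype table).
#' @param ... Passed to [simulate_acquisition()].
#' @return The simulation object, invisibly.
#' @export
pipeline_simulate <- function(config, library = table1_prototypes(), ...) {
  sim <- simulate_acquisition(library,
                              simulation_config(seed = config$seed), ...)
  write_acquisition(sim, config$dir)
  outs <- list.files(config$dir, full.names = TRUE)
  write_manifest(config$dir, "simulate", character(0), outs)
  invisible(sim)
}

#' Feature finding stage
#'
#' Reads every `<sample>_ms1.csv` / `<sample>_ms2.mgf` pair in the run
#' directory, runs [find_features()] per sample, and writes
#' `<sample>_features.csv` plus `<sample>_features.mgf` (the FBMN input
#' pair). Errors if no sample produces any feature.
#'
#' @param config [pipeline_config()].
#' @return Named list of feature tables, invisibly.
#' @export
pipeline_features <- function(config) {
  params <- do.call(feature_finder_params, config$feature_params)
  ms1_files <- list.files(config$dir, pattern = "_ms1\\.csv$",
                          full.names = TRUE)
  if (length(ms1_files) == 0) {
    stop("no <sample>_ms1.csv files in ", config$dir,
         "; run pipeline_simulate() or import data first", call. = FALSE)
  }
  out <- list()
  for (f in ms1_files) {
    sample <- sub("_ms1\\.csv$", "", basename(f))
    mgf <- file.path(config$dir, paste0(sample, "_ms2.mgf"))
    run <- list(list(ms1 = read_scans_csv(f),
                     ms2 = if (file.exists(mgf)) read_mgf(mgf) else list()))
    names(run) <- sample
    feats <- find_features(run, params)
    csv <- file.path(config$dir, paste0(sample, "_features.csv"))
    utils::write.csv(feats[, setdiff(names(feats), "ms2")], csv,
                     row.names = FALSE)
    keep <- !vapply(feats$ms2, is.null, logical(1))
    write_mgf(feats$ms2[keep],
              file.path(config$dir, paste0(sample, "_features.mgf")))
    out[[sample]] <- feats
  }
  if (all(vapply(out, nrow, integer(1)) == 0)) {
    stop("feature finding produced no features in any sample", call. = FALSE)
  }
  write_manifest(config$dir, "features", ms1_files,
                 list.files(config$dir, pattern = "_features\\.",
                            full.names = TRUE))
  invisible(out)
}

#' Molecular networking stage
#'
#' Builds the molecular network from the extract sample's feature spectra,
#' annotates against a local spectral library, propagates cluster
#' hypotheses, and writes GraphML plus the cluster-accounting CSV.
#'
#' @param config [pipeline_config()].
#' @param sample Sample whose features are networked (default `"extract"`).
#' @param library Optional local spectral library for [annotate_network()].
#' @return The `MolecularNetwork`, invisibly.
#' @export
pipeline_network <- function(config, sample = "extract", library = NULL) {
  params <- do.call(network_params, config$net_params)
  mgf <- file.path(config$dir, paste0(sample, "_features.mgf"))
  if (!file.exists(mgf)) {
    stop("missing ", mgf, "; run pipeline_features() first", call. = FALSE)
  }
  spectra <- read_mgf(mgf)
  net <- build_network(spectra, params)
  if (!is.null(library)) net <- annotate_network(net, library, params)
  net <- propagate_annotations(net)
  write_graphml(net, file.path(config$dir, paste0(sample, "_network.graphml")))
  utils::write.csv(network_stats(net),
                   file.path(config$dir, paste0(sample, "_network_stats.csv")),
                   row.names = FALSE)
  write_manifest(config$dir, "network", mgf,
                 file.path(config$dir, paste0(sample, c("_network.graphml",
                                                        "_network_stats.csv"))))
  invisible(net)
}

#' Rule-engine annotation stage
#'
#' Classifies every feature MS2 spectrum of a sample with
#' [classify_spectrum()] and writes the classification report CSV.
#'
#' @param config [pipeline_config()].
#' @param sample Sample name.
#' @param rulebase Rulebase data frame.
#' @return Classification data frame, invisibly.
#' @export
pipeline_annotate <- function(config, sample = "extract",
                              rulebase = default_rulebase()) {
  mgf <- file.path(config$dir, paste0(sample, "_features.mgf"))
  if (!file.exists(mgf)) {
    stop("missing ", mgf, "; run pipeline_features() first", call. = FALSE)
  }
  spectra <- read_mgf(mgf)
  rows <- lapply(spectra, function(s) {
    cls <- classify_spectrum(s, rulebase)
    data.frame(feature_id = s$id, precursor_mz = s$precursor_mz,
               rt = s$rt, compound_class = cls$compound_class,
               score = cls$score, runner_up = cls$runner_up,
               runner_up_score = cls$runner_up_score,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  out <- file.path(config$dir, paste0(sample, "_classes.csv"))
  utils::write.csv(report, out, row.names = FALSE)
  write_manifest(config$dir, "annotate", mgf, out)
  invisible(report)
}

#' In-vivo identification stage
#'
#' XIC presence calls of library prototypes in dosed vs blank plasma and
#' cerebrum, metabolite prediction for the detected prototypes, and matching
#' of predicted metabolites against dosed-only features with fragment/class
#' evidence. Observed prototype feature spectra (when found) supply the
#' fragment sets used as matching evidence.
#'
#' @param config [pipeline_config()].
#' @param library Prototype compound table.
#' @param proto_rt_tol Retention-time window (min) within which a dosed
#'   feature at a detected prototype's m/z is attributed to that prototype
#'   and removed from the metabolite search space.
#' @return List with `calls` (presence calls), `metabolites` (matched
#'   candidates) and `pathways`, invisibly.
#' @export
pipeline_invivo <- function(config, library = table1_prototypes(),
                            proto_rt_tol = 0.2) {
  need <- file.path(config$dir, paste0(
    c("plasma_dosed", "plasma_blank", "cerebrum_dosed", "cerebrum_blank"),
    "_ms1.csv"))
  if (!all(file.exists(need))) {
    stop("missing biosample scan tables; run pipeline_simulate() first",
         call. = FALSE)
  }
  scans <- lapply(stats::setNames(need, sub("_ms1\\.csv$", "",
                                            basename(need))), read_scans_csv)
  calls <- rbind(
    call_prototypes(library, scans$plasma_dosed, scans$plasma_blank,
                    "plasma", config$ppm_tol, config$min_height,
                    config$blank_fraction),
    call_prototypes(library, scans$cerebrum_dosed, scans$cerebrum_blank,
                    "cerebrum", config$ppm_tol, config$min_height,
                    config$blank_fraction))
  detected <- unique(calls$compound_id[calls$detected])
  proto <- library[library$id %in% detected, , drop = FALSE]
  feat_file <- function(s) file.path(config$dir, paste0(s, "_features.csv"))
  load_features <- function(s) {
    csv <- feat_file(s)
    if (!file.exists(csv)) return(NULL)
    df <- utils::read.csv(csv, stringsAsFactors = FALSE)
    mgf <- file.path(config$dir, paste0(s, "_features.mgf"))
    sp <- if (file.exists(mgf)) read_mgf(mgf) else list()
    ids <- vapply(sp, function(x) x$id, character(1))
    df$ms2 <- lapply(df$feature_id, function(id) {
      k <- match(id, ids)
      if (is.na(k)) NULL else sp[[k]]
    })
    df
  }
  dosed_feats <- load_features("plasma_dosed")
  blank_feats <- load_features("plasma_blank")
  matched <- NULL
  pathways <- NULL
  if (nrow(proto) > 0) {
    # observed prototype spectra as evidence source, falling back to the
    # library's printed fragments
    if (!is.null(dosed_feats) && nrow(dosed_feats) > 0) {
      proto$fragments <- lapply(seq_len(nrow(proto)), function(i) {
        target <- adduct_mz(monoisotopic_mass(proto$formula[[i]]),
                            proto$adduct[[i]])
        hit <- which(abs(ppm_error(dosed_feats$mz, target)) <= config$ppm_tol)
        if (length(hit) && !is.null(dosed_feats$ms2[[hit[[1]]]])) {
          dosed_feats$ms2[[hit[[1]]]]$mz
        } else proto$fragments[[i]]
      })
    }
    # features already attributed to a detected prototype (m/z and rt both
    # agree) are not metabolite candidates
    met_space <- dosed_feats
    if (!is.null(met_space) && nrow(met_space) > 0) {
      is_proto <- vapply(seq_len(nrow(met_space)), function(j) {
        any(vapply(seq_len(nrow(proto)), function(i) {
          target <- adduct_mz(monoisotopic_mass(proto$formula[[i]]),
                              proto$adduct[[i]])
          abs(ppm_error(met_space$mz[[j]], target)) <= config$ppm_tol &&
            abs(met_space$rt[[j]] - proto$rt[[i]]) <= proto_rt_tol
        }, logical(1)))
      }, logical(1))
      met_space <- met_space[!is_proto, , drop = FALSE]
    }
    cand <- predict_metabolite_candidates(proto, max_depth = config$max_depth)
    matched <- match_metabolites(cand, met_space, blank_feats,
                                 ppm_tol = config$ppm_tol)
    utils::write.csv(
      matched[, setdiff(names(matched), "prototype_fragments")],
      file.path(config$dir, "metabolite_report.csv"), row.names = FALSE)
    pathways <- assemble_pathways(proto, matched)
    write_graphml(pathways$graph, file.path(config$dir, "pathways.graphml"))
  }
  utils::write.csv(calls, file.path(config$dir, "presence_calls.csv"),
                   row.names = FALSE)
  write_manifest(config$dir, "invivo", need,
                 file.path(config$dir, c("presence_calls.csv",
                                         "metabolite_report.csv",
                                         "pathways.graphml")))
  invisible(list(calls = calls, metabolites = matched, pathways = pathways))
}

#' Merged pipeline report
#'
#' Combines the network accounting, classification report and in-vivo calls
#' into `report.csv` files mirroring the study's presentation: a prototype
#' table with +/- presence flags per matrix and the metabolite table schema.
#'
#' @param config [pipeline_config()].
#' @param library Prototype compound table used by the in-vivo stage.
#' @return List of report data frames, invisibly.
#' @export
pipeline_report <- function(config, library = table1_prototypes()) {
  calls_csv <- file.path(config$dir, "presence_calls.csv")
  if (!file.exists(calls_csv)) {
    stop("missing presence_calls.csv; run pipeline_invivo() first",
         call. = FALSE)
  }
  calls <- utils::read.csv(calls_csv, stringsAsFactors = FALSE)
  flag <- function(matrix) {
    d <- calls[calls$matrix == matrix, ]
    ifelse(library$id %in% d$compound_id[d$detected], "+", "-")
  }
  proto_report <- data.frame(id = library$id, name = library$name,
                             formula = library$formula,
                             adduct = library$adduct,
                             plasma = flag("plasma"),
                             cerebrum = flag("cerebrum"),
                             stringsAsFactors = FALSE)
  utils::write.csv(proto_report, file.path(config$dir, "report_prototypes.csv"),
                   row.names = FALSE)
  stats_csv <- file.path(config$dir, "extract_network_stats.csv")
  net_stats <- if (file.exists(stats_csv)) {
    utils::read.csv(stats_csv)
  } else {
    data.frame(total_nodes = 0, clustered_nodes = 0, non_clustered_nodes = 0,
               clusters = 0, annotated_nodes = 0, annotated_clusters = 0)
  }
  utils::write.csv(net_stats, file.path(config$dir, "report_network.csv"),
                   row.names = FALSE)
  write_manifest(config$dir, "report", calls_csv,
                 file.path(config$dir, c("report_prototypes.csv",
                                         "report_network.csv")))
  invisible(list(prototypes = proto_report, network = net_stats))
}

#' Run the full pipeline on a synthetic study
#'
#' Convenience wrapper chaining simulate, features, network, annotate,
#' in-vivo and report on one run directory.
#'
#' @param config [pipeline_config()].
#' @param library Compound table.
#' @param ... Passed to [pipeline_simulate()] (planting arguments).
#' @return List with the per-stage results.
#' @export
run_pipeline <- function(config, library = table1_prototypes(), ...) {
  sim <- pipeline_simulate(config, library, ...)
  feats <- pipeline_features(config)
  net <- pipeline_network(config)
  classes <- pipeline_annotate(config)
  invivo <- pipeline_invivo(config, library)
  report <- pipeline_report(config, library)
  list(sim = sim, features = feats, network = net, classes = classes,
       invivo = invivo, report = report)
}
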