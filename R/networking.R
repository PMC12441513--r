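# Feature-based molecular networking: modified-cosine spectral similarity
# with precursor-shift peak matching, graph construction under the workflow
# thresholds, cluster accounting, local library matching and in-cluster
# annotation propagation.

#' Molecular-networking parameters
#'
#' Defaults are the workflow's FBMN settings: 0.02 Da precursor and fragment
#' tolerances, minimum pair cosine 0.70, minimum matched fragment ions 6, and
#' library-search minimum matched peaks 6.
#'
#' @param precursor_tol,fragment_tol Mass tolerances, Da.
#' @param min_cosine Minimum modified-cosine score for an edge.
#' @param min_matched_peaks Minimum matched fragment ions for an edge.
#' @param library_min_matched_peaks Minimum matched peaks for a library hit.
#' @param intensity_transform `"sqrt"` (GNPS convention) or `"none"`.
#' @return A list of class `network_params`.
#' @export
network_params <- function(precursor_tol = 0.02, fragment_tol = 0.02,
                           min_cosine = 0.70, min_matched_peaks = 6L,
                           library_min_matched_peaks = 6L,
                           intensity_transform = c("sqrt", "none")) {
  intensity_transform <- match.arg(intensity_transform)
  stopifnot(precursor_tol > 0, fragment_tol > 0,
            min_cosine >= 0, min_cosine <= 1, min_matched_peaks >= 1)
  structure(list(precursor_tol = precursor_tol, fragment_tol = fragment_tol,
                 min_cosine = min_cosine,
                 min_matched_peaks = as.integer(min_matched_peaks),
                 library_min_matched_peaks = as.integer(library_min_matched_peaks),
                 intensity_transform = intensity_transform),
            class = "network_params")
}

#' Modified-cosine similarity between two MS2 spectra
#'
#' Fragment pairs may match directly (|dmz| <= tol) or shifted by the
#' precursor mass difference (|dmz - (precB - precA)| <= tol), which lets
#' analogues differing by one modification still align. Among candidate
#' pairs a one-to-one matching is built greedily by descending score
#' contribution (the GNPS practice); intensities are square-root transformed
#' before the cosine by default.
#'
#' @param a,b `Spectrum` objects of the same polarity.
#' @param fragment_tol Fragment tolerance, Da.
#' @param intensity_transform `"sqrt"` or `"none"`.
#' @return List with `cosine` (in \[0, 1\]) and `n_matched`.
#' @export
modified_cosine <- function(a, b, fragment_tol = 0.02,
                            intensity_transform = c("sqrt", "none")) {
  intensity_transform <- match.arg(intensity_transform)
  if (!identical(a$polarity, b$polarity)) {
    stop("cannot compare spectra of opposite polarity", call. = FALSE)
  }
  wa <- if (intensity_transform == "sqrt") sqrt(a$intensity) else a$intensity
  wb <- if (intensity_transform == "sqrt") sqrt(b$intensity) else b$intensity
  na <- sqrt(sum(wa^2)); nb <- sqrt(sum(wb^2))
  if (na == 0 || nb == 0) return(list(cosine = 0, n_matched = 0L))
  shift <- b$precursor_mz - a$precursor_mz
  # candidate pairs: direct and precursor-shifted; a pair eligible both ways
  # is counted once (same contribution either way)
  cand_i <- integer(0); cand_j <- integer(0)
  for (i in seq_along(a$mz)) {
    direct <- abs(b$mz - a$mz[i]) <= fragment_tol
    shifted <- abs(b$mz - a$mz[i] - shift) <= fragment_tol
    js <- which(direct | shifted)
    cand_i <- c(cand_i, rep.int(i, length(js)))
    cand_j <- c(cand_j, js)
  }
  if (length(cand_i) == 0) return(list(cosine = 0, n_matched = 0L))
  score <- wa[cand_i] * wb[cand_j]
  o <- order(score, decreasing = TRUE)
  used_i <- logical(length(a$mz)); used_j <- logical(length(b$mz))
  total <- 0; nm <- 0L
  for (k in o) {
    i <- cand_i[k]; j <- cand_j[k]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE; used_j[j] <- TRUE
      total <- total + score[k]
      nm <- nm + 1L
    }
  }
  list(cosine = min(1, total / (na * nb)), n_matched = nm)
}

#' Build a molecular network from MS2-bearing features
#'
#' All-pairs modified-cosine scoring within each polarity; an edge is kept iff
#' cosine >= `min_cosine` and matched peaks >= `min_matched_peaks`. A
#' "cluster" is a connected component with at least two nodes.
#'
#' @param spectra List of `Spectrum` objects (one per feature).
#' @param params A [network_params()] object.
#' @return Object of class `MolecularNetwork`: list with `graph` (igraph),
#'   `params`, and accessors via [network_stats()].
#' @export
build_network <- function(spectra, params = network_params()) {
  stopifnot(length(spectra) >= 1)
  ids <- vapply(spectra, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate spectrum ids", call. = FALSE)
  n <- length(spectra)
  edges <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (!identical(spectra[[i]]$polarity, spectra[[j]]$polarity)) next
        m <- modified_cosine(spectra[[i]], spectra[[j]], params$fragment_tol,
                             params$intensity_transform)
        if (m$cosine >= params$min_cosine &&
            m$n_matched >= params$min_matched_peaks) {
          edges[[length(edges) + 1L]] <- data.frame(
            from = ids[[i]], to = ids[[j]], cosine = m$cosine,
            n_matched = m$n_matched)
        }
      }
    }
  }
  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), cosine = numeric(0),
               n_matched = integer(0))
  vdf <- data.frame(
    name = ids,
    mz = vapply(spectra, function(s) s$precursor_mz, numeric(1)),
    rt = vapply(spectra, function(s) if (is.null(s$rt) || is.na(s$rt)) NA_real_
                else s$rt, numeric(1)),
    polarity = vapply(spectra, function(s) s$polarity, character(1)),
    annotation = NA_character_,
    annotation_source = "none",
    class_hypothesis = NA_character_,
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  structure(list(graph = g, params = params, spectra = spectra),
            class = "MolecularNetwork")
}

#' @export
print.MolecularNetwork <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf(paste0("<MolecularNetwork> %d nodes (%d clustered, %d ",
                     "non-clustered), %d edges, %d clusters, %d annotated\n"),
              s$total_nodes, s$clustered_nodes, s$non_clustered_nodes,
              igraph::ecount(x$graph), s$clusters, s$annotated_nodes))
  invisible(x)
}

#' Network accounting
#'
#' Totals mirroring the workflow's reporting: total nodes, clustered nodes
#' (in components of size >= 2), non-clustered nodes, number of clusters,
#' annotated node count, and clusters containing at least one annotation.
#'
#' @param network A `MolecularNetwork`.
#' @return One-row data frame.
#' @export
network_stats <- function(network) {
  g <- network$graph
  comp <- igraph::components(g)
  sizes <- comp$csize[comp$membership]
  annotated <- !is.na(igraph::V(g)$annotation)
  cluster_ids <- which(comp$csize >= 2)
  ann_clusters <- length(unique(comp$membership[annotated & sizes >= 2]))
  data.frame(
    total_nodes = as.integer(igraph::vcount(g)),
    clustered_nodes = as.integer(sum(sizes >= 2)),
    non_clustered_nodes = as.integer(sum(sizes < 2)),
    clusters = as.integer(length(cluster_ids)),
    annotated_nodes = as.integer(sum(annotated)),
    annotated_clusters = as.integer(ann_clusters)
  )
}

#' Match a spectrum against a local spectral library
#'
#' Best modified-cosine hit with cosine >= `min_cosine` and matched peaks >=
#' `library_min_matched_peaks`. Library entries are `(record, spectrum)`
#' pairs; entries of opposite polarity are skipped.
#'
#' @param spectrum Query `Spectrum`.
#' @param library List of lists with elements `record` (one-row compound data
#'   frame or list with `name`, `class`) and `spectrum` (`Spectrum`).
#' @param params [network_params()].
#' @return List with `name`, `class`, `cosine`, `n_matched`, or `NULL` when
#'   nothing passes.
#' @export
library_match <- function(spectrum, library, params = network_params()) {
  best <- NULL
  for (entry in library) {
    if (!identical(entry$spectrum$polarity, spectrum$polarity)) next
    m <- modified_cosine(spectrum, entry$spectrum, params$fragment_tol,
                         params$intensity_transform)
    if (m$cosine >= params$min_cosine &&
        m$n_matched >= params$library_min_matched_peaks &&
        (is.null(best) || m$cosine > best$cosine)) {
      best <- list(name = entry$record$name, class = entry$record$class,
                   cosine = m$cosine, n_matched = m$n_matched,
                   annotation_source = "library")
    }
  }
  best
}

#' Annotate network nodes by library search
#'
#' Runs [library_match()] for every node and writes `annotation`,
#' `annotation_source` and `class_hypothesis` attributes for the hits.
#'
#' @param network A `MolecularNetwork`.
#' @inheritParams library_match
#' @return The annotated network.
#' @export
annotate_network <- function(network, library, params = network$params) {
  g <- network$graph
  for (v in seq_len(igraph::vcount(g))) {
    id <- igraph::V(g)$name[[v]]
    sp <- network$spectra[[which(vapply(network$spectra, function(s) s$id,
                                        character(1)) == id)]]
    hit <- library_match(sp, library, params)
    if (!is.null(hit)) {
      g <- igraph::set_vertex_attr(g, "annotation", v, hit$name)
      g <- igraph::set_vertex_attr(g, "annotation_source", v, "library")
      g <- igraph::set_vertex_attr(g, "class_hypothesis", v, hit$class)
    }
  }
  network$graph <- g
  network
}

#' Propagate class annotations within clusters
#'
#' Unannotated nodes in a cluster containing at least one annotated node
#' receive that cluster's class as a flagged hypothesis
#' (`annotation_source = "cluster-hypothesis"`). Conflicting annotated classes
#' in one cluster yield the hypothesis `"ambiguous"` with all candidates
#' listed. Library and reference-standard annotations are never overwritten.
#'
#' @param network A `MolecularNetwork` whose annotated nodes carry a
#'   `class_hypothesis`.
#' @return The network with propagated hypotheses.
#' @export
propagate_annotations <- function(network) {
  g <- network$graph
  comp <- igraph::components(g)
  for (cid in which(comp$csize >= 2)) {
    members <- which(comp$membership == cid)
    annotated <- members[!is.na(igraph::vertex_attr(g, "annotation", members))]
    if (length(annotated) == 0) next
    classes <- unique(stats::na.omit(
      igraph::vertex_attr(g, "class_hypothesis", annotated)))
    if (length(classes) == 0) next
    hyp <- if (length(classes) == 1) classes else
      paste0("ambiguous: ", paste(sort(classes), collapse = "|"))
    targets <- setdiff(members, annotated)
    for (v in targets) {
      g <- igraph::set_vertex_attr(g, "class_hypothesis", v, hyp)
      g <- igraph::set_vertex_attr(g, "annotation_source", v,
                                   "cluster-hypothesis")
    }
  }
  network$graph <- g
  network
}
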