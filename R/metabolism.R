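# In-vivo identification stage: XIC presence/absence calls of prototypes in
# dosed vs blank biosamples, biotransformation-chain metabolite prediction,
# candidate matching with fragment/class evidence, and metabolic-pathway
# assembly.

#' The biotransformation ledger
#'
#' The phase-I/II reactions used for metabolite prediction, as net elemental
#' deltas: methylation (+CH2), demethylation (-CH2), hydroxylation (+O),
#' dehydroxylation (-O), reduction (+2H), dehydrogenation (-2H), sulfation
#' (+SO3), glucuronidation (+C6H8O6), glucosylation (+C6H10O5), glucuronide
#' and glucoside hydrolysis (-C6H8O6 / -C6H10O5), and decarboxylation (-CO2).
#' `mass_delta` is signed and equals the monoisotopic mass of the formula
#' delta.
#'
#' @return Data frame with `name`, `formula`, `direction`, `mass_delta`.
#' @export
biotransformation_ledger <- function() {
  df <- data.frame(
    name = c("methylation", "demethylation", "hydroxylation",
             "dehydroxylation", "reduction", "dehydrogenation", "sulfation",
             "glucuronidation", "glucosylation", "glucuronide hydrolysis",
             "glucoside hydrolysis", "decarboxylation"),
    formula = c("CH2", "CH2", "O", "O", "H2", "H2", "SO3", "C6H8O6",
                "C6H10O5", "C6H8O6", "C6H10O5", "CO2"),
    direction = c("gain", "loss", "gain", "loss", "gain", "loss", "gain",
                  "gain", "gain", "loss", "loss", "loss"),
    stringsAsFactors = FALSE
  )
  df$mass_delta <- ifelse(df$direction == "gain", 1, -1) *
    vapply(df$formula, function(f) monoisotopic_mass(f), numeric(1))
  df
}

#' Parse a mass-shift chain string
#'
#' Chains use the "+/- group" naming scheme of the metabolite tables, e.g.
#' `"+CH2"`, `"+SO3+CH2"`, `"-CH2-O"`, `"+2O+2H"`, `"-CO2+SO3"`. A leading
#' multiplier repeats the group (`"+2O"` is two hydroxylations). A `CH3`
#' token is read as methylation (net +CH2), the standard net change. `"2H"`
#' means the H2 reduction delta, not two separate protons.
#'
#' @param text Chain string.
#' @return Data frame with `sign` (+1/-1) and `formula` per elementary step.
#' @export
parse_chain <- function(text) {
  text <- gsub("[[:space:]]", "", text)
  if (text == "") return(data.frame(sign = integer(0), formula = character(0)))
  m <- gregexpr("[+-][0-9]?[A-Za-z][A-Za-z0-9]*", text)[[1]]
  toks <- regmatches(text, gregexpr("[+-][0-9]?[A-Za-z][A-Za-z0-9]*", text))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("cannot parse transformation chain '", text, "'", call. = FALSE)
  }
  steps <- list()
  for (tok in toks) {
    sign <- if (substr(tok, 1, 1) == "+") 1L else -1L
    body <- substring(tok, 2)
    mult <- 1L
    # a leading digit is a multiplier except in "2H" (the reduction delta)
    if (grepl("^[0-9]", body) && body != "2H") {
      mult <- as.integer(substr(body, 1, 1))
      body <- substring(body, 2)
    }
    if (body == "CH3") body <- "CH2"  # methylation: net +CH2
    if (body == "2H") body <- "H2"
    for (k in seq_len(mult)) {
      steps[[length(steps) + 1L]] <- data.frame(sign = sign, formula = body,
                                                stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, steps)
}

#' Apply a transformation chain to a formula
#'
#' @param formula Parent formula (string or `elemental_formula`).
#' @param chain Chain string or parsed chain data frame.
#' @return The transformed `elemental_formula`; errors if any element count
#'   would go negative.
#' @export
apply_chain <- function(formula, chain) {
  if (is.character(chain)) chain <- parse_chain(chain)
  f <- as_elemental(formula)
  for (i in seq_len(nrow(chain))) {
    f <- if (chain$sign[[i]] > 0) formula_add(f, chain$formula[[i]])
    else formula_subtract(f, chain$formula[[i]])
  }
  f
}

# Render a chain of ledger-row indices in the "+/-" naming scheme,
# multiplicities merged, ledger order.
render_chain <- function(ledger, idx) {
  tab <- table(idx)
  ord <- as.integer(names(tab))
  parts <- vapply(seq_along(ord), function(k) {
    i <- ord[[k]]; n <- as.integer(tab[[k]])
    sign <- if (ledger$direction[[i]] == "gain") "+" else "-"
    body <- if (ledger$formula[[i]] == "H2") "2H" else ledger$formula[[i]]
    if (n > 1) {
      if (body == "2H") paste0(sign, n, "(2H)") else paste0(sign, n, body)
    } else paste0(sign, body)
  }, character(1))
  paste(parts, collapse = "")
}

#' Predict metabolites of a prototype by transformation chains
#'
#' Enumerates all multisets of ledger transformations up to `max_depth`
#' steps, applies them by formula arithmetic, prunes chains that drive an
#' element count negative or return to the parent formula, and deduplicates
#' by resulting formula (order-insensitive chains collapse; the first chain
#' in ledger order is kept as the name).
#'
#' @param formula Prototype elemental formula (string or parsed).
#' @param name Prototype display name used in rendered metabolite names.
#' @param ledger Biotransformation table ([biotransformation_ledger()]).
#' @param max_depth Maximum chain length (default 2).
#' @return Data frame: `name`, `chain`, `formula`, `neutral_mass`,
#'   `mz_pos` (`[M+H]+`), `mz_neg` (`[M-H]-`), `depth`.
#' @export
predict_metabolites <- function(formula, name = "M",
                                ledger = biotransformation_ledger(),
                                max_depth = 2) {
  parent <- as_elemental(formula)
  parent_str <- format_formula(parent)
  if (max_depth < 1) {
    return(data.frame(name = character(0), chain = character(0),
                      formula = character(0), neutral_mass = numeric(0),
                      mz_pos = numeric(0), mz_neg = numeric(0),
                      depth = integer(0)))
  }
  combos <- list()
  idx <- seq_len(nrow(ledger))
  grow <- function(prefix, start, depth) {
    for (i in idx[idx >= start]) {
      chain <- c(prefix, i)
      combos[[length(combos) + 1L]] <<- chain
      if (depth < max_depth) grow(chain, i, depth + 1)
    }
  }
  grow(integer(0), 1L, 1L)
  out <- list()
  seen <- character(0)
  for (chain in combos) {
    f <- parent
    ok <- TRUE
    for (i in chain) {
      f <- tryCatch(
        if (ledger$direction[[i]] == "gain") formula_add(f, ledger$formula[[i]])
        else formula_subtract(f, ledger$formula[[i]]),
        error = function(e) NULL)
      if (is.null(f)) { ok <- FALSE; break }
    }
    if (!ok) next
    fs <- format_formula(f)
    if (fs == parent_str || fs %in% seen) next
    seen <- c(seen, fs)
    mass <- monoisotopic_mass(f)
    out[[length(out) + 1L]] <- data.frame(
      name = paste0(name, render_chain(ledger, chain)),
      chain = render_chain(ledger, chain),
      formula = fs, neutral_mass = mass,
      mz_pos = adduct_mz(mass, "[M+H]+"),
      mz_neg = adduct_mz(mass, "[M-H]-"),
      depth = length(chain), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Predict metabolite candidates for a whole prototype library
#'
#' Runs [predict_metabolites()] for every library row and attaches the
#' prototype columns that [match_metabolites()] needs for its evidence
#' checks.
#'
#' @param library Compound table (`id`, `name`, `formula`, `class`,
#'   list-column `fragments` optional).
#' @param ledger Biotransformation table.
#' @param max_depth Maximum chain length.
#' @return Candidate data frame with `prototype_id`, `prototype_formula`,
#'   `prototype_class` and list-column `prototype_fragments`.
#' @export
predict_metabolite_candidates <- function(library,
                                          ledger = biotransformation_ledger(),
                                          max_depth = 2) {
  out <- lapply(seq_len(nrow(library)), function(i) {
    cand <- predict_metabolites(library$formula[[i]], library$name[[i]],
                                ledger, max_depth)
    if (is.null(cand) || nrow(cand) == 0) return(NULL)
    cand$prototype_id <- library$id[[i]]
    cand$prototype_formula <- library$formula[[i]]
    cand$prototype_class <- library$class[[i]]
    cand$prototype_fragments <- rep(
      if ("fragments" %in% names(library)) library$fragments[i]
      else list(numeric(0)), nrow(cand))
    cand
  })
  do.call(rbind, Filter(Negate(is.null), out))
}

#' Extracted ion chromatogram from an MS1 scan table
#'
#' @param scans Scan table (`scan`, `rt`, `mz`, `intensity`).
#' @param target_mz Target m/z (> 0).
#' @param ppm_tol Window half-width in ppm (default 5).
#' @param rt_window Optional `c(min, max)` rt restriction, minutes.
#' @return List with `trace` (data frame `rt`, `intensity` summed per scan),
#'   `apex_height` (0 for an empty trace) and `apex_rt` (`NA` when empty).
#' @export
extract_xic <- function(scans, target_mz, ppm_tol = 5, rt_window = NULL) {
  stopifnot(target_mz > 0)
  if (is.null(scans) || nrow(scans) == 0) {
    return(list(trace = data.frame(rt = numeric(0), intensity = numeric(0)),
                apex_height = 0, apex_rt = NA_real_))
  }
  sel <- abs(scans$mz - target_mz) <= target_mz * ppm_tol * 1e-6
  if (!is.null(rt_window)) {
    sel <- sel & scans$rt >= rt_window[[1]] & scans$rt <= rt_window[[2]]
  }
  sub <- scans[sel, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(list(trace = data.frame(rt = numeric(0), intensity = numeric(0)),
                apex_height = 0, apex_rt = NA_real_))
  }
  agg <- stats::aggregate(intensity ~ rt, data = sub, FUN = sum)
  agg <- agg[order(agg$rt), ]
  apex <- which.max(agg$intensity)
  list(trace = agg, apex_height = agg$intensity[[apex]],
       apex_rt = agg$rt[[apex]])
}

#' XIC presence/absence calls for library prototypes
#'
#' For each compound the theoretical m/z of its selected adduct is computed
#' from the formula and extracted from the dosed and blank runs. A compound
#' is called detected when the dosed apex reaches `min_height` and the blank
#' apex stays below `blank_fraction` of it.
#'
#' @param library Compound table (see [read_compound_table()]).
#' @param dosed_scans,blank_scans MS1 scan tables.
#' @param matrix Label recorded on the calls (e.g. `"plasma"`).
#' @param ppm_tol XIC window, ppm (default 5, the workflow's error envelope).
#' @param min_height Detection threshold on the dosed apex (default 7000).
#' @param blank_fraction Maximum blank apex as a fraction of the dosed apex.
#' @return Data frame of `PresenceCall` rows: `compound_id`, `matrix`,
#'   `detected`, `dosed_height`, `blank_height`, `target_mz`.
#' @export
call_prototypes <- function(library, dosed_scans, blank_scans,
                            matrix = "plasma", ppm_tol = 5,
                            min_height = 7000, blank_fraction = 0.05) {
  calls <- lapply(seq_len(nrow(library)), function(i) {
    target <- adduct_mz(monoisotopic_mass(library$formula[[i]]),
                        library$adduct[[i]])
    dosed <- extract_xic(dosed_scans, target, ppm_tol)
    blank <- extract_xic(blank_scans, target, ppm_tol)
    data.frame(
      compound_id = library$id[[i]], matrix = matrix,
      detected = dosed$apex_height >= min_height &&
        blank$apex_height < blank_fraction * dosed$apex_height,
      dosed_height = dosed$apex_height, blank_height = blank$apex_height,
      target_mz = target, stringsAsFactors = FALSE)
  })
  do.call(rbind, calls)
}

#' Match predicted metabolites against dosed-only features
#'
#' A candidate is matched when a dosed feature lies within `ppm_tol` of the
#' predicted adduct m/z (polarity taken from the feature) and no blank
#' feature does. With `require_evidence`, the feature's MS2 must additionally
#' share at least `min_shared_fragments` peaks with the prototype's fragments
#' shifted by 0 or by the chain mass shift, or pass the rule-engine class
#' check for the prototype's class.
#'
#' @param candidates Prediction table from [predict_metabolites()], plus the
#'   caller-supplied columns `prototype_id`, `prototype_class` and
#'   list-column `prototype_fragments`.
#' @param dosed_features,blank_features Feature tables with `mz` and optional
#'   `ms2` list-column (see [find_features()]).
#' @param ppm_tol Mass tolerance, ppm.
#' @param require_evidence Demand fragment or class evidence (default TRUE).
#' @param min_shared_fragments Minimum shared fragments (default 1).
#' @param fragment_tol Fragment matching tolerance, Da.
#' @param rulebase Rulebase for the class check.
#' @return `candidates` with `matched_feature`, `measured_mz`, `ppm`,
#'   `shared_fragments`, `evidence` columns; unmatched rows carry `NA`.
#' @export
match_metabolites <- function(candidates, dosed_features,
                              blank_features = NULL, ppm_tol = 5,
                              require_evidence = TRUE,
                              min_shared_fragments = 1L, fragment_tol = 0.02,
                              rulebase = default_rulebase()) {
  n <- nrow(candidates)
  candidates$matched_feature <- NA_character_
  candidates$measured_mz <- NA_real_
  candidates$ppm <- NA_real_
  candidates$shared_fragments <- NA_integer_
  candidates$evidence <- NA_character_
  if (n == 0 || is.null(dosed_features) || nrow(dosed_features) == 0) {
    return(candidates)
  }
  blank_mz <- if (!is.null(blank_features) && nrow(blank_features) > 0) {
    blank_features$mz
  } else numeric(0)
  for (i in seq_len(n)) {
    shift <- candidates$neutral_mass[[i]] -
      monoisotopic_mass(candidates$prototype_formula[[i]])
    for (j in seq_len(nrow(dosed_features))) {
      fmz <- dosed_features$mz[[j]]
      pol_mz <- c(candidates$mz_pos[[i]], candidates$mz_neg[[i]])
      hit <- which(abs(ppm_error(fmz, pol_mz)) <= ppm_tol)
      if (length(hit) == 0) next
      pred <- pol_mz[[hit[[1]]]]
      if (length(blank_mz) &&
          any(abs(ppm_error(blank_mz, pred)) <= ppm_tol)) next
      sp <- if ("ms2" %in% names(dosed_features)) dosed_features$ms2[[j]] else NULL
      shared <- 0L
      evidence <- "mass only"
      if (!is.null(sp)) {
        proto_fr <- candidates$prototype_fragments[[i]]
        targets <- c(proto_fr, proto_fr + shift)
        shared <- sum(vapply(sp$mz, function(p) {
          any(abs(p - targets) <= fragment_tol)
        }, logical(1)))
      }
      if (require_evidence) {
        if (shared >= min_shared_fragments) {
          evidence <- sprintf("%d shared fragment(s)", shared)
        } else if (!is.null(sp)) {
          chk <- validate_annotation(sp, candidates$prototype_class[[i]],
                                     rulebase)
          if (chk$accept && !is.null(chk$classification) &&
              chk$classification$score > 0) {
            evidence <- "class check"
          } else next
        } else next
      } else if (shared > 0) {
        evidence <- sprintf("%d shared fragment(s)", shared)
      }
      candidates$matched_feature[[i]] <-
        if ("feature_id" %in% names(dosed_features)) {
          dosed_features$feature_id[[j]]
        } else as.character(j)
      candidates$measured_mz[[i]] <- fmz
      candidates$ppm[[i]] <- ppm_error(fmz, pred)
      candidates$shared_fragments[[i]] <- shared
      candidates$evidence[[i]] <- evidence
      break
    }
  }
  candidates
}

#' Assemble a metabolic pathway graph
#'
#' Directed graph with prototype and metabolite nodes; each matched
#' metabolite gains an edge from its prototype labelled by the transformation
#' chain. When two detected prototypes differ by a glycoside hydrolysis
#' (e.g. a glucuronide and its aglycone), a hydrolysis edge connects them.
#' A metabolite matched from several prototypes keeps all incoming edges,
#' flagged ambiguous.
#'
#' @param prototypes Compound table of detected prototypes (`id`, `name`,
#'   `formula`).
#' @param matched Matched candidate table ([match_metabolites()] output with
#'   `prototype_id`; unmatched rows are ignored).
#' @return List with `graph` (igraph) and `edges` (edge-list data frame).
#' @export
assemble_pathways <- function(prototypes, matched) {
  matched <- matched[!is.na(matched$matched_feature), , drop = FALSE]
  nodes <- data.frame(name = prototypes$id,
                      label = prototypes$name,
                      kind = "prototype", stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      chain = character(0), ambiguous = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(matched) > 0) {
    met_ids <- paste0(matched$prototype_id, ":", matched$formula)
    dup_formula <- matched$formula %in%
      matched$formula[duplicated(matched$formula)]
    nodes <- rbind(nodes, data.frame(name = met_ids, label = matched$name,
                                     kind = "metabolite",
                                     stringsAsFactors = FALSE))
    edges <- data.frame(from = matched$prototype_id, to = met_ids,
                        chain = matched$chain, ambiguous = dup_formula,
                        stringsAsFactors = FALSE)
  }
  # hydrolysis edges between detected prototypes (glucuronide -> aglycone)
  for (delta in c("C6H8O6", "C6H10O5")) {
    for (i in seq_len(nrow(prototypes))) {
      fi <- tryCatch(formula_subtract(prototypes$formula[[i]], delta),
                     error = function(e) NULL)
      if (is.null(fi)) next
      target <- format_formula(fi)
      hits <- which(vapply(prototypes$formula, function(f)
        format_formula(parse_formula(f)) == target, logical(1)))
      for (j in hits) {
        edges <- rbind(edges, data.frame(
          from = prototypes$id[[i]], to = prototypes$id[[j]],
          chain = paste0("-", delta, " (hydrolysis)"), ambiguous = FALSE,
          stringsAsFactors = FALSE))
      }
    }
  }
  nodes <- nodes[!duplicated(nodes$name), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  list(graph = g, edges = edges)
}
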