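# Rule-consistent synthetic data: MS2 spectra generated from class-specific
# fragmentation templates (the worked fragmentation cascades of the main
# structure classes), and full multi-sample acquisitions (extract, blank and
# dosed plasma/cerebrum) with planted metabolites and decoys plus a serialized
# ground truth, so every pipeline stage is testable without any download.

# Exact neutral-fragment masses used by the templates.
.LOSS <- list(
  H2O = 18.010565, CO = 27.994915, CH3 = 15.023475, CH2 = 14.015650,
  CH2O = 30.010565, O = 15.994915, CO2 = 43.989829, GlcA = 176.032088,
  Glc = 162.052823, MeOH = 32.026215, Acyl = 238.084124
)

#' Simulation configuration
#'
#' Defaults mirror the study conditions the pipeline is designed for:
#' triangular chromatographic peaks of 0.3 min at 0.05-min scan spacing,
#' base peak height 1e5 counts, m/z jitter well inside the 5 ppm error
#' envelope, and MS1 noise below the 1000-count detection threshold so that
#' noise never creates features (raise `ms1_noise_intensity` deliberately in
#' interference tests).
#'
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @param noise_peaks Poisson mean of extra MS2 noise peaks per spectrum.
#' @param noise_intensity MS2 noise intensity range (counts).
#' @param mz_jitter_ppm Gaussian m/z jitter sd in ppm (clamped at 5 ppm).
#' @param rt_jitter_sd Retention-time jitter sd, minutes.
#' @param scan_interval MS1 scan spacing, minutes.
#' @param peak_width Chromatographic peak base width, minutes.
#' @param base_height Apex height of planted features, counts.
#' @param ms1_noise_peaks Poisson mean of MS1 noise peaks per scan.
#' @param ms1_noise_intensity MS1 noise intensity range (counts).
#' @param mz_range Acquisition m/z range.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, noise_peaks = 2,
                              noise_intensity = c(100, 800),
                              mz_jitter_ppm = 1.5, rt_jitter_sd = 0.02,
                              scan_interval = 0.05, peak_width = 0.3,
                              base_height = 1e5, ms1_noise_peaks = 3,
                              ms1_noise_intensity = c(100, 900),
                              mz_range = c(100, 1250)) {
  stopifnot(mz_jitter_ppm <= 5)
  structure(list(seed = as.integer(seed), noise_peaks = noise_peaks,
                 noise_intensity = noise_intensity,
                 mz_jitter_ppm = mz_jitter_ppm, rt_jitter_sd = rt_jitter_sd,
                 scan_interval = scan_interval, peak_width = peak_width,
                 base_height = base_height, ms1_noise_peaks = ms1_noise_peaks,
                 ms1_noise_intensity = ms1_noise_intensity,
                 mz_range = mz_range),
            class = "simulation_config")
}

# deterministic small integer from a string (for per-compound sub-seeds)
str_seed <- function(s) sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 100000L

# Class fragmentation templates: cumulative neutral-loss cascades applied to
# the precursor, plus fixed diagnostic ions. Mirrors the worked pathways:
# glucuronide/glycoside cleavage + H2O/CO cascade + RDA ion for flavonoids,
# the CH2 ladder for sesquiterpenes, ring-C cleavage ions for indole
# alkaloids, and so on.
class_template <- function(class, polarity, formula) {
  L <- .LOSS
  has_glca <- !is.null(tryCatch(formula_subtract(formula, "C6H8O6"),
                                error = function(e) NULL))
  has_glc <- !is.null(tryCatch(formula_subtract(formula, "C6H10O5"),
                               error = function(e) NULL))
  mass <- monoisotopic_mass(formula)
  if (class == "flavonoid" && polarity == "negative") {
    if (has_glca) {
      return(list(losses = c(L$GlcA, L$GlcA + L$CH3, L$GlcA + L$H2O,
                             L$GlcA + L$H2O + L$CO, L$GlcA + L$CH2O,
                             L$GlcA + L$O),
                  diag = c(169.0661)))
    }
    return(list(losses = c(L$CH3, L$H2O, L$H2O + L$CO, L$CH2O, L$O),
                diag = c(169.0661)))
  }
  if (class == "flavonoid") {  # positive mode
    return(list(losses = c(L$H2O, L$H2O + L$CO, L$CH3, L$CH2O, L$O, L$CO2),
                diag = numeric(0)))
  }
  if (class == "terpenoid" && polarity == "negative") {
    return(list(losses = c(L$CH2O, L$CH2O + L$O, L$CH2O + L$O + L$Glc,
                           L$CH2O + L$O + L$Glc + L$H2O),
                diag = c(179.0565, 89.0249)))
  }
  if (class == "terpenoid") {
    if (mass >= 400) {  # triterpene-style RDA diagnostics
      return(list(losses = c(L$H2O, L$H2O + L$CO2, 2 * L$H2O + L$CO2),
                  diag = c(249.1352, 203.1791, 191.1795)))
    }
    return(list(losses = (1:7) * L$CH2, diag = numeric(0)))  # CH2 ladder
  }
  if (class == "phenylpropanoid") {
    losses <- c(L$CH3, L$CH2O, 2 * L$CH3, L$H2O, L$CO2, 2 * L$CH2O)
    if (has_glc) losses <- c(losses, L$Glc)
    return(list(losses = losses, diag = numeric(0)))
  }
  if (class == "alkaloid") {
    return(list(losses = c(L$MeOH, 116.0473, L$MeOH + L$CO),
                diag = c(170.0966, 160.0757, 144.0851, 130.0655)))
  }
  if (class == "anthraquinone") {
    losses <- c(L$CH3, 2 * L$CH3, 2 * L$CH3 + L$CO)
    if (has_glc) losses <- c(losses, L$Glc, L$Glc + L$O, L$Glc + L$O + L$CH2)
    else losses <- c(losses, L$O, L$O + L$CH2, L$CO)
    return(list(losses = losses, diag = numeric(0)))
  }
  if (class == "phenylethanoid glycoside") {
    return(list(losses = c(L$Glc, L$Glc + L$H2O, 2 * L$Glc),
                diag = c(179.0351, 135.0452, 161.0245)))
  }
  if (class == "oligosaccharide") {
    return(list(losses = c(L$Acyl, L$Acyl + L$O, L$Acyl + L$O + L$CH2O,
                           L$Acyl + L$O + 2 * L$CH2O, L$H2O, L$Acyl + L$CH2),
                diag = numeric(0)))
  }
  if (class == "phenolic acid" && polarity == "negative") {
    return(list(losses = c(L$CO2, L$CO2 + L$H2O, L$H2O, L$O, L$CO,
                           L$CO2 + L$CO),
                diag = numeric(0)))
  }
  if (class %in% c("phenolic acid", "xanthone", "naphthopyrone", "phthalein",
                   "aromatic aldehyde", "diarylheptanoid")) {
    return(list(losses = c(L$H2O, L$H2O + L$CO, L$CH3, L$CH2O, L$CO2,
                           L$H2O + 2 * L$CO),
                diag = numeric(0)))
  }
  if (class == "organic acid") {
    return(list(losses = c(L$CO2, L$H2O, L$CO2 + L$H2O, L$O, L$CO,
                           L$CO2 + L$CO),
                diag = numeric(0)))
  }
  stop("no fragmentation template for class '", class, "'; available: ",
       paste(compound_classes(), collapse = ", "), call. = FALSE)
}

#' Simulate a rule-consistent MS2 spectrum for a compound
#'
#' The precursor sits at the compound's adduct m/z (plus ppm jitter);
#' fragments follow the compound class's template cascade and diagnostic
#' ions, with descending fixed intensity ranks (base peak 1e5) and
#' Poisson-count uniform noise peaks below the fragments.
#'
#' @param compound One-row compound record (needs `id`, `formula`, `adduct`,
#'   `class`, `rt`).
#' @param config [simulation_config()].
#' @param salt Extra string mixed into the per-compound sub-seed so repeated
#'   plants of one compound differ reproducibly.
#' @return A `Spectrum`.
#' @export
simulate_spectrum <- function(compound, config = simulation_config(),
                              salt = "") {
  polarity <- adduct_polarity(compound$adduct)
  set.seed(config$seed + str_seed(paste0(compound$id, salt)))
  prec_theo <- adduct_mz(monoisotopic_mass(compound$formula), compound$adduct)
  tmpl <- class_template(compound$class, polarity, compound$formula)
  frag <- c(prec_theo - tmpl$losses, tmpl$diag)
  frag <- frag[frag > 80 & frag < min(1250, prec_theo - 0.5)]
  frag <- sort(unique(round(frag, 6)), decreasing = TRUE)
  ints <- config$base_height * 0.9^(seq_along(frag))
  jitter <- function(mz) {
    d <- stats::rnorm(length(mz), 0, config$mz_jitter_ppm)
    d <- pmin(pmax(d, -5), 5)
    mz * (1 + d * 1e-6)
  }
  n_noise <- stats::rpois(1, config$noise_peaks)
  if (n_noise > 0) {
    nmz <- stats::runif(n_noise, 80, 1250)
    nint <- stats::runif(n_noise, config$noise_intensity[[1]],
                         config$noise_intensity[[2]])
    frag <- c(jitter(frag), nmz)
    ints <- c(ints, nint)
  } else {
    frag <- jitter(frag)
  }
  new_spectrum(id = compound$id, precursor_mz = jitter(prec_theo),
               polarity = polarity, rt = compound$rt, mz = frag,
               intensity = ints, precursor_intensity = config$base_height)
}

# triangular chromatographic profile: fractions of apex height over the peak
.PEAK_PROFILE <- c(0.05, 0.35, 0.7, 1, 0.7, 0.35, 0.05)

#' Simulate a multi-sample acquisition
#'
#' Emits MS1 scan tables and MS2 spectra for an extract sample, blank and
#' dosed plasma, and blank and dosed cerebrum. Every planted compound yields
#' a triangular 7-scan MS1 peak above all feature-finder thresholds plus one
#' MS2 scan. Metabolites (prototype + transformation chain) appear only in
#' the dosed matrices named for them; decoys sit at metabolite m/z values
#' with scrambled fragments; blanks contain only noise.
#'
#' @param library Compound table; rows referenced by the id arguments.
#' @param config [simulation_config()].
#' @param extract_ids Compound ids planted in the extract (default: all).
#' @param plasma_ids,cerebrum_ids Ids planted in the dosed matrices.
#' @param metabolites Data frame `prototype_id`, `chain` (e.g. `"+CH2"`),
#'   `matrix` (`"plasma"` / `"cerebrum"`), or `NULL`.
#' @param decoys Number of decoy features planted in dosed plasma: each sits
#'   at the predicted m/z of a plasma prototype transformed by a chain from
#'   `decoy_chains` (chains that are *not* planted as real metabolites) but
#'   carries scrambled fragments, so only evidence filtering can reject it.
#' @param decoy_chains Chains used for decoy masses.
#' @return List: `samples` (named list of `list(ms1, ms2)`), `ground_truth`
#'   (data frame), `config`.
#' @export
simulate_acquisition <- function(library, config = simulation_config(),
                                 extract_ids = library$id,
                                 plasma_ids = character(0),
                                 cerebrum_ids = character(0),
                                 metabolites = NULL, decoys = 0L,
                                 decoy_chains = c("+SO3", "+C6H10O5")) {
  plan <- list(extract = extract_ids, plasma_blank = character(0),
               plasma_dosed = plasma_ids, cerebrum_blank = character(0),
               cerebrum_dosed = cerebrum_ids)
  truth <- list()
  samples <- list()
  # expand metabolite plants into synthetic compound rows
  met_rows <- NULL
  if (!is.null(metabolites) && nrow(metabolites) > 0) {
    met_rows <- do.call(rbind, lapply(seq_len(nrow(metabolites)), function(k) {
      p <- library[library$id == metabolites$prototype_id[[k]], ]
      stopifnot(nrow(p) == 1)
      f <- apply_chain(p$formula[[1]], metabolites$chain[[k]])
      adduct <- if (adduct_polarity(p$adduct[[1]]) == "positive") "[M+H]+"
      else "[M-H]-"
      data.frame(id = paste0(p$id[[1]], metabolites$chain[[k]]),
                 rt = p$rt[[1]] + 0.6 * k, name = paste0(p$name[[1]],
                                                         metabolites$chain[[k]]),
                 formula = format_formula(f), adduct = adduct,
                 class = p$class[[1]], prototype_id = p$id[[1]],
                 chain = metabolites$chain[[k]],
                 matrix = metabolites$matrix[[k]], stringsAsFactors = FALSE)
    }))
  }
  for (matrix in names(plan)) {
    set.seed(config$seed + str_seed(matrix))
    ids <- plan[[matrix]]
    rows <- library[library$id %in% ids, , drop = FALSE]
    ms2 <- list()
    peaks <- list()
    add_compound <- function(row, kind, prototype_id = NA, chain = NA) {
      rt0 <- row$rt + stats::rnorm(1, 0, config$rt_jitter_sd)
      prec <- adduct_mz(monoisotopic_mass(row$formula), row$adduct)
      rts <- rt0 + (seq_along(.PEAK_PROFILE) -
                      (length(.PEAK_PROFILE) + 1) / 2) * config$scan_interval
      hts <- config$base_height * .PEAK_PROFILE
      mzj <- prec * (1 + pmin(pmax(stats::rnorm(length(rts), 0,
                                                config$mz_jitter_ppm),
                                   -5), 5) * 1e-6)
      peaks[[length(peaks) + 1L]] <<- data.frame(rt = rts, mz = mzj,
                                                 intensity = hts)
      sp <- simulate_spectrum(row, config, salt = matrix)
      sp$rt <- rt0
      ms2[[length(ms2) + 1L]] <<- sp
      truth[[length(truth) + 1L]] <<- data.frame(
        matrix = matrix, id = row$id, kind = kind, class = row$class,
        mz = prec, rt = rt0, prototype_id = prototype_id, chain = chain,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(rows))) add_compound(rows[i, ], "prototype")
    if (!is.null(met_rows)) {
      mm <- met_rows[paste0(met_rows$matrix, "_dosed") == matrix, ,
                     drop = FALSE]
      for (i in seq_len(nrow(mm))) {
        add_compound(mm[i, ], "metabolite", mm$prototype_id[[i]],
                     mm$chain[[i]])
      }
    }
    if (matrix == "plasma_dosed" && decoys > 0 && nrow(rows) > 0) {
      for (d in seq_len(decoys)) {
        proto <- rows[((d - 1) %% nrow(rows)) + 1, ]
        chain <- decoy_chains[((d - 1) %% length(decoy_chains)) + 1]
        f <- tryCatch(apply_chain(proto$formula[[1]], chain),
                      error = function(e) NULL)
        if (is.null(f)) next
        adduct <- if (adduct_polarity(proto$adduct[[1]]) == "positive")
          "[M+H]+" else "[M-H]-"
        prec <- adduct_mz(monoisotopic_mass(f), adduct)
        rt <- proto$rt[[1]] + 3.5 + 0.7 * d
        peaks_rt <- rt + (seq_along(.PEAK_PROFILE) -
                            (length(.PEAK_PROFILE) + 1) / 2) *
          config$scan_interval
        peaks[[length(peaks) + 1L]] <- data.frame(
          rt = peaks_rt, mz = prec,
          intensity = config$base_height * .PEAK_PROFILE)
        scram <- sort(stats::runif(8, 80, min(1250, prec - 20)))
        ms2[[length(ms2) + 1L]] <- new_spectrum(
          id = paste0("decoy", d), precursor_mz = prec,
          polarity = adduct_polarity(adduct), rt = rt, mz = scram,
          intensity = config$base_height * 0.9^(1:8),
          precursor_intensity = config$base_height)
        truth[[length(truth) + 1L]] <- data.frame(
          matrix = matrix, id = paste0("decoy", d), kind = "decoy",
          class = proto$class[[1]], mz = prec, rt = rt,
          prototype_id = proto$id[[1]], chain = chain,
          stringsAsFactors = FALSE)
      }
    }
    # MS1 noise floor, below the detection threshold by default
    rt_max <- if (length(peaks)) max(vapply(peaks, function(p) max(p$rt),
                                            numeric(1))) + 1 else 5
    grid <- seq(0.1, rt_max, by = config$scan_interval)
    noise <- lapply(grid, function(rt) {
      k <- stats::rpois(1, config$ms1_noise_peaks)
      if (k == 0) return(NULL)
      data.frame(rt = rt, mz = stats::runif(k, config$mz_range[[1]],
                                            config$mz_range[[2]]),
                 intensity = stats::runif(k, config$ms1_noise_intensity[[1]],
                                          config$ms1_noise_intensity[[2]]))
    })
    scans <- do.call(rbind, c(peaks, Filter(Negate(is.null), noise)))
    if (is.null(scans)) {
      scans <- data.frame(rt = numeric(0), mz = numeric(0),
                          intensity = numeric(0))
    }
    # snap rts to a shared grid so co-eluting peaks share scans
    scans$rt <- round(scans$rt / config$scan_interval) * config$scan_interval
    scans$scan <- as.integer(factor(scans$rt))
    scans <- scans[order(scans$rt, scans$mz),
                   c("scan", "rt", "mz", "intensity")]
    samples[[matrix]] <- list(ms1 = scans, ms2 = ms2)
  }
  gt <- if (length(truth)) do.call(rbind, truth) else NULL
  list(samples = samples, ground_truth = gt, config = config)
}

#' Packaged study tables
#'
#' Returns the packaged transcriptions of the absorbed-prototype table (50
#' rows) and the plasma-metabolite table (60 rows), after an integrity check
#' on row counts and required columns.
#'
#' @return List with `table1` and `table2` data frames.
#' @export
table_fixtures <- function() {
  t1 <- table1_prototypes()
  t2 <- table2_metabolites()
  if (nrow(t1) != 50 || nrow(t2) != 60 ||
      !all(c("parent", "chain") %in% names(t2))) {
    stop("packaged table fixtures failed the integrity check", call. = FALSE)
  }
  list(table1 = t1, table2 = t2)
}

#' Write a simulated acquisition to a run directory
#'
#' Serializes each sample's MS1 scan table as CSV and MS2 spectra as MGF,
#' the ground truth as CSV, and the configuration as YAML.
#'
#' @param sim Output of [simulate_acquisition()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_acquisition <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(sim$samples)) {
    write_scans_csv(sim$samples[[m]]$ms1, file.path(dir, paste0(m, "_ms1.csv")))
    write_mgf(sim$samples[[m]]$ms2, file.path(dir, paste0(m, "_ms2.mgf")))
  }
  if (!is.null(sim$ground_truth)) {
    utils::write.csv(sim$ground_truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  yaml::write_yaml(unclass(sim$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
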