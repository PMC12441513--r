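# Readers/writers for the artifacts the pipeline touches: MGF spectra,
# centroided mzML (via mzR), scan/feature/compound/rule CSV tables and
# GraphML network export. Retention time is minutes everywhere internally.

.CLASS_VOCAB <- c(
  "flavonoid", "terpenoid", "phenylpropanoid", "alkaloid", "anthraquinone",
  "phenylethanoid glycoside", "phenolic acid", "xanthone", "oligosaccharide",
  "phthalein", "naphthopyrone", "organic acid", "aromatic aldehyde",
  "diarylheptanoid"
)

#' The closed compound-class vocabulary
#'
#' The fourteen structure classes used for library records, fragmentation
#' rules and classification results.
#' @return Character vector of class labels.
#' @export
compound_classes <- function() .CLASS_VOCAB

#' Construct an MS2 spectrum
#'
#' @param id Feature/spectrum identifier.
#' @param precursor_mz Precursor m/z (> 0).
#' @param polarity `"positive"` or `"negative"`.
#' @param rt Retention time in minutes.
#' @param mz,intensity Fragment peak vectors (equal length; intensities >= 0).
#' @param precursor_charge +1 or -1; defaults by polarity.
#' @param precursor_intensity Optional precursor ion intensity.
#' @return An object of class `Spectrum`: peaks stored sorted by m/z.
#' @export
new_spectrum <- function(id, precursor_mz, polarity, rt, mz, intensity,
                         precursor_charge = NULL, precursor_intensity = NA_real_) {
  stopifnot(length(mz) == length(intensity))
  polarity <- match.arg(polarity, c("positive", "negative"))
  if (is.null(precursor_charge)) {
    precursor_charge <- if (polarity == "positive") 1L else -1L
  }
  if (!is.finite(precursor_mz) || precursor_mz <= 0) {
    stop("precursor_mz must be a positive number", call. = FALSE)
  }
  if (length(mz) && (any(!is.finite(mz)) || any(!is.finite(intensity)) ||
                     any(intensity < 0))) {
    stop("peaks must be finite with non-negative intensities", call. = FALSE)
  }
  o <- order(mz)
  structure(
    list(id = as.character(id), precursor_mz = precursor_mz,
         precursor_charge = as.integer(precursor_charge), polarity = polarity,
         rt = rt, mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
         precursor_intensity = precursor_intensity),
    class = "Spectrum"
  )
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("<Spectrum %s> precursor %.4f (%s), rt %.2f min, %d peaks\n",
              x$id, x$precursor_mz, x$polarity, x$rt, length(x$mz)))
  invisible(x)
}

#' Read an MGF file of MS2 spectra
#'
#' Accepts the usual BEGIN IONS / END IONS dialect with `PEPMASS`, `CHARGE`
#' and either `RTINSECONDS` or `RTINMINUTES`. `TITLE` is used as the spectrum
#' id; a missing charge defaults to +1/-1 from the `POLARITY`/charge context
#' (with a warning). Blocks without `PEPMASS` are rejected with a warning.
#'
#' @param path MGF file path.
#' @return List of [new_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (line == "BEGIN IONS") {
      j <- i + 1L
      hdr <- character(0); mz <- numeric(0); int <- numeric(0)
      while (j <= n && trimws(lines[[j]]) != "END IONS") {
        l <- trimws(lines[[j]])
        if (l != "") {
          if (grepl("^[A-Za-z]", l)) {
            hdr <- c(hdr, l)
          } else {
            parts <- strsplit(l, "[ \t]+")[[1]]
            if (length(parts) < 2 || anyNA(suppressWarnings(as.numeric(parts[1:2])))) {
              stop("malformed MGF peak line at line ", j, ": '", l, "'",
                   call. = FALSE)
            }
            mz <- c(mz, as.numeric(parts[[1]]))
            int <- c(int, as.numeric(parts[[2]]))
          }
        }
        j <- j + 1L
      }
      if (j > n) stop("unterminated BEGIN IONS block starting at line ", i,
                      call. = FALSE)
      keys <- toupper(sub("=.*", "", hdr))
      vals <- sub("^[^=]*=", "", hdr)
      get <- function(k) if (k %in% keys) vals[[match(k, keys)]] else NA_character_
      pep <- get("PEPMASS")
      if (is.na(pep)) {
        warning("MGF block ending at line ", j, " has no PEPMASS; skipped")
      } else {
        pp <- as.numeric(strsplit(trimws(pep), "[ \t]+")[[1]])
        rt <- if (!is.na(get("RTINMINUTES"))) {
          as.numeric(get("RTINMINUTES"))
        } else if (!is.na(get("RTINSECONDS"))) {
          as.numeric(get("RTINSECONDS")) / 60
        } else NA_real_
        ch_raw <- get("CHARGE")
        if (is.na(ch_raw)) {
          charge <- 1L
          warning("MGF block ending at line ", j,
                  " has no CHARGE; defaulting to +1")
        } else {
          sign <- if (grepl("-", ch_raw)) -1L else 1L
          charge <- sign * as.integer(gsub("[^0-9]", "", ch_raw))
        }
        id <- get("TITLE")
        if (is.na(id)) id <- paste0("spectrum_", length(spectra) + 1L)
        spectra[[length(spectra) + 1L]] <- new_spectrum(
          id = id, precursor_mz = pp[[1]],
          polarity = if (charge < 0) "negative" else "positive",
          rt = rt, mz = mz, intensity = int, precursor_charge = charge,
          precursor_intensity = if (length(pp) > 1) pp[[2]] else NA_real_
        )
      }
      i <- j + 1L
    } else {
      if (line != "" && !grepl("^#", line) && i == 1L && !grepl("^BEGIN", line)) {
        # leading junk tolerated (some exporters write comments)
      }
      i <- i + 1L
    }
  }
  spectra
}

#' Write spectra to MGF
#'
#' Inverse of [read_mgf()]: `read_mgf(write_mgf(s, path))` preserves id,
#' precursor m/z, charge, rt and peaks to 6 decimal places.
#'
#' @param spectra List of `Spectrum` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d%s", abs(s$precursor_charge),
                       if (s$precursor_charge < 0) "-" else "+"), con)
    if (!is.na(s$rt)) writeLines(sprintf("RTINMINUTES=%.6f", s$rt), con)
    if (length(s$mz)) {
      writeLines(sprintf("%.6f %.6f", s$mz, s$intensity), con)
    }
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read centroided mzML
#'
#' Thin wrapper over `mzR` (must be installed). MS2 scans are returned as
#' `Spectrum` objects; MS1 scans as a long scan table suitable for
#' [build_chromatograms()]. Profile-mode files are rejected: peak picking is a
#' precondition of the workflow, not reimplemented here.
#'
#' @param path mzML file path.
#' @return List with `ms1` (data frame `scan`, `rt`, `mz`, `intensity`) and
#'   `ms2` (list of `Spectrum`).
#' @export
read_mzml_centroided <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package", call. = FALSE)
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hd <- mzR::header(handle)
  if ("centroided" %in% names(hd) && any(!is.na(hd$centroided) & !hd$centroided)) {
    stop("profile-mode spectra detected; only centroided mzML is supported",
         call. = FALSE)
  }
  ms1 <- NULL
  ms2 <- list()
  ms1_rows <- list()
  for (k in seq_len(nrow(hd))) {
    rt <- hd$retentionTime[[k]] / 60  # mzR reports seconds
    if (is.na(rt)) {
      warning("scan ", hd$seqNum[[k]], " has no retention time; skipped")
      next
    }
    pk <- mzR::peaks(handle, k)
    if (hd$msLevel[[k]] == 1L) {
      if (nrow(pk)) {
        ms1_rows[[length(ms1_rows) + 1L]] <- data.frame(
          scan = hd$seqNum[[k]], rt = rt, mz = pk[, 1], intensity = pk[, 2])
      }
    } else if (hd$msLevel[[k]] == 2L) {
      pol <- if (!is.null(hd$polarity) && !is.na(hd$polarity[[k]]) &&
                 hd$polarity[[k]] < 0) "negative" else "positive"
      ms2[[length(ms2) + 1L]] <- new_spectrum(
        id = paste0("scan_", hd$seqNum[[k]]),
        precursor_mz = hd$precursorMZ[[k]], polarity = pol, rt = rt,
        mz = pk[, 1], intensity = pk[, 2],
        precursor_intensity = hd$precursorIntensity[[k]])
    }
  }
  ms1 <- if (length(ms1_rows)) do.call(rbind, ms1_rows) else
    data.frame(scan = integer(0), rt = numeric(0), mz = numeric(0),
               intensity = numeric(0))
  list(ms1 = ms1, ms2 = ms2)
}

#' Read/write an MS1 scan table CSV
#'
#' The plain-text stand-in for centroided MS1 data used by the synthetic
#' generator: long format with columns `scan`, `rt` (minutes), `mz`,
#' `intensity`.
#'
#' @param path CSV path.
#' @return Data frame of scans sorted by rt then mz.
#' @export
read_scans_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan", "rt", "mz", "intensity")
  if (!all(need %in% names(df))) {
    stop("scan table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df[order(df$rt, df$mz), need]
}

#' @rdname read_scans_csv
#' @param scans Scan data frame.
#' @export
write_scans_csv <- function(scans, path) {
  utils::write.csv(scans, path, row.names = FALSE)
  invisible(path)
}

#' Read a compound library table
#'
#' CSV with columns `id`, `rt`, `name`, `formula`, `adduct`,
#' `theoretical_mz`, `measured_mz`, `error_ppm`, `fragments`
#' (semicolon-separated m/z), `class`, and optional `plasma` / `cerebrum`
#' (+/- flags) and `parent` / `chain` (for metabolite tables). Formulas are
#' validated by [parse_formula()] and class labels against
#' [compound_classes()].
#'
#' @param path CSV path.
#' @return Data frame with list-column `fragments` and logical
#'   `in_plasma` / `in_cerebrum` where flags are present.
#' @export
read_compound_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "name", "formula", "adduct", "class")
  if (!all(need %in% names(df))) {
    stop("compound table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$class), .CLASS_VOCAB)
  if (length(bad)) {
    stop("unknown compound class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (f in df$formula) parse_formula(f)  # validation
  df$adduct <- normalize_adduct_name(df$adduct)
  invisible(lapply(df$adduct, adduct_polarity))  # validation
  df$fragments <- lapply(df$fragments, function(x) {
    if (is.na(x) || x == "") numeric(0) else as.numeric(strsplit(x, ";")[[1]])
  })
  frag_ok <- vapply(df$fragments, function(v) all(v > 80 & v < 1250), logical(1))
  if (!all(frag_ok)) {
    stop("MS2 fragments outside the acquisition range (80, 1250) in row(s): ",
         paste(df$id[!frag_ok], collapse = ", "), call. = FALSE)
  }
  if ("plasma" %in% names(df)) df$in_plasma <- trimws(df$plasma) == "+"
  if ("cerebrum" %in% names(df)) df$in_cerebrum <- trimws(df$cerebrum) == "+"
  df
}

#' Packaged compound tables
#'
#' `table1_prototypes()`: the 50 absorbed prototype constituents (plasma /
#' cerebrum presence flags). `table2_metabolites()`: the 60 plasma metabolites
#' with parent compound and canonical biotransformation chain.
#' `extract_compounds()`: additional worked-example extract constituents used
#' by the synthetic generator.
#'
#' @return Data frames (see [read_compound_table()]).
#' @export
table1_prototypes <- function() {
  read_compound_table(system.file("extdata", "table1_prototypes.csv",
                                  package = "herbnet", mustWork = TRUE))
}

#' @rdname table1_prototypes
#' @export
table2_metabolites <- function() {
  read_compound_table(system.file("extdata", "table2_metabolites.csv",
                                  package = "herbnet", mustWork = TRUE))
}

#' @rdname table1_prototypes
#' @export
extract_compounds <- function() {
  read_compound_table(system.file("extdata", "extract_compounds.csv",
                                  package = "herbnet", mustWork = TRUE))
}

#' Read a fragmentation rulebase CSV
#'
#' Columns: `rule_id`, `class`, `polarity`, `kind`
#' (`diagnostic_ion` / `neutral_loss` / `serial_loss`), `value` (m/z for
#' diagnostics, Da for losses), `series_count`, `tolerance`, `weight`.
#'
#' @param path CSV path.
#' @return Validated rulebase data frame.
#' @export
read_rulebase <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_rulebase(df)
}

validate_rulebase <- function(df) {
  need <- c("rule_id", "class", "polarity", "kind", "value", "series_count",
            "tolerance", "weight")
  if (!all(need %in% names(df))) {
    stop("rulebase must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(df$kind %in% c("diagnostic_ion", "neutral_loss", "serial_loss")),
            all(df$polarity %in% c("positive", "negative")),
            all(df$value > 0), all(df$weight >= 0),
            all(df$series_count[df$kind == "serial_loss"] >= 2))
  bad <- setdiff(unique(df$class), .CLASS_VOCAB)
  if (length(bad)) {
    stop("unknown class label(s) in rulebase: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Export a molecular network to GraphML
#'
#' Nodes carry feature id, precursor m/z, rt and annotation; edges carry the
#' modified-cosine score and matched-peak count. The file reloads in igraph /
#' Cytoscape with components preserved.
#'
#' @param network A `MolecularNetwork` (see [build_network()]) or igraph object.
#' @param path Output path.
#' @export
write_graphml <- function(network, path) {
  g <- if (inherits(network, "MolecularNetwork")) network$graph else network
  stopifnot(inherits(g, "igraph"))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
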