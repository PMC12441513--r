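# Simplified reimplementation of the MZmine processing chain: chromatogram
# building from centroided MS1 scans, local-minimum peak resolving, 13C
# isotope filtering, cross-sample join alignment and the MS2-bearing-features
# filter. Parameter defaults are the published workflow settings.

.C13_SPACING <- 1.00336  # 13C - 12C mass difference, Da

#' Feature-finder parameters
#'
#' Defaults reproduce the published processing chain: MS1/MS2 noise levels
#' 1000/100 counts, chromatograms of at least 5 consecutive scans reaching
#' 3000 counts, minimum absolute feature height 7000, m/z tolerance
#' 0.005 Da or 10 ppm (whichever is larger), chromatographic threshold 90%,
#' peak duration (0, 1\] min, 13C filter at 0.001 Da/5 ppm and 0.01 min with
#' maximum charge one, join aligner at 0.001 Da/5 ppm and 0.1 min with m/z
#' weight 3 and rt weight 1.
#'
#' @param ... Override any default by name.
#' @return List of class `feature_finder_params`.
#' @export
feature_finder_params <- function(...) {
  p <- list(
    noise_ms1 = 1000, noise_ms2 = 100,
    min_consecutive_scans = 5L, min_height = 7000,
    min_intensity_consecutive = 3000,
    mz_tol_da = 0.005, mz_tol_ppm = 10,
    chrom_threshold = 0.90, peak_duration_max = 1,
    min_scans_resolve = 5L,
    isotope_mz_tol_da = 0.001, isotope_mz_tol_ppm = 5,
    isotope_rt_tol = 0.01, max_charge = 1L,
    align_mz_tol_da = 0.001, align_mz_tol_ppm = 5,
    align_rt_tol = 0.1, weight_mz = 3, weight_rt = 1
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  p[names(dots)] <- dots
  stopifnot(all(vapply(p, function(x) is.numeric(x) && x > 0, logical(1))))
  structure(p, class = "feature_finder_params")
}

# "0.005 Da or 10 ppm" = the more permissive of the two, MZmine convention.
mz_tolerance <- function(mz, tol_da, tol_ppm) {
  pmax(tol_da, tol_ppm * 1e-6 * mz)
}

#' Build chromatogram traces from MS1 scans
#'
#' Greedy m/z-bin tracing: scanning in rt order, a centroid above the MS1
#' noise level joins the open trace whose running intensity-weighted mean m/z
#' is nearest and within tolerance, else opens a new trace. A trace survives
#' only with at least `min_consecutive_scans` consecutive points and a summit
#' reaching `min_intensity_consecutive`.
#'
#' @param scans Data frame `scan`, `rt` (minutes), `mz`, `intensity`.
#' @param params [feature_finder_params()].
#' @return List of traces: each a list with `mz_center` and `points`
#'   (data frame `rt`, `intensity`, sorted by rt).
#' @export
build_chromatograms <- function(scans, params = feature_finder_params()) {
  if (is.null(scans) || nrow(scans) == 0) return(list())
  scans <- scans[scans$intensity >= params$noise_ms1, , drop = FALSE]
  if (nrow(scans) == 0) return(list())
  scan_keys <- sort(unique(scans$rt))
  open <- list()    # each: mz (running mean), wsum, rts, ints, last_rt_index
  closed <- list()
  for (si in seq_along(scan_keys)) {
    rt <- scan_keys[[si]]
    pk <- scans[scans$rt == rt, , drop = FALSE]
    pk <- pk[order(-pk$intensity), , drop = FALSE]
    # close traces with a scan gap
    if (length(open)) {
      stale <- vapply(open, function(tr) tr$last < si - 1L, logical(1))
      closed <- c(closed, open[stale])
      open <- open[!stale]
    }
    taken <- logical(length(open))
    for (r in seq_len(nrow(pk))) {
      mz <- pk$mz[[r]]; int <- pk$intensity[[r]]
      best <- 0L; best_d <- Inf
      for (t in seq_along(open)) {
        if (taken[[t]] || open[[t]]$last == si) next
        d <- abs(open[[t]]$mz - mz)
        if (d <= mz_tolerance(mz, params$mz_tol_da, params$mz_tol_ppm) &&
            d < best_d) {
          best <- t; best_d <- d
        }
      }
      if (best > 0L) {
        tr <- open[[best]]
        tr$wsum <- tr$wsum + int
        tr$mz <- (tr$mz * (tr$wsum - int) + mz * int) / tr$wsum
        tr$rts <- c(tr$rts, rt); tr$ints <- c(tr$ints, int); tr$last <- si
        open[[best]] <- tr
        taken[[best]] <- TRUE
      } else {
        open[[length(open) + 1L]] <- list(mz = mz, wsum = int, rts = rt,
                                          ints = int, last = si)
        taken <- c(taken, TRUE)
      }
    }
  }
  closed <- c(closed, open)
  keep <- Filter(function(tr) {
    length(tr$rts) >= params$min_consecutive_scans &&
      max(tr$ints) >= params$min_intensity_consecutive
  }, closed)
  lapply(keep, function(tr) {
    o <- order(tr$rts)
    list(mz_center = tr$mz,
         points = data.frame(rt = tr$rts[o], intensity = tr$ints[o]))
  })
}

#' Resolve features from a trace at local minima
#'
#' The trace is cut at interior local minima lying below
#' `(1 - chrom_threshold)` of the smaller adjacent apex (the 90% threshold
#' read as an intensity floor for valley splitting). Segments must reach the
#' minimum absolute height, contain at least `min_scans_resolve` points and
#' span at most `peak_duration_max` minutes.
#'
#' @param trace A trace from [build_chromatograms()].
#' @param params [feature_finder_params()].
#' @param sample Sample label attached to the features.
#' @return List of features: `mz`, `rt_apex`, `height`, `rt_start`, `rt_end`,
#'   `sample`.
#' @export
resolve_local_minimum <- function(trace, params = feature_finder_params(),
                                  sample = "sample") {
  pts <- trace$points
  n <- nrow(pts)
  if (n == 0) return(list())
  ints <- pts$intensity
  # interior local minima deep enough to split: valley < (1 - threshold) of
  # the lower neighbouring apex
  cuts <- integer(0)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      if (ints[i] <= ints[i - 1] && ints[i] <= ints[i + 1]) {
        left_apex <- max(ints[1:(i - 1)])
        right_apex <- max(ints[(i + 1):n])
        if (ints[i] < (1 - params$chrom_threshold) * min(left_apex, right_apex)) {
          cuts <- c(cuts, i)
        }
      }
    }
  }
  bounds <- c(1L, cuts, n)
  feats <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[[k]]; b <- bounds[[k + 1L]]
    seg <- pts[a:b, , drop = FALSE]
    apex <- which.max(seg$intensity)
    dur <- max(seg$rt) - min(seg$rt)
    if (seg$intensity[[apex]] >= params$min_height &&
        nrow(seg) >= params$min_scans_resolve &&
        dur > 0 && dur <= params$peak_duration_max) {
      feats[[length(feats) + 1L]] <- list(
        mz = trace$mz_center, rt_apex = seg$rt[[apex]],
        height = seg$intensity[[apex]],
        rt_start = min(seg$rt), rt_end = max(seg$rt), sample = sample)
    }
  }
  feats
}

#' Remove 13C isotope satellites
#'
#' Within one sample, feature B is removed as the 13C satellite of feature A
#' when mz(B) - mz(A) is within tolerance of 1.00336 Da, the apexes co-elute
#' within the rt tolerance, and B is lower than A (the monotonic-shape check
#' at charge one).
#'
#' @param features List of features (see [resolve_local_minimum()]).
#' @param params [feature_finder_params()].
#' @return Filtered feature list.
#' @export
isotope_filter <- function(features, params = feature_finder_params()) {
  if (length(features) < 2) return(features)
  mz <- vapply(features, `[[`, numeric(1), "mz")
  rt <- vapply(features, `[[`, numeric(1), "rt_apex")
  h <- vapply(features, `[[`, numeric(1), "height")
  drop <- logical(length(features))
  for (b in seq_along(features)) {
    tol <- mz_tolerance(mz[[b]], params$isotope_mz_tol_da,
                        params$isotope_mz_tol_ppm)
    sat_of <- which(abs(mz[[b]] - mz - .C13_SPACING) <= tol &
                      abs(rt[[b]] - rt) <= params$isotope_rt_tol &
                      h[[b]] < h)
    if (length(sat_of)) drop[[b]] <- TRUE
  }
  features[!drop]
}

#' Join-align features across samples
#'
#' Greedy best-score matching of per-sample feature lists onto aligned rows:
#' a candidate pair must lie within both the m/z and rt tolerances; its score
#' is `weight_mz * (1 - |dmz|/mz_tol) + weight_rt * (1 - |drt|/rt_tol)`.
#' Ties break by lower |dmz|, then lower sample index. Aligned rows carry
#' per-sample heights; rows without an MS2 spectrum are dropped afterwards by
#' [assign_ms2()] / [find_features()].
#'
#' @param feature_lists Named list (per sample) of feature lists.
#' @param params [feature_finder_params()].
#' @return Data frame: `feature_id`, `mz`, `rt`, `rt_start`, `rt_end`,
#'   `height` (max across samples) and one `height_<sample>` column per
#'   sample.
#' @export
join_align <- function(feature_lists, params = feature_finder_params()) {
  stopifnot(length(feature_lists) >= 1)
  samples <- names(feature_lists)
  if (is.null(samples)) samples <- paste0("S", seq_along(feature_lists))
  rows <- list()  # each: mz, rt, rt_start, rt_end, heights (named)
  for (si in seq_along(feature_lists)) {
    feats <- feature_lists[[si]]
    if (length(feats) == 0) next
    # score all candidate row/feature pairs, assign greedily one-to-one
    cand <- list()
    for (fi in seq_along(feats)) {
      f <- feats[[fi]]
      for (ri in seq_along(rows)) {
        r <- rows[[ri]]
        mz_tol <- mz_tolerance(f$mz, params$align_mz_tol_da,
                               params$align_mz_tol_ppm)
        dmz <- abs(f$mz - r$mz); drt <- abs(f$rt_apex - r$rt)
        if (dmz <= mz_tol && drt <= params$align_rt_tol) {
          cand[[length(cand) + 1L]] <- c(
            fi = fi, ri = ri,
            score = params$weight_mz * (1 - dmz / mz_tol) +
              params$weight_rt * (1 - drt / params$align_rt_tol),
            dmz = dmz)
        }
      }
    }
    assigned_f <- logical(length(feats))
    assigned_r <- logical(length(rows))
    if (length(cand)) {
      cdf <- do.call(rbind, cand)
      o <- order(-cdf[, "score"], cdf[, "dmz"], cdf[, "fi"])
      for (k in o) {
        fi <- cdf[k, "fi"]; ri <- cdf[k, "ri"]
        if (assigned_f[[fi]] || assigned_r[[ri]]) next
        assigned_f[[fi]] <- TRUE; assigned_r[[ri]] <- TRUE
        f <- feats[[fi]]; r <- rows[[ri]]
        w <- c(r$n, 1)
        r$mz <- stats::weighted.mean(c(r$mz, f$mz), w)
        r$rt <- stats::weighted.mean(c(r$rt, f$rt_apex), w)
        r$rt_start <- min(r$rt_start, f$rt_start)
        r$rt_end <- max(r$rt_end, f$rt_end)
        r$n <- r$n + 1
        r$heights[[samples[[si]]]] <- f$height
        rows[[ri]] <- r
      }
    }
    for (fi in which(!assigned_f)) {
      f <- feats[[fi]]
      rows[[length(rows) + 1L]] <- list(
        mz = f$mz, rt = f$rt_apex, rt_start = f$rt_start, rt_end = f$rt_end,
        n = 1, heights = stats::setNames(list(f$height), samples[[si]]))
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(feature_id = character(0), mz = numeric(0),
                      rt = numeric(0), rt_start = numeric(0),
                      rt_end = numeric(0), height = numeric(0))
    for (s in samples) out[[paste0("height_", s)]] <- numeric(0)
    return(out)
  }
  rows <- rows[order(vapply(rows, `[[`, numeric(1), "rt"),
                     vapply(rows, `[[`, numeric(1), "mz"))]
  out <- data.frame(
    feature_id = sprintf("F%03d", seq_along(rows)),
    mz = vapply(rows, `[[`, numeric(1), "mz"),
    rt = vapply(rows, `[[`, numeric(1), "rt"),
    rt_start = vapply(rows, `[[`, numeric(1), "rt_start"),
    rt_end = vapply(rows, `[[`, numeric(1), "rt_end"),
    stringsAsFactors = FALSE
  )
  for (s in samples) {
    out[[paste0("height_", s)]] <- vapply(rows, function(r) {
      if (s %in% names(r$heights)) r$heights[[s]] else 0
    }, numeric(1))
  }
  out$height <- do.call(pmax, as.list(out[paste0("height_", samples)]))
  out
}

#' Pair aligned features with MS2 spectra
#'
#' A feature receives the MS2 scan whose precursor m/z lies within the align
#' tolerance and whose rt falls inside the feature's duration; among several,
#' the highest precursor intensity wins.
#'
#' @param features Aligned feature table from [join_align()].
#' @param ms2 List of `Spectrum` objects.
#' @param params [feature_finder_params()].
#' @param drop_unmatched Drop rows without an MS2 scan (the
#'   "feature with MS2" filter); default `TRUE`.
#' @return The feature table with list-column `ms2` of spectra (or `NULL`).
#' @export
assign_ms2 <- function(features, ms2, params = feature_finder_params(),
                       drop_unmatched = TRUE) {
  if (nrow(features) == 0) {
    features$ms2 <- list()
    return(features)
  }
  assigned <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    tol <- mz_tolerance(features$mz[[i]], params$align_mz_tol_da,
                        params$align_mz_tol_ppm)
    best <- NULL; best_int <- -Inf
    for (s in ms2) {
      if (abs(s$precursor_mz - features$mz[[i]]) <= tol &&
          !is.na(s$rt) && s$rt >= features$rt_start[[i]] - 1e-9 &&
          s$rt <= features$rt_end[[i]] + 1e-9) {
        p_int <- if (is.na(s$precursor_intensity)) 0 else s$precursor_intensity
        if (p_int > best_int) { best <- s; best_int <- p_int }
      }
    }
    assigned[[i]] <- best
  }
  features$ms2 <- assigned
  if (drop_unmatched) {
    keep <- !vapply(assigned, is.null, logical(1))
    features <- features[keep, , drop = FALSE]
  }
  features
}

#' Run the full feature-finding chain on a multi-sample run
#'
#' Chromatogram building, local-minimum resolving and isotope filtering per
#' sample, join alignment across samples, then MS2 assignment with the
#' MS2-bearing-rows filter. MS2 spectra ids are rewritten to the aligned
#' feature ids so networking nodes and feature rows agree.
#'
#' @param run Named list per sample: each a list with `ms1` (scan table) and
#'   `ms2` (list of `Spectrum`).
#' @param params [feature_finder_params()].
#' @return Aligned feature table with `ms2` list-column.
#' @export
find_features <- function(run, params = feature_finder_params()) {
  per_sample <- lapply(run, function(smp) {
    traces <- build_chromatograms(smp$ms1, params)
    feats <- unlist(lapply(traces, resolve_local_minimum, params = params),
                    recursive = FALSE)
    isotope_filter(feats, params)
  })
  aligned <- join_align(per_sample, params)
  all_ms2 <- unlist(lapply(run, `[[`, "ms2"), recursive = FALSE)
  out <- assign_ms2(aligned, all_ms2, params)
  if (nrow(out) > 0) {
    out$ms2 <- lapply(seq_len(nrow(out)), function(i) {
      s <- out$ms2[[i]]
      s$id <- out$feature_id[[i]]
      s
    })
  }
  out
}
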