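# Modified-cosine similarity, network construction, cluster accounting,
# library matching and annotation propagation.

test_that("modified cosine: self-similarity, disjoint spectra, polarity guard", {
  s <- spec(c(100.1, 150.2, 200.3, 250.4), c(10, 40, 90, 160))
  self <- modified_cosine(s, s)
  expect_equal(self$cosine, 1, tolerance = 1e-12)
  expect_identical(self$n_matched, 4L)
  far <- spec(c(300.7, 320.9), precursor = 500)  # nothing within tolerance
  none <- modified_cosine(s, far)
  expect_identical(none$cosine, 0)
  expect_identical(none$n_matched, 0L)
  pos <- spec(c(100.1), polarity = "positive")
  expect_error(modified_cosine(s, pos), "polarity")
})

test_that("precursor-shifted peaks match across an analogue pair", {
  # B is A shifted by +14.0157 (methylation): all peaks match shifted
  a <- spec(c(100.0, 150.0, 200.0), c(50, 80, 100), precursor = 300)
  b <- spec(c(100.0, 150.0, 200.0) + 14.0157, c(50, 80, 100),
            precursor = 314.0157)
  m <- modified_cosine(a, b)
  expect_equal(m$cosine, 1, tolerance = 1e-9)
  expect_identical(m$n_matched, 3L)
})

test_that("modified cosine is symmetric", {
  set.seed(17)
  for (k in 1:30) {
    a <- spec(runif(5, 100, 500), runif(5, 10, 100),
              precursor = runif(1, 500, 600))
    b <- spec(runif(5, 100, 500), runif(5, 10, 100),
              precursor = runif(1, 500, 600))
    expect_equal(modified_cosine(a, b)$cosine, modified_cosine(b, a)$cosine,
                 tolerance = 1e-9)
  }
})

test_that("greedy matching stays within 5% of the exhaustive optimum", {
  set.seed(101)
  worst <- 1
  for (trial in 1:300) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    pa <- runif(1, 300, 500); pb <- pa + runif(1, -30, 30)
    amz <- runif(na, 100, 290)
    # seed some relationships: direct and shifted copies plus jitter
    bmz <- c(amz[seq_len(min(2, na))] + runif(2, -0.01, 0.01),
             amz[seq_len(min(2, na))] + (pb - pa) + runif(2, -0.01, 0.01),
             runif(nb, 100, 290))[seq_len(nb)]
    a <- spec(amz, runif(na, 10, 100), precursor = pa)
    b <- spec(bmz, runif(nb, 10, 100), precursor = pb)
    greedy <- modified_cosine(a, b)$cosine
    exact <- brute_modified_cosine(a, b)
    if (exact > 0) worst <- min(worst, greedy / exact)
  }
  expect_gte(worst, 0.95)
})

test_that("toy shifted-match case equals the brute-force optimum", {
  a <- spec(c(100.00, 120.00, 150.00), c(100, 50, 80), precursor = 300)
  b <- spec(c(100.005, 134.01, 164.02), c(90, 60, 70), precursor = 314.0157)
  greedy <- modified_cosine(a, b)
  expect_equal(greedy$cosine, brute_modified_cosine(a, b), tolerance = 1e-9)
})

test_that("network construction obeys thresholds and counts clusters", {
  single <- build_network(list(spec(c(100.1, 150.1), id = "only")))
  st <- network_stats(single)
  expect_identical(st$total_nodes, 1L)
  expect_identical(st$clusters, 0L)
  expect_identical(st$non_clustered_nodes, 1L)
  expect_equal(igraph::ecount(single$graph), 0)

  cfg <- simulation_config(seed = 11)
  fam1 <- rbind(compound_row("A", "C21H18O11", "[M-H]-", "flavonoid", 7.3),
                compound_row("B", "C15H10O5", "[M-H]-", "flavonoid", 10.0),
                compound_row("C", "C22H20O11", "[M-H]-", "flavonoid", 8.1))
  fam2 <- rbind(compound_row("D", "C15H24O", "[M+H-H2O]+", "terpenoid", 20.3),
                compound_row("E", "C15H22O", "[M+H-H2O]+", "terpenoid", 21.0))
  sp <- lapply(seq_len(3), function(i) simulate_spectrum(fam1[i, ], cfg))
  sp2 <- lapply(seq_len(2), function(i) simulate_spectrum(fam2[i, ], cfg))
  net <- build_network(c(sp, sp2))
  st <- network_stats(net)
  expect_identical(st$total_nodes, 5L)
  expect_identical(st$clusters, 2L)          # one per planted family
  expect_identical(st$clustered_nodes, 5L)
  # oracle: every kept edge agrees with the brute-force matcher
  edf <- igraph::as_data_frame(net$graph, "edges")
  all_sp <- c(sp, sp2)
  ids <- vapply(all_sp, function(s) s$id, character(1))
  for (e in seq_len(nrow(edf))) {
    a <- all_sp[[match(edf$from[e], ids)]]
    b <- all_sp[[match(edf$to[e], ids)]]
    expect_gte(brute_modified_cosine(a, b), 0.70 * 0.95)
  }
})

test_that("raising the cosine threshold never adds edges; nodes invariant", {
  cfg <- simulation_config(seed = 19)
  lib <- table1_prototypes()
  rows <- lib[lib$class == "flavonoid", ][1:6, ]
  sp <- lapply(seq_len(nrow(rows)), function(i)
    simulate_spectrum(rows[i, ], cfg))
  cuts <- c(0.5, 0.7, 0.9, 0.99)
  counts <- vapply(cuts, function(ct) {
    g <- build_network(sp, network_params(min_cosine = ct))
    expect_identical(network_stats(g)$total_nodes, length(sp))
    igraph::ecount(g$graph)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("library matching annotates planted identities and resists decoys", {
  cfg <- simulation_config(seed = 23, noise_peaks = 0)
  bai <- compound_row("P17", "C21H18O11", "[M-H]-", "flavonoid", 7.3,
                      name = "Baicalin")
  lib_entry <- list(record = list(name = "Baicalin", class = "flavonoid"),
                    spectrum = simulate_spectrum(bai, cfg))
  query <- simulate_spectrum(bai, simulation_config(seed = 99))
  hit <- library_match(query, list(lib_entry))
  expect_identical(hit$name, "Baicalin")
  expect_identical(hit$annotation_source, "library")
  expect_gte(hit$n_matched, 6)
  # empty library
  expect_null(library_match(query, list()))
  # decoy: same precursor, shuffled non-matching peaks
  decoy <- lib_entry
  decoy$spectrum$mz <- sort(decoy$spectrum$mz * 0.77 + 3)
  expect_null(library_match(query, list(decoy)))
})

test_that("cluster annotation propagation flags hypotheses and conflicts", {
  cfg <- simulation_config(seed = 29)
  fam <- rbind(compound_row("A", "C21H18O11", "[M-H]-", "flavonoid", 7.3,
                            name = "Baicalin"),
               compound_row("B", "C22H20O11", "[M-H]-", "flavonoid", 8.1))
  sp <- lapply(seq_len(2), function(i) simulate_spectrum(fam[i, ], cfg))
  net <- build_network(sp)
  net$graph <- igraph::set_vertex_attr(net$graph, "annotation", 1, "Baicalin")
  net$graph <- igraph::set_vertex_attr(net$graph, "class_hypothesis", 1,
                                       "flavonoid")
  out <- propagate_annotations(net)
  expect_identical(igraph::vertex_attr(out$graph, "class_hypothesis", 2),
                   "flavonoid")
  expect_identical(igraph::vertex_attr(out$graph, "annotation_source", 2),
                   "cluster-hypothesis")
  # conflicting classes in one cluster propagate as ambiguous
  fam3 <- rbind(fam, compound_row("C", "C15H10O5", "[M-H]-", "flavonoid", 10))
  sp3 <- lapply(seq_len(3), function(i) simulate_spectrum(fam3[i, ], cfg))
  net3 <- build_network(sp3)
  net3$graph <- igraph::set_vertex_attr(net3$graph, "annotation", 1, "x")
  net3$graph <- igraph::set_vertex_attr(net3$graph, "class_hypothesis", 1,
                                        "flavonoid")
  net3$graph <- igraph::set_vertex_attr(net3$graph, "annotation", 2, "y")
  net3$graph <- igraph::set_vertex_attr(net3$graph, "class_hypothesis", 2,
                                        "anthraquinone")
  out3 <- propagate_annotations(net3)
  expect_match(igraph::vertex_attr(out3$graph, "class_hypothesis", 3),
               "ambiguous")
  # singleton unknowns stay untouched
  lone <- build_network(list(spec(c(100.1, 120.2), id = "lone")))
  out_lone <- propagate_annotations(lone)
  expect_true(is.na(igraph::vertex_attr(out_lone$graph, "class_hypothesis",
                                        1)))
})
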