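# Biotransformation ledger, metabolite prediction, XIC presence calls,
# candidate matching and pathway assembly.

test_that("ledger mass deltas equal their formula arithmetic", {
  led <- biotransformation_ledger()
  for (i in seq_len(nrow(led))) {
    sign <- if (led$direction[[i]] == "gain") 1 else -1
    expect_equal(led$mass_delta[[i]],
                 sign * monoisotopic_mass(led$formula[[i]]),
                 tolerance = 1e-5, label = led$name[[i]])
  }
  # key conjugation masses
  expect_equal(led$mass_delta[led$name == "glucuronidation"], 176.03209,
               tolerance = 1e-5)
  expect_equal(led$mass_delta[led$name == "sulfation"], 79.95682,
               tolerance = 1e-5)
})

test_that("chain mass shifts equal formula arithmetic to depth 3", {
  led <- biotransformation_ledger()
  set.seed(53)
  base <- "C21H18O11"
  for (k in 1:40) {
    idx <- sample(nrow(led), sample(1:3, 1), replace = TRUE)
    f <- parse_formula(base)
    ok <- TRUE
    for (i in idx) {
      f <- tryCatch(
        if (led$direction[[i]] == "gain") formula_add(f, led$formula[[i]])
        else formula_subtract(f, led$formula[[i]]),
        error = function(e) NULL)
      if (is.null(f)) { ok <- FALSE; break }
    }
    if (!ok) next
    expect_equal(monoisotopic_mass(f) - monoisotopic_mass(base),
                 sum(led$mass_delta[idx]), tolerance = 1e-5)
  }
})

test_that("metabolite prediction reproduces the worked baicalin products", {
  pred <- predict_metabolites("C21H18O11", "Baicalin", max_depth = 2)
  methyl <- pred[pred$chain == "+CH2", ]
  expect_identical(methyl$formula, "C22H20O11")
  expect_equal(round(methyl$mz_neg, 4), 459.0933)
  glca <- pred[pred$chain == "+C6H8O6", ]
  expect_identical(glca$formula, "C27H26O17")
  expect_equal(round(glca$mz_neg, 4), 621.1097)
  # deduplication by formula, no parent, no negative counts
  expect_false(any(duplicated(pred$formula)))
  expect_false("C21H18O11" %in% pred$formula)
  expect_identical(nrow(predict_metabolites("C21H18O11", max_depth = 0)), 0L)
})

test_that("every packaged metabolite row reproduces from its parent by chain arithmetic", {
  tabs <- table_fixtures()
  t1 <- tabs$table1; t2 <- tabs$table2
  for (i in seq_len(nrow(t2))) {
    parent <- t1[t1$name == t2$parent[[i]], ]
    expect_identical(nrow(parent), 1L, label = paste("parent of", t2$id[[i]]))
    f <- apply_chain(parent$formula[[1]], t2$chain[[i]])
    expect_identical(format_formula(f), t2$formula[[i]],
                     label = paste(t2$id[[i]], "formula"))
    calc <- adduct_mz(monoisotopic_mass(f), t2$adduct[[i]])
    expect_lt(abs(calc - t2$theoretical_mz[[i]]), 2e-4,
              label = paste(t2$id[[i]], "theoretical m/z"))
  }
})

test_that("XIC extraction recovers planted signal inside its ppm window", {
  scans <- data.frame(scan = 1:7, rt = seq(7.2, by = 0.05, length.out = 7),
                      mz = 445.0777,
                      intensity = c(5, 35, 70, 100, 70, 35, 5) * 1000)
  hit <- extract_xic(scans, 445.0776, ppm_tol = 5)
  expect_equal(hit$apex_height, 1e5)
  expect_equal(hit$apex_rt, 7.35)
  # a query 10 ppm away at 5 ppm tolerance finds nothing
  miss <- extract_xic(scans, 445.0776 * (1 + 10e-6), ppm_tol = 5)
  expect_identical(nrow(miss$trace), 0L)
  expect_identical(miss$apex_height, 0)
  # isomer pair resolved by rt window
  iso <- rbind(scans,
               transform(scans, rt = rt + 1, intensity = intensity / 2))
  early <- extract_xic(iso, 445.0776, 5, rt_window = c(7.0, 7.6))
  late <- extract_xic(iso, 445.0776, 5, rt_window = c(8.0, 8.7))
  expect_equal(early$apex_height, 1e5)
  expect_equal(late$apex_height, 5e4)
})

test_that("presence calls demand dosed signal and clean blanks", {
  lib <- table1_prototypes()
  planted <- c("P17", "P33", "P38", "P41", "P5", "P24", "P26", "P2", "P22",
               "P40")
  sim <- simulate_acquisition(lib, simulation_config(seed = 61),
                              extract_ids = character(0),
                              plasma_ids = planted)
  calls <- call_prototypes(lib, sim$samples$plasma_dosed$ms1,
                           sim$samples$plasma_blank$ms1)
  det <- calls$compound_id[calls$detected]
  # exactly the planted subset: P22/P26 and P33/P24 etc. share formulas, so
  # compare by target mass rather than id
  planted_mz <- sort(unique(round(calls$target_mz[calls$compound_id %in%
                                                    planted], 3)))
  detected_mz <- sort(unique(round(calls$target_mz[calls$detected], 3)))
  expect_identical(detected_mz, planted_mz)
  expect_true(all(planted %in% det))
  # a compound equally present in the blank is not "detected"
  dosed <- sim$samples$plasma_dosed$ms1
  calls2 <- call_prototypes(lib[lib$id == "P17", ], dosed, dosed)
  expect_false(any(calls2$detected))
  # empty dosed run detects nothing
  empty <- data.frame(scan = integer(0), rt = numeric(0), mz = numeric(0),
                      intensity = numeric(0))
  expect_false(any(call_prototypes(lib, empty, empty)$detected))
})

test_that("metabolite matching needs mass, dosed-only status and evidence", {
  proto_frag <- c(269.0461, 251.0346, 223.0406, 169.0661)
  cand <- predict_metabolites("C21H18O11", "Baicalin", max_depth = 1)
  cand <- cand[cand$chain == "+CH2", ]
  cand$prototype_id <- "P17"
  cand$prototype_formula <- "C21H18O11"
  cand$prototype_class <- "flavonoid"
  cand$prototype_fragments <- list(proto_frag)
  # planted analogue: right mass, fragments shifted by +CH2
  analog <- new_spectrum("F1", cand$mz_neg, "negative", 8.1,
                         mz = proto_frag + 14.0157,
                         intensity = c(100, 60, 40, 30))
  dosed <- data.frame(feature_id = "F1", mz = cand$mz_neg + 1e-4, rt = 8.1)
  dosed$ms2 <- list(analog)
  hit <- match_metabolites(cand, dosed, NULL)
  expect_identical(hit$matched_feature, "F1")
  expect_gte(hit$shared_fragments, 4)
  # decoy at the right mass with unrelated fragments is refused
  decoy <- new_spectrum("F1", cand$mz_neg, "negative", 8.1,
                        mz = c(101.3, 222.9, 333.3, 401.1),
                        intensity = c(100, 80, 60, 40))
  dosed_decoy <- dosed
  dosed_decoy$ms2 <- list(decoy)
  miss <- match_metabolites(cand, dosed_decoy, NULL)
  expect_true(is.na(miss$matched_feature))
  # without the evidence requirement the decoy mass alone would match
  loose <- match_metabolites(cand, dosed_decoy, NULL, require_evidence = FALSE)
  expect_identical(loose$matched_feature, "F1")
  # candidate mass present in the blank is not dosed-only
  blank <- data.frame(feature_id = "B1", mz = cand$mz_neg, rt = 3.0)
  gone <- match_metabolites(cand, dosed, blank)
  expect_true(is.na(gone$matched_feature))
})

test_that("pathway assembly draws transformation and hydrolysis edges", {
  protos <- data.frame(id = c("P17", "P33"), name = c("Baicalin", "Baicalein"),
                       formula = c("C21H18O11", "C15H10O5"),
                       stringsAsFactors = FALSE)
  matched <- data.frame(
    prototype_id = c("P17", "P17", "P33"),
    name = c("Baicalin+CH2", "Baicalin+C6H8O6", "Baicalein-O"),
    chain = c("+CH2", "+C6H8O6", "-O"),
    formula = c("C22H20O11", "C27H26O17", "C15H10O4"),
    matched_feature = c("F1", "F2", "F3"), stringsAsFactors = FALSE)
  pw <- assemble_pathways(protos, matched)
  expect_equal(igraph::vcount(pw$graph), 5)
  hydro <- pw$edges[grepl("hydrolysis", pw$edges$chain), ]
  expect_identical(hydro$from, "P17")
  expect_identical(hydro$to, "P33")
  # no metabolites: isolated prototype nodes
  none <- assemble_pathways(protos[2, , drop = FALSE],
                            matched[0, , drop = FALSE])
  expect_equal(igraph::vcount(none$graph), 1)
  expect_equal(igraph::ecount(none$graph), 0)
  # two prototypes colliding on one metabolite formula are both kept, flagged
  iso <- data.frame(
    prototype_id = c("P17", "P33"), name = c("A+CH2", "B+C6H8O6+CH2"),
    chain = c("+CH2", "+C6H8O6+CH2"), formula = c("C22H20O11", "C22H20O11"),
    matched_feature = c("F1", "F1"), stringsAsFactors = FALSE)
  amb <- assemble_pathways(protos, iso)
  expect_true(all(amb$edges$ambiguous[!grepl("hydrolysis",
                                             amb$edges$chain)]))
})

test_that("plasma/cerebrum intersection of the prototype table is recovered", {
  t1 <- table1_prototypes()
  shared <- t1$id[t1$in_plasma & t1$in_cerebrum]
  expect_identical(length(shared), 16L)
  expect_true(all(c("P17", "P33", "P38", "P41") %in% shared))
})
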