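test_that("the packaged registry reproduces the frozen CSR tallies", {
  reg <- load_trait_registry()
  counts <- registry_class_counts(reg)
  expect_identical(counts[["C"]], 9L)
  expect_identical(counts[["S"]], 6L)
  expect_identical(counts[["R"]], 9L)
  expect_identical(counts[["foraging"]], 6L)
  expect_identical(sum(reg$class == "conditional_CS"), 1L)
  expect_identical(reg$pathway_name[reg$class == "conditional_CS"],
                   "ABC transporters")
  # conditional override moves the ABC entry between the S and C tallies
  counts_c <- registry_class_counts(reg, conditional = "C")
  expect_identical(counts_c[["C"]], 10L)
  expect_identical(counts_c[["S"]], 5L)
})

test_that("registry validation rejects malformed or duplicated entries", {
  reg <- load_trait_registry()
  tmp <- tempfile(fileext = ".tsv")
  bad <- rbind(as.data.frame(reg)[, 1:4], as.data.frame(reg)[1, 1:4])
  utils::write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_trait_registry(tmp), "duplicate")
  utils::write.table(as.data.frame(reg)[1:5, 1:4], tmp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(load_trait_registry(tmp), "tallies")
})

test_that("pathway calls classify into treatment trait profiles as printed", {
  reg <- load_trait_registry()

  # all not-significant: empty profile
  empty <- classify_calls(fake_calls(not_significant = "Ribosome"), reg)
  expect_length(unlist(lapply(empty$classes, unlist)), 0)

  # a registry-C pathway enriched in treatment lands in C-enriched
  p <- classify_calls(fake_calls(enriched_treatment = "Clavulanic acid biosynthesis"), reg)
  expect_identical(p$classes$C$enriched, "Clavulanic acid biosynthesis")

  # the high-dose rhizosphere treatment row: its three C-enriched pathways
  p100 <- classify_calls(fake_calls(
    enriched_treatment = c("Biosynthesis of type II polyketide products",
                           "Clavulanic acid biosynthesis",
                           "Staurosporine biosynthesis",
                           "ABC transporters"),
    enriched_baseline = c("Acarbose and validamycin biosynthesis",
                          "Polyketide sugar unit biosynthesis",
                          "Ribosome")), reg, treatment = "rhizosphere.100")
  expect_setequal(p100$classes$C$enriched,
                  c("Biosynthesis of type II polyketide products",
                    "Clavulanic acid biosynthesis",
                    "Staurosporine biosynthesis"))
  expect_setequal(p100$classes$C$depleted,
                  c("Acarbose and validamycin biosynthesis",
                    "Polyketide sugar unit biosynthesis"))
  # conditional ABC transporters resolves to S by default, to C on request
  expect_identical(p100$classes$S$enriched, "ABC transporters")
  p100c <- classify_calls(fake_calls(enriched_treatment = "ABC transporters"),
                          reg, conditional = "C")
  expect_identical(p100c$classes$C$enriched, "ABC transporters")

  # matching is case/whitespace-insensitive; unknown pathways are reported
  p2 <- classify_calls(fake_calls(enriched_treatment = c("  RIBOSOME ", "path42")), reg)
  expect_identical(p2$classes$R$enriched, "Ribosome")
  expect_identical(p2$unclassified$enriched, "path42")

  # two printed names sharing one trait count once
  p3 <- classify_calls(fake_calls(
    enriched_treatment = c("Carbon metabolism", "TCA cycle")), reg)
  expect_identical(p3$classes$R$enriched, "Carbon metabolism")
})

test_that("CSR scores follow the net-change equation with per-class scaling", {
  reg <- load_trait_registry()

  # empty profile scores (0, 0, 0)
  s0 <- csr_score(classify_calls(fake_calls(), reg), reg)
  expect_identical(c(s0$delta_C, s0$delta_S, s0$delta_R), c(0, 0, 0))

  # worked example: 3 C enriched, 1 C depleted, N_C = 9 => 22.22
  p <- classify_calls(fake_calls(
    enriched_treatment = c("Clavulanic acid biosynthesis",
                           "Staurosporine biosynthesis",
                           "Carbapenem biosynthesis"),
    enriched_baseline = "Polyketide sugar unit biosynthesis"), reg)
  s <- csr_score(p, reg)
  expect_equal(s$delta_C, (3 / 9 - 1 / 9) * 100, tolerance = 1e-12)
  expect_equal(round(s$delta_C, 2), 22.22)
  expect_identical(c(s$delta_S, s$delta_R), c(0, 0))

  # boundary: every R trait depleted, none enriched => -100
  r_names <- unique(reg$pathway_name[reg$class == "R"])
  pr <- classify_calls(fake_calls(enriched_baseline = r_names), reg)
  expect_equal(csr_score(pr, reg)$delta_R, -100)

  # antisymmetry: swapping enriched and depleted negates every delta
  p_swap <- classify_calls(fake_calls(
    enriched_treatment = "Polyketide sugar unit biosynthesis",
    enriched_baseline = c("Clavulanic acid biosynthesis",
                          "Staurosporine biosynthesis",
                          "Carbapenem biosynthesis")), reg)
  s_swap <- csr_score(p_swap, reg)
  expect_equal(s_swap$delta_C, -s$delta_C)

  # pathways outside the registry never move the axes
  p_noise <- classify_calls(fake_calls(
    enriched_treatment = c("Clavulanic acid biosynthesis",
                           "Staurosporine biosynthesis",
                           "Carbapenem biosynthesis", "pathX", "pathY"),
    enriched_baseline = c("Polyketide sugar unit biosynthesis", "pathZ")), reg)
  expect_equal(csr_score(p_noise, reg)$delta_C, s$delta_C)

  # foraging traits are excluded from all three axes
  pf <- classify_calls(fake_calls(enriched_treatment = "Bacterial chemotaxis"), reg)
  sf <- csr_score(pf, reg)
  expect_identical(c(sf$delta_C, sf$delta_S, sf$delta_R), c(0, 0, 0))

  # global denominator option scales by the 24 CSR traits
  expect_equal(csr_score(p, reg, denominator = "global")$delta_C,
               (3 - 1) / 24 * 100)
})

test_that("coordinate export is tidy, stably ordered and bounded", {
  reg <- load_trait_registry()
  s1 <- csr_score(classify_calls(fake_calls(), reg,
                                 treatment = "bulk.20"), reg)
  s2 <- csr_score(classify_calls(
    fake_calls(enriched_treatment = "Clavulanic acid biosynthesis"),
    reg, treatment = "rhizosphere.0"), reg)
  coords <- csr_coordinates(list(s2, s1))
  expect_identical(coords$treatment, c("bulk.20", "rhizosphere.0"))
  expect_true(all(abs(as.matrix(coords[, -1])) <= 100))
  expect_error(csr_coordinates(list(s1, s1)), "duplicate")
})

test_that("planting effects in one class moves only that class's axis", {
  # build a map whose pathway ids are registry names: plant C pathways up
  # and R pathways down in the treatment, expect delta_C > 0 > delta_R
  reg <- load_trait_registry()
  c_names <- reg$pathway_name[reg$class == "C"][1:3]
  r_names <- unique(reg$pathway_name[reg$class == "R"])[1:3]
  kos <- sprintf("K%04d", 1:360)
  sets <- split(kos, rep(1:12, each = 30))
  names(sets) <- c(c_names, r_names, paste0("noise", 1:6))
  pm <- pathway_map(sets)
  des <- two_cell_design(5)
  effects <- c(
    lapply(c_names, planted_effect, cell = "rhizosphere.0", log2_fc = 2,
           affected_fraction = 0.8, direction = "up"),
    lapply(r_names, planted_effect, cell = "rhizosphere.0", log2_fc = 2,
           affected_fraction = 0.8, direction = "down")
  )
  tab <- generate_counts(pm, des, effects, base_mean = 400, dispersion = 0.05,
                         libsize_cv = 0.2, seed = 21)
  cmp <- pairwise_comparison(des, "rhizosphere.0", "bulk.0")
  sets_hat <- extract_enriched_sets(nb_wald_test(tab, cmp), 0.05)
  calls <- call_pathways(sets_hat, pm, config = bootstrap_config(seed = 21))
  prof <- classify_calls(calls, reg, treatment = "rhizosphere.0")
  score <- csr_score(prof, reg)
  expect_gt(score$delta_C, 0)
  expect_lt(score$delta_R, 0)
  expect_equal(score$delta_S, 0)
})
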