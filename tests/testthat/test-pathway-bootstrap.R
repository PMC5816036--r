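test_that("observed hits is the plain intersection count", {
  expect_identical(observed_hits(c("k1", "k2", "k3"), c("k1", "k2", "k3")), 3L)
  expect_identical(observed_hits(c("k1", "k2"), c("k8", "k9")), 0L)
  expect_identical(observed_hits(c("k1", "k2", "k5"), c("k2", "k5", "k9")), 2L)
})

test_that("expected hit draws are marginally hypergeometric", {
  u <- sprintf("K%03d", 1:10)
  pk <- u[1:4]
  draws <- expected_hit_draws(5, u, pk, n_reps = 10000, seed = 1)
  expect_gt(mean(draws), 1.9)   # exact mean nK/N = 2
  expect_lt(mean(draws), 2.1)
  # goodness of fit against the combinatorially enumerated pmf
  expect_gt(gof_pvalue(draws, hyper_pmf_enum(10, 4, 5)), 0.01)

  # forced draws
  expect_true(all(expected_hit_draws(10, u, pk, 100, seed = 2) == 4))
  expect_true(all(expected_hit_draws(5, u, character(0), 100, seed = 3) == 0))
  expect_error(expected_hit_draws(11, u, pk, 10, seed = 1), "universe")
})

test_that("difference-of-medians follows the midpoint convention and the hypergeometric median", {
  expect_equal(median_difference(4, c(2, 2, 2)), 2)
  expect_equal(median_difference(3, c(3, 3, 3, 3)), 0)
  expect_equal(median_difference(5, c(1, 3)), 3)
  expect_error(median_difference(1, integer(0)), "non-empty")

  # N = 10, K = 4, n = 5: enumerated pmf has median 2, so at large reps
  # the statistic concentrates at observed - 2
  pmf <- hyper_pmf_enum(10, 4, 5)
  expect_equal(pmf_median(pmf), 2)
  draws <- expected_hit_draws(5, sprintf("K%03d", 1:10), sprintf("K%03d", 1:4),
                              n_reps = 10001, seed = 4)
  expect_equal(median_difference(4, draws), 2)
})

test_that("the randomized null matches exhaustive subset-pair enumeration", {
  # N = 6, K = 2, n = 3 and N = 8, K = 3, n = 4: brute-force enumeration
  # of all subset pairs gives the exact difference distribution
  cases <- list(c(N = 6, K = 2, n = 3), c(N = 8, K = 3, n = 4))
  for (cs in cases) {
    u <- sprintf("K%03d", seq_len(cs["N"]))
    pk <- u[seq_len(cs["K"])]
    exact <- null_diff_pmf_enum(cs["N"], cs["K"], cs["n"])
    nd <- null_distribution(cs["n"], u, pk,
                            bootstrap_config(n_reps = 10000, seed = 11))
    expect_lt(ks_distance(nd$differences, exact), 0.02)
    expect_lt(abs(mean(nd$differences)), 0.05)  # symmetric about 0
    expect_lte(nd$lower_limit, nd$upper_limit)
  }

  # empty pathway: all null differences are exactly 0
  u <- sprintf("K%03d", 1:20)
  nd0 <- null_distribution(5, u, character(0),
                           bootstrap_config(n_reps = 500, seed = 1))
  expect_true(all(nd0$differences == 0))
  expect_identical(c(nd0$lower_limit, nd0$upper_limit), c(0L, 0L))
})

test_that("percentile limits sit at the configured order statistics and mirror each other", {
  # N = 6, K = 2, n = 3, ranks 50/950 of 1000: limits stay inside the
  # attainable difference range {-2..2}, and the rate at which the two
  # limits mirror each other matches sampling order statistics directly
  # from the exhaustively enumerated difference pmf
  u <- sprintf("K%03d", 1:6)
  pk <- u[1:2]
  sym <- vapply(1:100, function(s) {
    nd <- null_distribution(3, u, pk, bootstrap_config(n_reps = 1000, seed = s))
    expect_true(all(c(nd$lower_limit, nd$upper_limit) %in% -2:2))
    nd$lower_limit == -nd$upper_limit
  }, logical(1))

  pmf <- null_diff_pmf_enum(6, 2, 3)
  set.seed(99)
  oracle_sym <- mean(replicate(500, {
    d <- sort(sample(as.numeric(names(pmf)), 1000, replace = TRUE, prob = pmf))
    d[50] == -d[950]
  }))
  expect_lt(abs(mean(sym) - oracle_sym), 0.15)
  expect_gte(mean(sym), 0.5)

  expect_error(bootstrap_config(n_reps = 1000, lower_index = 0), "lower_index")
  expect_error(bootstrap_config(n_reps = 50), "n_reps")
})

test_that("a strongly planted pathway is called enriched, random sets are calibrated", {
  # planted: universe 500, pathway 20 KOs, enriched set of 25 with 15 inside
  u <- sprintf("K%04d", 1:500)
  pm <- pathway_map(list(target = u[1:20], decoy = u[21:60]), universe = u)
  es <- enriched_ko_sets(list(id = "planted"),
                         c(u[1:15], u[101:110]), character(0))
  calls <- suppressWarnings(call_pathways(es, pm, config = bootstrap_config(seed = 1)))
  tr <- calls[calls$direction == "treatment", ]
  expect_identical(tr$call[tr$pathway_id == "target"], "enriched")
  expect_identical(tr$observed_hits[tr$pathway_id == "target"], 15L)
  # call rule invariants
  expect_true(all((tr$call == "enriched") ==
                    (tr$median_difference > tr$upper_limit)))
  expect_true(all((tr$call == "depleted") ==
                    (tr$median_difference < tr$lower_limit)))

  # pathway disjoint from the enriched KOs is never called enriched
  es2 <- enriched_ko_sets(list(id = "disjoint"), u[490:499], character(0))
  calls2 <- suppressWarnings(call_pathways(es2, pm, config = bootstrap_config(seed = 2)))
  expect_identical(
    calls2$call[calls2$direction == "treatment" & calls2$pathway_id == "target"],
    "not_significant")

  # empty enriched set: warning, all not_significant with zero statistics
  es3 <- enriched_ko_sets(list(id = "empty"), character(0), character(0))
  w <- testthat::capture_warnings(
    calls3 <- call_pathways(es3, pm, config = bootstrap_config(seed = 3)))
  expect_match(w, "empty enriched set", all = TRUE)
  expect_length(w, 2)  # one warning per direction
  expect_true(all(calls3$call == "not_significant"))
  expect_true(all(calls3$median_difference == 0))
})

test_that("pathway calls are deterministic given the master seed", {
  pm <- generate_pathway_map(30, 400, c(1, 20), 0.2, seed = 5)
  es <- generate_enriched_sets(pm, 20, seed = 6)
  c1 <- suppressWarnings(call_pathways(es, pm, config = bootstrap_config(seed = 99)))
  c2 <- suppressWarnings(call_pathways(es, pm, config = bootstrap_config(seed = 99)))
  expect_identical(c1, c2)
})

test_that("adding a pathway KO to the enriched set never decreases the median difference", {
  # same substream for both draw sizes: the n-subset draws are prefixes of
  # the (n+1)-subset draws, so the guarantee holds replicate by replicate
  u <- sprintf("K%04d", 1:200)
  pk <- u[1:25]
  set.seed(123)
  for (case in 1:10) {
    enriched <- u[sample(seq_along(u), 20)]
    extra <- setdiff(pk, enriched)[1]
    if (is.na(extra)) next
    obs1 <- observed_hits(enriched, pk)
    obs2 <- observed_hits(c(enriched, extra), pk)
    d1 <- expected_hit_draws(length(enriched), u, pk, 2000, seed = case)
    d2 <- expected_hit_draws(length(enriched) + 1, u, pk, 2000, seed = case)
    expect_gte(median_difference(obs2, d2), median_difference(obs1, d1))
  }
})

test_that("the under-representation screen excludes redundancy-driven pathways only", {
  # pathway absent from the metagenome but large in the reference: excluded
  u <- sprintf("K%04d", 1:100)
  pm <- pathway_map(list(absent = u[51:80],    # 30 KOs, none observed
                         present = u[1:20]),   # fully contained
                    universe = u)
  metagenome <- u[1:50]
  scr <- underrepresentation_screen(metagenome, pm, bootstrap_config(seed = 1))
  expect_identical(scr$excluded, "absent")
  expect_identical(scr$retained, "present")
  expect_length(intersect(scr$excluded, scr$retained), 0)

  # metagenome = full universe: nothing can be under-represented
  scr_full <- underrepresentation_screen(u, pm, bootstrap_config(seed = 2))
  expect_length(scr_full$excluded, 0)

  expect_error(underrepresentation_screen(c(u[1], "K9999"), pm,
                                          bootstrap_config(seed = 1)),
               "absent from the reference")
})
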