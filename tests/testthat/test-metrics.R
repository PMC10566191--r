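test_that("class table tallies classes, proportions and coverage weights", {
  gm <- make_worked_toy()
  ct <- build_class_table(gm)
  expect_identical(unname(ct$e["M_focal"]), 3L)
  expect_equal(unname(ct$counts[["M_focal"]]), c(5L, 45L, 50L))
  expect_equal(unname(ct$props[["M_focal"]]), c(0.05, 0.45, 0.50))
  # proportions sum to 1 per marker; full coverage sums to CV = 1
  expect_true(all(abs(vapply(ct$props, sum, 1) - 1) < 1e-12))
  expect_equal(sum(ct$e * ct$w), 1, tolerance = 1e-12)

  toy <- toy_matrix()
  ct2 <- build_class_table(toy)
  expect_identical(unname(ct2$e), c(3L, 2L, 1L))
  # missing calls excluded from the denominator
  expect_equal(unname(ct2$props[["m2"]]), c(2 / 3, 1 / 3))
  # monomorphic marker: single class at p = 1
  expect_equal(unname(ct2$props[["m3"]]), 1)
})

test_that("all-missing markers are excluded; fully missing matrices rejected", {
  calls <- matrix(c("AA", "AB", NA, NA), nrow = 2, byrow = TRUE,
                  dimnames = list(c("m1", "m2"), c("s1", "s2")))
  ct <- build_class_table(genotype_matrix(calls))
  expect_identical(ct$excluded_markers, "m2")
  expect_identical(ct$m, 1L)
  calls[] <- NA_character_
  expect_error(build_class_table(genotype_matrix(calls)), "missing")
})

test_that("coverage matches closed forms and the per-definition oracle", {
  toy <- toy_matrix()  # m1: AA/AB/BB, m2: AA/AB, m3: CC
  ct <- build_class_table(toy)
  expect_equal(coverage(c("s1", "s2", "s3", "s4"), toy, ct), 1)
  expect_equal(coverage(character(0), toy, ct), 0)
  # s1+s3: m1 covers AA,BB (2/3); m2 covers AA,AB (2/2); m3 covers CC (1/1)
  expect_equal(coverage(c("s1", "s3"), toy, ct), (2 / 3 + 1 + 1) / 3)
  # two-marker closed forms: cover 1 of 3 + 2 of 2 -> 2/3; 2 of 3 + 2 of 2 -> 5/6
  two <- genotype_matrix(matrix(
    c("AA", "AB", "BB",
      "AA", "AB", "AA"), nrow = 2, byrow = TRUE,
    dimnames = list(c("m1", "m2"), c("s1", "s2", "s3"))))
  tt <- build_class_table(two)
  expect_equal(coverage(c("s1", "s2"), two, tt), (2 / 3 + 1) / 2)
  expect_equal(coverage("s2", two, tt), (1 / 3 + 1 / 2) / 2)
  expect_equal(coverage(c("s1", "s2"), two, tt),
               coverage_by_definition(1:2, two), tolerance = 1e-12)
})

test_that("coverage is monotone under core growth and bounded in [0, 1]", {
  for (seed in 1:5) {
    gm <- random_panel(20, 15, missing_rate = 0.15, seed = seed)
    ct <- build_class_table(gm)
    set.seed(seed + 100)
    perm <- sample(ncol(gm))
    cvs <- vapply(seq_along(perm), function(k) {
      coverage(perm[seq_len(k)], gm, ct)
    }, numeric(1))
    expect_true(all(diff(cvs) >= -1e-12))
    expect_true(all(cvs >= 0 & cvs <= 1 + 1e-12))
    expect_equal(cvs[length(cvs)], 1)
  }
})

test_that("base-c Shannon index matches closed forms", {
  # e=2 marker under different core compositions
  gm <- genotype_matrix(matrix(
    c("AA", "AA", "BB", "BB", "AA", "AA", "AA", "AA", "BB", "BB"),
    nrow = 1, dimnames = list("m1", paste0("s", 1:10))))
  ct <- build_class_table(gm)
  expect_equal(shannon_index(c("s1", "s3"), gm, ct)$sh, 1)      # 0.5/0.5
  expect_equal(shannon_index(c("s1", "s2"), gm, ct)$sh, 0)      # 1.0/0.0
  # proportions (0.8, 0.2): -(0.8 log2 0.8 + 0.2 log2 0.2)
  core <- c("s1", "s2", "s5", "s6", "s3")  # 4 AA, 1 BB
  expect_equal(shannon_index(core, gm, ct)$sh, 0.7219280948873623,
               tolerance = 1e-12)
  # monomorphic marker scores 1 by default, is dropped with "exclude"
  toy <- toy_matrix()
  ct2 <- build_class_table(toy)
  full <- colnames(toy)
  sh <- shannon_index(full, toy, ct2)
  expect_equal(unname(sh$per_marker["m3"]), 1)
  sh_ex <- shannon_index(full, toy, ct2, monomorphic = "exclude")
  expect_equal(sh_ex$sh, mean(sh$per_marker[c("m1", "m2")]))
  expect_true(all(sh$per_marker >= 0 & sh$per_marker <= 1))
})

test_that("modified Rogers distance has the closed-form pair values", {
  gm <- genotype_matrix(matrix(c("AA", "BB", "AB", "AA"), nrow = 1,
                               dimnames = list("m1", paste0("s", 1:4))))
  expect_equal(modified_rogers_pair("s1", "s2", gm), 1)    # AA vs BB
  expect_equal(modified_rogers_pair("s1", "s3", gm), 0.5)  # AA vs AB
  expect_equal(modified_rogers_pair("s1", "s4", gm), 0)    # identical
  expect_equal(modified_rogers_pair("s2", "s3", gm), 0.5)  # BB vs AB
  # one-token labels: different labels contribute the maximal 2 * 1^2
  g2 <- genotype_matrix(matrix(c("X", "Y"), nrow = 1,
                               dimnames = list("m1", c("s1", "s2"))))
  expect_equal(modified_rogers_pair("s1", "s2", g2), 1)
})

test_that("modified Rogers is a bounded metric and pairs drop missing markers", {
  for (seed in 1:5) {
    gm <- random_panel(12, 8, missing_rate = 0.2, seed = seed + 10)
    n <- ncol(gm)
    D <- matrix(0, n, n)
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      D[a, b] <- D[b, a] <- modified_rogers_pair(a, b, gm)
    }
    expect_true(all(D >= 0 & D <= 1 + 1e-12))
    expect_equal(D, t(D))
  }
  # identical call vectors at distance 0
  gm <- genotype_matrix(matrix(c("AA", "AA", "AB", "AB"), nrow = 2,
                               byrow = TRUE,
                               dimnames = list(c("m1", "m2"),
                                               c("s1", "s2"))))
  expect_equal(modified_rogers_pair("s1", "s2", gm), 0)
  # no shared non-missing marker -> incomparable
  g3 <- genotype_matrix(matrix(c("AA", NA, NA, "BB"), nrow = 2,
                               dimnames = list(c("m1", "m2"),
                                               c("s1", "s2"))))
  expect_error(modified_rogers_pair("s1", "s2", g3), "no marker")
})

test_that("mean modified Rogers equals the mean of enumerated pairs", {
  # three accessions with pairwise distances {1, 1, 0}
  gm <- genotype_matrix(matrix(c("AA", "BB", "AA"), nrow = 1,
                               dimnames = list("m1", c("s1", "s2", "s3"))))
  expect_equal(mean_modified_rogers(c("s1", "s2", "s3"), gm), 2 / 3,
               tolerance = 1e-12)
  expect_error(mean_modified_rogers("s1", gm), "two")
  # duplicated profiles -> 0
  g2 <- genotype_matrix(matrix(rep(c("AA", "AB"), 4), nrow = 2,
                               dimnames = list(c("m1", "m2"),
                                               paste0("s", 1:4))))
  expect_equal(mean_modified_rogers(paste0("s", 1:4), g2), 0)
  # vectorized all-pairs route agrees with the per-pair definition
  for (seed in 1:4) {
    gm <- random_panel(15, 9, missing_rate = 0.15, seed = seed + 30)
    idx <- 1:9
    pairwise <- combn(idx, 2, function(p) {
      modified_rogers_pair(p[1], p[2], gm)
    })
    expect_equal(mean_modified_rogers(idx, gm), mean(pairwise),
                 tolerance = 1e-12)
  }
})

test_that("rarity score follows the odds-inverse definition and is additive", {
  gm <- make_worked_toy()
  ct <- build_class_table(gm)
  # the A-carrier's focal-marker term is (1 - 0.05)/0.05 = 19
  a_carrier <- "ACC0001"
  drop_focal <- gm[-1, , drop = FALSE]
  rs_full <- rarity_score(a_carrier, gm, ct)
  rs_rest <- rarity_score(a_carrier, drop_focal, build_class_table(drop_focal))
  expect_equal(rs_full - rs_rest, 19, tolerance = 1e-12)

  # monomorphic-everywhere profile scores 0
  mono <- genotype_matrix(matrix("AA", 3, 2,
                                 dimnames = list(paste0("m", 1:3),
                                                 c("s1", "s2"))))
  expect_equal(rarity_score("s1", mono, build_class_table(mono)), 0)

  # single 50/50 marker, everything else missing -> RS = 1
  calls <- matrix(c("AA", "BB", NA, "AA"), nrow = 2, byrow = TRUE,
                  dimnames = list(c("m1", "m2"), c("s1", "s2")))
  g2 <- genotype_matrix(calls)
  expect_equal(rarity_score("s1", g2, build_class_table(g2)), 1 + 0)

  # additivity: RS equals the sum of per-marker terms
  gm3 <- random_panel(10, 6, missing_rate = 0.2, seed = 77)
  ct3 <- build_class_table(gm3)
  rs_all <- rarity_score(3, gm3, ct3)
  terms <- vapply(seq_len(nrow(gm3)), function(i) {
    sub <- gm3[i, , drop = FALSE]
    rarity_score(3, sub, build_class_table(sub))
  }, numeric(1))
  expect_equal(rs_all, sum(terms), tolerance = 1e-12)
})

test_that("optimized metrics equal per-definition recomputation to 1e-12", {
  for (seed in 1:6) {
    gm <- random_panel(20, 15, missing_rate = 0.15, seed = seed + 200)
    ct <- build_class_table(gm)
    set.seed(seed)
    core <- sample(15, sample(2:10, 1))
    expect_equal(coverage(core, gm, ct), coverage_by_definition(core, gm),
                 tolerance = 1e-12)
    expect_equal(shannon_index(core, gm, ct)$sh,
                 shannon_by_definition(core, gm), tolerance = 1e-12)
    for (a in sample(15, 3)) {
      expect_equal(unname(rarity_score(a, gm, ct)),
                   rarity_by_definition(a, gm), tolerance = 1e-12)
    }
  }
})

test_that("rarest-class proportions compare entire collection and core", {
  gm <- make_worked_toy()
  ct <- build_class_table(gm)
  props <- rarest_allele_props(worked_toy_core(), gm, ct)
  focal <- props[props$marker_id == "M_focal", ]
  expect_equal(focal$prop_entire, 0.05)
  expect_equal(focal$prop_core, 0.10)  # 1 A among 10 core calls
  # a core lacking the rarest class scores 0 there
  no_a <- rarest_allele_props(sprintf("ACC%04d", 6:15), gm, ct)
  expect_equal(no_a$prop_core[no_a$marker_id == "M_focal"], 0)
  # core = entire collection: both proportions agree at every marker
  all_props <- rarest_allele_props(colnames(gm), gm, ct)
  expect_equal(all_props$prop_core, all_props$prop_entire, tolerance = 1e-12)
})

test_that("evaluate_core assembles a consistent report", {
  gm <- make_worked_toy()
  ct <- build_class_table(gm)
  rep_full <- evaluate_core(colnames(gm), gm, ct)
  expect_equal(rep_full$cv, 1)
  expect_true(rep_full$mr_available)
  expect_true(all(c(rep_full$cv, rep_full$sh, rep_full$mr) >= 0))
  expect_true(all(c(rep_full$cv, rep_full$sh, rep_full$mr) <= 1))
  expect_gte(rep_full$rs_mean, 0)
  expect_equal(rep_full$rs_log, log(rep_full$rs_mean))

  singleton <- evaluate_core("ACC0001", gm, ct)
  expect_false(singleton$mr_available)
  expect_true(is.na(singleton$mr))
  expect_identical(nrow(singleton$per_marker_rarest_prop), nrow(gm))
})
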