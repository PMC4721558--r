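test_that("pair assembly respects the missing-data bookkeeping", {
  ds <- fixture()
  er <- build_pairs(ds, "er")
  expect_equal(nrow(er$pairs), 30)
  expect_equal(er$n_total_cases, 30)
  expect_equal(er$n_complete, 29)  # one absent panel

  her2 <- build_pairs(ds, "her2", coding = "reliability-binary")
  expect_equal(her2$n_complete, 27)  # absent panel + two no-tissue HER2 cells
  expect_setequal(unique(stats::na.omit(c(her2$pairs$tma1, her2$pairs$tma2))),
                  c("pos", "neg"))

  ki67 <- build_pairs(ds, "ki67")
  expect_equal(ki67$pairs$tma2[ki67$pairs$case_id == "6-27"], "high")  # 14.0%
  expect_equal(ki67$pairs$tma1[ki67$pairs$case_id == "6-27"], "low")   # 13.3%

  expect_error(build_pairs(ds, "ck5/6"), "unknown target")

  empty <- study_dataset(ds$cases[0, ], ds$panels[0, ])
  expect_equal(nrow(build_pairs(empty, "er")$pairs), 0)
})

test_that("concordance counts a case discordant only on two definite calls", {
  ds <- fixture()
  expect_equal(percent_concordance(build_pairs(ds, "er"))$percent, 100)
  ki <- percent_concordance(build_pairs(ds, "ki67"))
  expect_equal(ki$percent, 90)
  expect_equal(ki$n_discordant, 3)

  one <- make_pair_set("pos", "neg")
  expect_equal(percent_concordance(one)$percent, 0)
  # a missing member never counts discordant
  half <- make_pair_set(c("pos", NA), c("neg", "neg"))
  expect_equal(percent_concordance(half)$n_discordant, 1)
  expect_equal(percent_concordance(half)$percent, 50)
  expect_error(percent_concordance(make_pair_set(character(0), character(0))),
               "empty")
  # display rounding is half-up: 26/30 concordant prints 87, not 86
  ps <- make_pair_set(c(rep("a", 26), rep("a", 4)),
                      c(rep("a", 26), rep("b", 4)))
  expect_equal(percent_concordance(ps)$percent, 87)
})

test_that("fixture contingency tables match the hand recount", {
  ds <- fixture()
  her2 <- contingency_table(build_pairs(ds, "her2",
                                        coding = "reliability-binary"))
  expect_equal(her2[c("pos", "neg"), c("pos", "neg")],
               matrix(c(7L, 0L, 1L, 19L), 2, 2,
                      dimnames = list(c("pos", "neg"), c("pos", "neg"))))
  ki67 <- contingency_table(build_pairs(ds, "ki67"))
  expect_equal(ki67[c("high", "low"), c("high", "low")],
               matrix(c(1L, 1L, 2L, 25L), 2, 2,
                      dimnames = list(c("high", "low"), c("high", "low"))))
})

test_that("kappa agrees with a brute-force double-loop oracle", {
  set.seed(7)
  for (rep in 1:1000) {
    k <- sample(2:4, 1)
    ct <- random_square_table(k)
    got <- cohen_kappa(ct)
    want <- brute_force_kappa(ct)
    if (is.na(want)) {
      expect_false(got$kappa_defined)
    } else {
      expect_equal(got$kappa, want, tolerance = 1e-12)
    }
  }
})

test_that("kappa respects its analytic bounds and invariances", {
  set.seed(21)
  for (rep in 1:200) {
    ct <- random_square_table(sample(2:4, 1))
    res <- cohen_kappa(ct)
    if (!res$kappa_defined) next
    expect_lte(res$kappa, res$p_observed + 1e-12)
    expect_lte(res$kappa, 1)
    expect_gte(res$kappa, -1)
    off_mass <- sum(ct) - sum(diag(ct))
    expect_equal(res$kappa == 1, off_mass == 0 && res$p_expected < 1)
    # consistent relabeling of both margins leaves kappa unchanged
    perm <- sample(nrow(ct))
    expect_equal(cohen_kappa(ct[perm, perm])$kappa, res$kappa,
                 tolerance = 1e-12)
  }
  # perfect agreement over >= 2 occupied diagonal cells
  expect_equal(cohen_kappa(diag(c(5L, 3L)))$kappa, 1)
  # all mass in one cell: agreement indistinguishable from chance
  deg <- cohen_kappa(matrix(c(12L, 0L, 0L, 0L), 2, 2))
  expect_false(deg$kappa_defined)
  expect_error(kappa_ci(deg), "undefined")
  expect_error(cohen_kappa(matrix(0L, 2, 2)), "empty")
  expect_error(cohen_kappa(matrix(1L, 2, 3)), "square")
})

test_that("asymptotic standard errors match the reference values", {
  # reference kappa/SE computed independently with the large-sample
  # (Fleiss-Cohen-Everitt) variance for these tables
  cases <- list(
    list(ct = matrix(c(7, 1, 0, 19), 2, 2, byrow = TRUE),
         kappa = 0.907850, se = 0.090043, ci = c(0.731369, 1.000000)),
    list(ct = matrix(c(1, 2, 1, 25), 2, 2, byrow = TRUE),
         kappa = 0.345865, se = 0.291042, ci = c(-0.224567, 0.916296)),
    list(ct = matrix(c(2, 1, 1, 25), 2, 2, byrow = TRUE),
         kappa = 0.628205, se = 0.241536, ci = c(0.154804, 1.000000)),
    list(ct = matrix(c(2, 1, 0, 26), 2, 2, byrow = TRUE),
         kappa = 0.781955, se = 0.209098, ci = c(0.372131, 1.000000)),
    list(ct = matrix(c(16, 1, 1, 11), 2, 2, byrow = TRUE),
         kappa = 0.857843, se = 0.096961, ci = c(0.667804, 1.000000)),
    list(ct = matrix(c(10, 2, 1, 0, 5, 3, 2, 1, 6), 3, 3, byrow = TRUE),
         kappa = 0.542373, se = 0.125395, ci = c(0.296604, 0.788142))
  )
  for (cs in cases) {
    ar <- kappa_ci(cohen_kappa(cs$ct))
    expect_equal(ar$kappa, cs$kappa, tolerance = 1e-5)
    expect_equal(ar$se, cs$se, tolerance = 1e-5)
    expect_equal(c(ar$ci_low, ar$ci_high), cs$ci, tolerance = 1e-5)
  }
})

test_that("the dichotomized Ki67 interval straddles zero despite 90% concordance", {
  ds <- fixture()
  ar <- kappa_ci(cohen_kappa(build_pairs(ds, "ki67")))
  expect_lt(ar$ci_low, 0)
  expect_gt(ar$ci_high, ar$kappa)
  expect_lt(ar$kappa, 0.4)  # fair agreement only, from low prevalence
  expect_equal(percent_concordance(build_pairs(ds, "ki67"))$percent, 90)
})

test_that("bootstrap intervals are reproducible and bounded", {
  ds <- fixture()
  ar <- cohen_kappa(build_pairs(ds, "her2", coding = "reliability-binary"))
  b1 <- kappa_ci(ar, method = "bootstrap", n_boot = 500, seed = 13)
  b2 <- kappa_ci(ar, method = "bootstrap", n_boot = 500, seed = 13)
  expect_equal(c(b1$ci_low, b1$ci_high), c(b2$ci_low, b2$ci_high))
  expect_gte(b1$ci_low, -1)
  expect_lte(b1$ci_high, 1)
  expect_error(kappa_ci(ar, method = "bootstrap", n_boot = 50), ">= 100")
  # a plain table has no pair-level data to resample
  expect_error(kappa_ci(cohen_kappa(matrix(c(7, 1, 0, 19), 2, 2)),
                        method = "bootstrap"), "pair-level")
})

test_that("bootstrap coverage is near nominal on simulated pair sets", {
  # two replicate raters with joint cell probabilities [[.4,.1],[.1,.4]]:
  # true kappa = (0.8 - 0.5) / (1 - 0.5) = 0.6
  set.seed(31)
  true_kappa <- 0.6
  hits <- 0
  n_sim <- 120
  for (s in 1:n_sim) {
    cells <- sample(1:4, 60, replace = TRUE, prob = c(0.4, 0.1, 0.1, 0.4))
    tma1 <- c("a", "a", "b", "b")[cells]
    tma2 <- c("a", "b", "a", "b")[cells]
    ar <- cohen_kappa(make_pair_set(tma1, tma2))
    if (!ar$kappa_defined) next
    ci <- kappa_ci(ar, method = "bootstrap", level = 0.90, n_boot = 200,
                   seed = s)
    if (ci$ci_low <= true_kappa && true_kappa <= ci$ci_high) hits <- hits + 1
  }
  coverage <- hits / n_sim
  expect_gt(coverage, 0.78)
  expect_lt(coverage, 0.99)
})

test_that("the reliability report carries every target with its conventions", {
  rep <- reliability_report(fixture())
  expect_equal(nrow(rep), 9)  # 7 stains + phenotype under both sources
  expect_true(all(c("er", "pr", "her2", "ck56", "egfr", "ki67") %in%
                  rep$target))
  er <- rep[rep$target == "er", ]
  expect_equal(er$concordance_pct, 100)
  expect_equal(er$kappa, 1)
  expect_equal(rep$n_pairs_kappa[rep$target == "her2"], 27)
  expect_equal(rep$kappa[rep$target == "egfr"], 0.782, tolerance = 5e-4)
  expect_equal(rep$kappa[rep$target == "ck56"], 0.628, tolerance = 5e-4)
  # PR from these panel columns: 0.858 under the documented conventions
  expect_equal(rep$kappa[rep$target == "pr"], 0.858, tolerance = 5e-4)
  expect_true(all(grepl("kappa:", rep$convention)))
})
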