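panel <- function(er = "neg", pr = "neg", her2 = "neg", ck56 = "neg",
                  egfr = "neg", ki67 = 5) {
  list(er = er, pr = pr, her2 = her2, ck56 = ck56, egfr = egfr,
       ki67_percent = ki67)
}

test_that("classifier reproduces the reference panel calls", {
  # hormone-receptor positive with HER2 3+ is Luminal B regardless of Ki67
  expect_equal(classify(panel(er = "pos", pr = "pos", her2 = "3+",
                              ki67 = 9))$kind, "LuminalB")
  # triple negative without basal markers is unclassifiable
  expect_equal(classify(panel(ki67 = 12.3))$kind, "Unclassifiable")
  # HER2 2+ counts as negative for classification: basal markers decide
  expect_equal(classify(panel(her2 = "2+", ck56 = "pos", egfr = "pos"))$kind,
               "BasalLike")
  # HR+, HER2-, Ki67 over the cutoff is Luminal B
  expect_equal(classify(panel(er = "pos", pr = "pos", ki67 = 16.3))$kind,
               "LuminalB")
  # HR+, HER2 missing, low Ki67: Luminal A under HER2-, B under HER2+
  amb <- classify(panel(er = "pos", pr = "pos", her2 = NA, ki67 = 8.3))
  expect_equal(amb$kind, "Ambiguous")
  expect_equal(amb$candidates, c("LuminalA", "LuminalB"))
  # no information at all
  expect_equal(classify(panel(er = NA, pr = NA, her2 = NA, ck56 = NA,
                              egfr = NA, ki67 = NA))$kind, "Unknown")
})

test_that("Ki67 boundary value counts as high", {
  expect_equal(classify(panel(er = "pos", ki67 = 14.0))$kind, "LuminalB")
  expect_equal(classify(panel(er = "pos", ki67 = 13.9))$kind, "LuminalA")
  rules20 <- phenotype_rules(ki67_cutoff = 20)
  expect_equal(classify(panel(er = "pos", ki67 = 14.0), rules20)$kind,
               "LuminalA")
})

test_that("exactly one branch fires for every complete panel", {
  cutoff <- phenotype_rules()$ki67_cutoff
  grid <- expand.grid(er = c("pos", "neg"), pr = c("pos", "neg"),
                      her2 = c("neg", "1+", "2+", "3+"),
                      ck56 = c("pos", "neg"), egfr = c("pos", "neg"),
                      ki67 = c(cutoff - 0.1, cutoff),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    call <- classify(panel(g$er, g$pr, g$her2, g$ck56, g$egfr, g$ki67))
    expect_true(call$kind %in% c("LuminalA", "LuminalB", "HER2", "BasalLike",
                                 "Unclassifiable"))
    expect_length(call$candidates, 0)
    # agrees with the rule table written out independently
    expect_equal(call$kind,
                 oracle_subtype(g$er, g$pr,
                                if (g$her2 == "3+") "pos" else "neg",
                                g$ck56, g$egfr, g$ki67 >= cutoff))
  }
})

test_that("missing markers resolve by completion enumeration", {
  set.seed(99)
  cutoff <- phenotype_rules()$ki67_cutoff
  lv <- c("pos", "neg", NA)
  for (rep in 1:300) {
    er <- sample(lv, 1)
    pr <- sample(lv, 1)
    her2 <- sample(c("neg", "1+", "2+", "3+", NA), 1)
    ck56 <- sample(lv, 1)
    egfr <- sample(lv, 1)
    ki67 <- if (runif(1) < 0.3) NA else round(runif(1, 0, 30), 1)
    got <- classify(panel(er, pr, her2, ck56, egfr, ki67))
    want <- oracle_classify(
      er, pr,
      if (is.na(her2)) NA else if (her2 == "3+") "pos" else "neg",
      ck56, egfr,
      if (is.na(ki67)) NA else ki67 >= cutoff)
    expect_equal(got$kind, want$kind)
    if (want$kind == "Ambiguous") {
      expect_equal(got$candidates, want$candidates)
    }
  }
})

test_that("enlarging the HER2-positive set only moves calls along HER2 axes", {
  strict <- phenotype_rules(her2_positive_levels = "3+")
  loose <- phenotype_rules(her2_positive_levels = c("2+", "3+"))
  grid <- expand.grid(er = c("pos", "neg"), pr = c("pos", "neg"),
                      her2 = c("neg", "1+", "2+", "3+"),
                      ck56 = c("pos", "neg"), egfr = c("pos", "neg"),
                      ki67 = c(5, 20), stringsAsFactors = FALSE)
  allowed <- list(
    LuminalA = c("LuminalA", "LuminalB"),
    LuminalB = "LuminalB",
    BasalLike = c("BasalLike", "HER2"),
    Unclassifiable = c("Unclassifiable", "HER2"),
    HER2 = "HER2"
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    a <- classify(panel(g$er, g$pr, g$her2, g$ck56, g$egfr, g$ki67), strict)
    b <- classify(panel(g$er, g$pr, g$her2, g$ck56, g$egfr, g$ki67), loose)
    expect_true(b$kind %in% allowed[[a$kind]])
  }
})

test_that("rules validate their arguments", {
  expect_error(phenotype_rules(ki67_cutoff = 0), "ki67_cutoff")
  expect_error(phenotype_rules(her2_positive_levels = "2+"), "upward-closed")
  expect_error(phenotype_rules(her2_positive_levels = "4+"), "drawn from")
  expect_silent(phenotype_rules(her2_positive_levels = c("1+", "2+", "3+")))
})

test_that("dataset classification yields one call per scored panel", {
  ds <- fixture()
  calls <- classify_dataset(ds)
  expect_equal(nrow(calls), 59)  # one panel is entirely missing
  expect_equal(sum(calls$tma_id == "TMA1"), 29)
  expect_equal(sum(calls$tma_id == "TMA2"), 30)
  empty <- classify_dataset(study_dataset(ds$cases[0, ], ds$panels[0, ]))
  expect_equal(nrow(empty), 0)
})

test_that("phenotype labels parse and format consistently", {
  calls <- parse_phenotype_label(c("Luminal A", "HER 2", "Basal-like",
                                   "Luminal A or Luminal B", NA))
  expect_equal(calls[[1]]$kind, "LuminalA")
  expect_equal(calls[[2]]$kind, "HER2")
  expect_equal(calls[[3]]$kind, "BasalLike")
  expect_equal(calls[[4]]$kind, "Ambiguous")
  expect_equal(calls[[4]]$candidates, c("LuminalA", "LuminalB"))
  expect_null(calls[[5]])
  expect_equal(format_phenotype(calls[[4]]), "Luminal A or Luminal B")
  expect_error(parse_phenotype_label("Luminal C"), "unrecognized")
})
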