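# Independent oracles and random-input generators for property tests.

# Cohen's kappa by explicit double loops over categories (no matrix algebra),
# kept deliberately naive and separate from the package implementation.
brute_force_kappa <- function(ct) {
  k <- nrow(ct)
  n <- sum(ct)
  agree <- 0
  for (i in seq_len(k)) agree <- agree + ct[i, i]
  po <- agree / n
  pe <- 0
  for (i in seq_len(k)) {
    row_i <- 0
    col_i <- 0
    for (j in seq_len(k)) {
      row_i <- row_i + ct[i, j]
      col_i <- col_i + ct[j, i]
    }
    pe <- pe + (row_i / n) * (col_i / n)
  }
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

random_square_table <- function(k, n_max = 60) {
  n <- sample(seq(k * k, n_max), 1)
  counts <- as.vector(stats::rmultinom(1, n, prob = stats::runif(k * k)))
  matrix(counts, k, k)
}

# Surrogate-subtype rule table written directly from the published algorithm,
# independent of the package's classifier internals. Inputs are "pos"/"neg"
# and a logical for high Ki67.
oracle_subtype <- function(er, pr, her2, ck56, egfr, ki67_high) {
  if (er == "pos" || pr == "pos") {
    if (her2 == "pos") return("LuminalB")
    if (ki67_high) return("LuminalB") else return("LuminalA")
  }
  if (her2 == "pos") return("HER2")
  if (ck56 == "pos" || egfr == "pos") return("BasalLike")
  "Unclassifiable"
}

# Enumerate every completion of a possibly-missing panel with nested loops.
oracle_classify <- function(er, pr, her2_bin, ck56, egfr, ki67_high) {
  if (is.na(er) && is.na(pr)) return(list(kind = "Unknown"))
  lv <- function(x) if (is.na(x)) c("pos", "neg") else x
  kv <- if (is.na(ki67_high)) c(TRUE, FALSE) else ki67_high
  kinds <- character(0)
  for (a in lv(er)) for (b in lv(pr)) for (h in lv(her2_bin))
    for (c5 in lv(ck56)) for (e in lv(egfr)) for (k in kv) {
      kinds <- c(kinds, oracle_subtype(a, b, h, c5, e, k))
    }
  kinds <- unique(kinds)
  if (length(kinds) == 1) list(kind = kinds) else
    list(kind = "Ambiguous", candidates = sort(kinds))
}

# Random valid study dataset for round-trip properties.
random_dataset <- function(n_cases = 8) {
  years <- sample(1947:2009, n_cases, replace = TRUE)
  cases <- data.frame(
    case_id = sprintf("C%02d", seq_len(n_cases)),
    year = years,
    histology = sample(c("IDC", "Invasive lobular carcinoma",
                         "Mixed IDC and mucinous carcinoma"),
                       n_cases, replace = TRUE),
    grade = sample(1:3, n_cases, replace = TRUE),
    stringsAsFactors = FALSE
  )
  rand_call <- function(n) sample(c("pos", "neg", NA), n, replace = TRUE,
                                  prob = c(0.5, 0.4, 0.1))
  rand_her2 <- function(n) sample(c("neg", "1+", "2+", "3+", NA), n,
                                  replace = TRUE,
                                  prob = c(0.5, 0.1, 0.15, 0.15, 0.1))
  one_tma <- function(tma) {
    data.frame(
      case_id = cases$case_id, tma_id = tma,
      ck_cocktail = rand_call(n_cases), er = rand_call(n_cases),
      pr = rand_call(n_cases), her2 = rand_her2(n_cases),
      ck56 = rand_call(n_cases), egfr = rand_call(n_cases),
      ki67_percent = ifelse(stats::runif(n_cases) < 0.1, NA,
                            round(stats::runif(n_cases, 0, 40), 1)),
      printed_phenotype = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  panels <- rbind(one_tma("TMA1"), one_tma("TMA2"))
  # occasionally blank out a whole panel (an absent array result)
  if (stats::runif(1) < 0.5) {
    i <- sample(nrow(panels), 1)
    panels[i, c("ck_cocktail", "er", "pr", "her2", "ck56", "egfr")] <- NA
    panels$ki67_percent[i] <- NA
  }
  study_dataset(cases, panels)
}

expect_dataset_equal <- function(a, b) {
  norm <- function(d) {
    rownames(d$cases) <- NULL
    rownames(d$panels) <- NULL
    d
  }
  a <- norm(a)
  b <- norm(b)
  expect_equal(a$cases[order(a$cases$case_id), ],
               b$cases[order(b$cases$case_id), ],
               ignore_attr = TRUE)
  key <- function(p) order(p$case_id, p$tma_id)
  expect_equal(a$panels[key(a$panels), ], b$panels[key(b$panels), ],
               ignore_attr = TRUE)
}

fixture <- function() read_dataset(tma_fixture_path())

# minimal pair_set wrapper so agreement functions can be driven with
# synthetic pair tables
make_pair_set <- function(tma1, tma2, target = "sim") {
  pairs <- data.frame(case_id = sprintf("P%d", seq_along(tma1)),
                      tma1 = tma1, tma2 = tma2, stringsAsFactors = FALSE)
  structure(list(target = target, coding = NA_character_, policy = "test",
                 pairs = pairs, n_total_cases = nrow(pairs),
                 n_complete = sum(!is.na(tma1) & !is.na(tma2))),
            class = "pair_set")
}
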