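# Test-retest agreement between duplicate TMAs -------------------------------

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

RELIABILITY_TARGETS <- c("ck_cocktail", "er", "pr", "her2", "ck56", "egfr",
                         "ki67", "phenotype")

#' Assemble per-case TMA1/TMA2 call pairs for one target
#'
#' Builds one pair per case. Codings:
#' \describe{
#'   \item{binary markers}{`pos`/`neg` calls taken as stored.}
#'   \item{`her2`, `coding = "ordinal"`}{the reported stain categories, so a
#'     `2+` vs `neg` pair differs while `2+` vs `2+` agrees.}
#'   \item{`her2`, `coding = "reliability-binary"`}{`2+` and `3+` map to
#'     positive, `neg` and `1+` to negative. This is the coding under which
#'     duplicate arrays are compared as positive-vs-negative stain results;
#'     it is deliberately distinct from the classifier's HER2-positive set
#'     (`3+` only).}
#'   \item{`ki67`}{percent dichotomized at the rules cutoff (boundary counts
#'     high).}
#'   \item{`phenotype`}{calls coded by display label; `Unknown` is treated as
#'     missing and an ambiguous-set call is a definite category of its own,
#'     differing from any non-identical call. `source = "classifier"` uses
#'     [classify_dataset()]; `source = "printed"` uses the phenotype labels
#'     carried in the table (the as-published calls).}
#' }
#'
#' @param ds A `tma_study`.
#' @param target One of `ck_cocktail`, `er`, `pr`, `her2`, `ck56`, `egfr`,
#'   `ki67`, `phenotype`.
#' @param coding For `her2` only: `"ordinal"` (default) or
#'   `"reliability-binary"`.
#' @param rules [phenotype_rules()]; supplies the Ki67 cutoff and the
#'   classifier conventions.
#' @param source For `phenotype` only: `"classifier"` (default) or
#'   `"printed"`.
#' @return A `pair_set`: list with `target`, `coding`, `policy`, `pairs`
#'   (data frame `case_id`, `tma1`, `tma2`), `n_total_cases`, `n_complete`.
#' @export
#' @examples
#' ds <- read_dataset(tma_fixture_path())
#' build_pairs(ds, "er")
build_pairs <- function(ds, target,
                        coding = c("ordinal", "reliability-binary"),
                        rules = phenotype_rules(),
                        source = c("classifier", "printed")) {
  coding <- match.arg(coding)
  source <- match.arg(source)
  if (!target %in% RELIABILITY_TARGETS) {
    stop("unknown target '", target, "'; expected one of ",
         paste(RELIABILITY_TARGETS, collapse = ", "), call. = FALSE)
  }
  ids <- ds$cases$case_id
  get_panel_value <- function(id, tma) {
    row <- ds$panels[ds$panels$case_id == id & ds$panels$tma_id == tma, ]
    if (nrow(row) == 0) return(NA_character_)
    code_panel(row, target, coding, rules)
  }
  policy <- target_policy(target, coding, rules, source)

  if (target == "phenotype") {
    if (source == "classifier") {
      calls <- classify_dataset(ds, rules)
      lookup <- function(id, tma) {
        hit <- calls$case_id == id & calls$tma_id == tma
        if (!any(hit)) return(NA_character_)
        if (calls$kind[hit] == "Unknown") return(NA_character_)
        calls$label[hit]
      }
    } else {
      lookup <- function(id, tma) {
        row <- ds$panels[ds$panels$case_id == id & ds$panels$tma_id == tma, ]
        if (nrow(row) == 0 || is.na(row$printed_phenotype)) {
          return(NA_character_)
        }
        call <- parse_phenotype_label(row$printed_phenotype)[[1]]
        if (call$kind == "Unknown") return(NA_character_)
        format_phenotype(call)
      }
    }
    tma1 <- vapply(ids, lookup, character(1), tma = "TMA1")
    tma2 <- vapply(ids, lookup, character(1), tma = "TMA2")
  } else {
    tma1 <- vapply(ids, get_panel_value, character(1), tma = "TMA1")
    tma2 <- vapply(ids, get_panel_value, character(1), tma = "TMA2")
  }

  pairs <- data.frame(case_id = ids, tma1 = unname(tma1),
                      tma2 = unname(tma2), stringsAsFactors = FALSE)
  structure(list(
    target = target, coding = if (target == "her2") coding else NA_character_,
    policy = policy, pairs = pairs,
    n_total_cases = length(ids),
    n_complete = sum(!is.na(pairs$tma1) & !is.na(pairs$tma2))
  ), class = "pair_set")
}

code_panel <- function(row, target, coding, rules) {
  switch(target,
    her2 = {
      if (coding == "reliability-binary") {
        if (is.na(row$her2)) NA_character_
        else if (row$her2 %in% c("2+", "3+")) "pos" else "neg"
      } else {
        as.character(row$her2)
      }
    },
    ki67 = {
      k <- row$ki67_percent
      if (is.na(k)) NA_character_
      else if (k >= rules$ki67_cutoff) "high" else "low"
    },
    as.character(row[[target]])
  )
}

target_policy <- function(target, coding, rules, source) {
  switch(target,
    her2 = if (coding == "reliability-binary")
      "HER2 {2+,3+}=positive, {neg,1+}=negative" else
      "HER2 compared on reported stain categories",
    ki67 = sprintf("Ki67 dichotomized at %g%% (boundary high)",
                   rules$ki67_cutoff),
    phenotype = sprintf(
      "%s calls; Unknown = missing; ambiguous set = distinct definite category",
      source),
    "calls as stored"
  )
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> target=%s  n=%d cases, %d complete pairs\n",
              x$target, x$n_total_cases, x$n_complete))
  cat("  policy:", x$policy, "\n")
  invisible(x)
}

#' Percent concordance between duplicate TMAs
#'
#' Concordance is computed over all cases: a case counts as discordant only
#' when both calls are definite and differ, so a pair with a missing member
#' is never discordant. The denominator is the number of cases, not the
#' number of complete pairs.
#'
#' @param ps A [build_pairs()] result.
#' @return List with `percent` (integer-rounded, half-up), `raw` (unrounded
#'   percent), `n_discordant`, `n_total_cases`.
#' @export
#' @examples
#' ds <- read_dataset(tma_fixture_path())
#' percent_concordance(build_pairs(ds, "er"))$percent
percent_concordance <- function(ps) {
  if (ps$n_total_cases == 0) stop("empty pair set", call. = FALSE)
  p <- ps$pairs
  disc <- !is.na(p$tma1) & !is.na(p$tma2) & p$tma1 != p$tma2
  raw <- 100 * (ps$n_total_cases - sum(disc)) / ps$n_total_cases
  list(percent = round_half_up(raw), raw = raw,
       n_discordant = sum(disc), n_total_cases = ps$n_total_cases)
}

#' Contingency table of complete pairs
#'
#' Square table over the union of categories seen in either margin
#' (complete pairs only).
#'
#' @param ps A [build_pairs()] result.
#' @return Integer matrix with TMA1 categories in rows, TMA2 in columns.
#' @export
contingency_table <- function(ps) {
  p <- ps$pairs
  keep <- !is.na(p$tma1) & !is.na(p$tma2)
  p <- p[keep, , drop = FALSE]
  cats <- sort(unique(c(p$tma1, p$tma2)))
  ct <- matrix(0L, length(cats), length(cats), dimnames = list(cats, cats))
  for (i in seq_len(nrow(p))) {
    ct[p$tma1[i], p$tma2[i]] <- ct[p$tma1[i], p$tma2[i]] + 1L
  }
  ct
}

#' Unweighted Cohen's kappa
#'
#' Chance-corrected agreement for a square contingency table of complete
#' pairs: `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed
#' agreement proportion and `p_e` the chance agreement implied by the
#' marginals. When all mass sits in a single cell `p_e = 1` and kappa is
#' undefined (`NA`, flagged via `kappa_defined`).
#'
#' @param x A square count matrix, or a `pair_set` (its complete pairs are
#'   tabulated first).
#' @return An `agreement_result` list: `table`, `n`, `p_observed`,
#'   `p_expected`, `kappa`, `kappa_defined`, plus the originating pairs when
#'   `x` was a `pair_set`.
#' @export
#' @examples
#' cohen_kappa(matrix(c(7, 0, 1, 19), 2, 2))$kappa
cohen_kappa <- function(x) {
  pairs <- NULL
  if (inherits(x, "pair_set")) {
    pairs <- x$pairs[!is.na(x$pairs$tma1) & !is.na(x$pairs$tma2), ,
                     drop = FALSE]
    ct <- contingency_table(x)
  } else {
    ct <- as.matrix(x)
    if (nrow(ct) != ncol(ct)) stop("table must be square", call. = FALSE)
  }
  n <- sum(ct)
  if (n < 1) stop("empty contingency table", call. = FALSE)
  po <- sum(diag(ct)) / n
  pe <- sum(rowSums(ct) * colSums(ct)) / n^2
  defined <- pe < 1
  kappa <- if (defined) (po - pe) / (1 - pe) else NA_real_
  structure(list(table = ct, n = n, p_observed = po, p_expected = pe,
                 kappa = kappa, kappa_defined = defined, pairs = pairs),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> n=%d  p_o=%.4f  p_e=%.4f  kappa=%s\n",
              x$n, x$p_observed, x$p_expected,
              if (x$kappa_defined) sprintf("%.3f", x$kappa) else "undefined"))
  if (!is.null(x$ci_low)) {
    cat(sprintf("  %d%% CI (%s): (%.3f, %.3f)\n",
                round(100 * x$level), x$ci_method, x$ci_low, x$ci_high))
  }
  invisible(x)
}

# Large-sample variance of unweighted kappa (Fleiss-Cohen-Everitt form).
kappa_var_asymptotic <- function(ct) {
  n <- sum(ct)
  p <- ct / n
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(pr * pc)
  k <- (po - pe) / (1 - pe)
  a <- sum(diag(p) * (1 - (pr + pc) * (1 - k))^2)
  # off-diagonal cell (i, j) is weighted by (p_.i + p_j.)^2
  off <- (1 - k)^2 * (outer(pc, pr, function(ci, rj) (ci + rj)^2) * p)
  diag(off) <- 0
  b <- sum(off)
  cterm <- (k - pe * (1 - k))^2
  (a + b - cterm) / (n * (1 - pe)^2)
}

#' Confidence interval for Cohen's kappa
#'
#' `method = "asymptotic"` uses the standard large-sample standard error for
#' unweighted kappa (Fleiss-Cohen-Everitt) and a normal interval, clipped to
#' `[-1, 1]`. `method = "bootstrap"` resamples complete pairs (cases) with
#' replacement and takes the percentile interval; resamples whose table
#' degenerates to a single category (kappa undefined) are dropped.
#'
#' @param ar An [cohen_kappa()] result.
#' @param method `"asymptotic"` or `"bootstrap"`.
#' @param level Confidence level, default 0.95.
#' @param n_boot Bootstrap replicates (>= 100), default 2000.
#' @param seed Integer seed for the bootstrap; required for reproducibility.
#' @return `ar` augmented with `se` (asymptotic only), `ci_low`, `ci_high`,
#'   `ci_method`, `level`.
#' @export
kappa_ci <- function(ar, method = c("asymptotic", "bootstrap"),
                     level = 0.95, n_boot = 2000, seed = 1L) {
  method <- match.arg(method)
  if (!ar$kappa_defined) stop("kappa undefined; no CI", call. = FALSE)
  if (method == "asymptotic") {
    v <- kappa_var_asymptotic(ar$table)
    se <- sqrt(max(v, 0))
    z <- stats::qnorm(1 - (1 - level) / 2)
    ar$se <- se
    ar$ci_low <- max(-1, ar$kappa - z * se)
    ar$ci_high <- min(1, ar$kappa + z * se)
  } else {
    if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
    if (is.null(ar$pairs)) {
      stop("bootstrap CI needs pair-level data; compute kappa from a pair_set",
           call. = FALSE)
    }
    p <- ar$pairs
    boots <- local({
      set.seed(seed)
      replicate(n_boot, {
        idx <- sample.int(nrow(p), replace = TRUE)
        tab <- table(factor(p$tma1[idx]), factor(p$tma2[idx]))
        cats <- sort(unique(c(p$tma1[idx], p$tma2[idx])))
        m <- matrix(0L, length(cats), length(cats),
                    dimnames = list(cats, cats))
        m[rownames(tab), colnames(tab)] <- tab
        res <- cohen_kappa(m)
        if (res$kappa_defined) res$kappa else NA_real_
      })
    })
    boots <- boots[!is.na(boots)]
    qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE, type = 7)
    ar$se <- stats::sd(boots)
    ar$ci_low <- max(-1, qs[1])
    ar$ci_high <- min(1, qs[2])
  }
  ar$ci_method <- method
  ar$level <- level
  ar
}

#' Test-retest reliability report across all targets
#'
#' One row per target, in the layout of a published reliability table:
#' percent concordance over all cases, Cohen's kappa on complete pairs, and
#' its confidence interval. HER2 concordance compares the reported stain
#' categories while HER2 kappa uses the reliability-binary coding
#' (`{2+,3+}` positive); both conventions are recorded in the output. The
#' phenotype row is reported twice: once from the classifier's calls and
#' once from the as-published labels carried in the table (the two differ
#' only in how indefinite calls are labelled).
#'
#' @param ds A `tma_study`.
#' @param rules [phenotype_rules()].
#' @param ci_method `"asymptotic"` or `"bootstrap"`.
#' @param level Confidence level.
#' @param n_boot,seed Bootstrap parameters (used only for
#'   `ci_method = "bootstrap"`).
#' @return Data frame with columns `target`, `n_cases`, `n_complete`,
#'   `concordance_pct`, `concordance_raw`, `n_pairs_kappa`, `kappa`, `se`,
#'   `ci_low`, `ci_high`, `convention`.
#' @export
#' @examples
#' reliability_report(read_dataset(tma_fixture_path()))
reliability_report <- function(ds, rules = phenotype_rules(),
                               ci_method = c("asymptotic", "bootstrap"),
                               level = 0.95, n_boot = 2000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  specs <- list(
    list(target = "ck_cocktail", conc = list(), kap = list()),
    list(target = "er", conc = list(), kap = list()),
    list(target = "pr", conc = list(), kap = list()),
    list(target = "her2", conc = list(coding = "ordinal"),
         kap = list(coding = "reliability-binary")),
    list(target = "ck56", conc = list(), kap = list()),
    list(target = "egfr", conc = list(), kap = list()),
    list(target = "ki67", conc = list(), kap = list()),
    list(target = "phenotype", conc = list(source = "classifier"),
         kap = list(source = "classifier"), name = "phenotype (classifier)"),
    list(target = "phenotype", conc = list(source = "printed"),
         kap = list(source = "printed"), name = "phenotype (as published)")
  )
  rows <- lapply(specs, function(s) {
    ps_conc <- do.call(build_pairs,
                       c(list(ds = ds, target = s$target, rules = rules),
                         s$conc))
    ps_kap <- do.call(build_pairs,
                      c(list(ds = ds, target = s$target, rules = rules),
                        s$kap))
    conc <- percent_concordance(ps_conc)
    ar <- if (ps_kap$n_complete > 0) cohen_kappa(ps_kap) else NULL
    has_kappa <- !is.null(ar) && ar$kappa_defined
    if (has_kappa) {
      ar <- kappa_ci(ar, method = ci_method, level = level,
                     n_boot = n_boot, seed = seed)
    }
    data.frame(
      target = if (!is.null(s$name)) s$name else s$target,
      n_cases = conc$n_total_cases,
      n_complete = ps_conc$n_complete,
      concordance_pct = conc$percent,
      concordance_raw = conc$raw,
      n_pairs_kappa = if (is.null(ar)) 0L else ar$n,
      kappa = if (has_kappa) ar$kappa else NA_real_,
      se = if (has_kappa) ar$se else NA_real_,
      ci_low = if (has_kappa) ar$ci_low else NA_real_,
      ci_high = if (has_kappa) ar$ci_high else NA_real_,
      convention = paste(ps_conc$policy, "|", "kappa:", ps_kap$policy),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
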