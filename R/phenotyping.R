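# Surrogate molecular phenotype ----------------------------------------------
#
# Immunostain surrogate for intrinsic breast cancer subtype:
#   Luminal A      ER+ and/or PR+, HER2-, Ki67 < cutoff
#   Luminal B      ER+ and/or PR+ and HER2+; or ER+ and/or PR+, HER2-,
#                  Ki67 >= cutoff
#   HER2-enriched  ER- and PR-, HER2+
#   Basal-like     ER-, PR-, HER2-, CK5/6+ and/or EGFR+
#   Unclassifiable ER-, PR-, HER2-, CK5/6-, EGFR-
# Missing markers are resolved by enumerating every completion of the
# missing values: a unanimous verdict is returned as-is, disagreement yields
# an Ambiguous call carrying the candidate set, and a panel with both
# hormone receptors missing is Unknown.

PHENOTYPE_KINDS <- c("LuminalA", "LuminalB", "HER2", "BasalLike",
                     "Unclassifiable", "Ambiguous", "Unknown")

#' Classification rules for the surrogate phenotype
#'
#' @param ki67_cutoff Percent cutoff separating low from high proliferation;
#'   a value equal to the cutoff counts as high. Default 14.
#' @param her2_positive_levels HER2 ordinal levels counted as HER2-positive
#'   for classification. Must be an upward-closed subset of
#'   `neg < 1+ < 2+ < 3+`; the default `"3+"` reflects that 2+ (equivocal)
#'   stains classify as HER2-negative.
#' @return A `phenotype_rules` list.
#' @export
#' @examples
#' phenotype_rules()
phenotype_rules <- function(ki67_cutoff = 14, her2_positive_levels = "3+") {
  stopifnot(is.numeric(ki67_cutoff), length(ki67_cutoff) == 1,
            ki67_cutoff > 0, ki67_cutoff < 100)
  if (!all(her2_positive_levels %in% HER2_LEVELS)) {
    stop("her2_positive_levels must be drawn from ",
         paste(HER2_LEVELS, collapse = ", "), call. = FALSE)
  }
  idx <- sort(match(her2_positive_levels, HER2_LEVELS))
  if (length(idx) && !identical(idx, seq(min(idx), length(HER2_LEVELS)))) {
    stop("her2_positive_levels must be upward-closed on the ordinal scale",
         call. = FALSE)
  }
  structure(list(ki67_cutoff = ki67_cutoff,
                 her2_positive_levels = her2_positive_levels),
            class = "phenotype_rules")
}

# ordinal HER2 -> binary under a rule set; NA stays NA
her2_to_binary <- function(her2, positive_levels) {
  ifelse(is.na(her2), NA_character_,
         ifelse(her2 %in% positive_levels, "pos", "neg"))
}

# deterministic branch for a complete panel; inputs are "pos"/"neg" and
# ki67_high is TRUE/FALSE
classify_complete <- function(er, pr, her2_bin, ck56, egfr, ki67_high) {
  hr_pos <- er == "pos" | pr == "pos"
  if (hr_pos) {
    if (her2_bin == "pos") return("LuminalB")
    if (ki67_high) return("LuminalB")
    return("LuminalA")
  }
  if (her2_bin == "pos") return("HER2")
  if (ck56 == "pos" || egfr == "pos") return("BasalLike")
  "Unclassifiable"
}

#' Classify one TMA panel into a surrogate molecular phenotype
#'
#' @param panel A one-row data frame (or list) with fields `er`, `pr`,
#'   `her2`, `ck56`, `egfr`, `ki67_percent` coded as in [study_dataset()].
#'   The CK cocktail, grade and histology are never classifier inputs.
#' @param rules A [phenotype_rules()] object.
#' @return A `phenotype_call`: list with `kind` (one of LuminalA, LuminalB,
#'   HER2, BasalLike, Unclassifiable, Ambiguous, Unknown) and `candidates`
#'   (character vector of subtypes, non-empty only for Ambiguous).
#' @export
#' @examples
#' classify(list(er = "pos", pr = "pos", her2 = "3+", ck56 = "neg",
#'               egfr = "neg", ki67_percent = 9))
classify <- function(panel, rules = phenotype_rules()) {
  er <- as.character(panel$er)
  pr <- as.character(panel$pr)
  her2_bin <- her2_to_binary(as.character(panel$her2),
                             rules$her2_positive_levels)
  ck56 <- as.character(panel$ck56)
  egfr <- as.character(panel$egfr)
  ki67 <- as.numeric(panel$ki67_percent)
  ki67_high <- if (is.na(ki67)) NA else ki67 >= rules$ki67_cutoff

  if (is.na(er) && is.na(pr)) {
    return(phenotype_call("Unknown"))
  }

  complete_grid <- function(x) if (is.na(x)) MARKER_LEVELS else x
  ki67_grid <- if (is.na(ki67_high)) c(TRUE, FALSE) else ki67_high
  grid <- expand.grid(
    er = complete_grid(er), pr = complete_grid(pr),
    her2_bin = complete_grid(her2_bin), ck56 = complete_grid(ck56),
    egfr = complete_grid(egfr), ki67_high = ki67_grid,
    stringsAsFactors = FALSE
  )
  kinds <- unique(vapply(seq_len(nrow(grid)), function(i) {
    classify_complete(grid$er[i], grid$pr[i], grid$her2_bin[i],
                      grid$ck56[i], grid$egfr[i], grid$ki67_high[i])
  }, character(1)))
  if (length(kinds) == 1) {
    phenotype_call(kinds)
  } else {
    phenotype_call("Ambiguous", candidates = sort(kinds))
  }
}

phenotype_call <- function(kind, candidates = character(0)) {
  stopifnot(kind %in% PHENOTYPE_KINDS)
  if (kind == "Ambiguous" && length(candidates) < 2) {
    stop("Ambiguous call needs >= 2 candidates", call. = FALSE)
  }
  if (kind != "Ambiguous") candidates <- character(0)
  structure(list(kind = kind, candidates = candidates),
            class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat(format_phenotype(x), "\n")
  invisible(x)
}

#' Display label for a phenotype call
#'
#' @param call A `phenotype_call`.
#' @return A label such as `"Luminal A"` or `"Luminal A or Luminal B"`.
#' @export
format_phenotype <- function(call) {
  lab <- c(LuminalA = "Luminal A", LuminalB = "Luminal B", HER2 = "HER2",
           BasalLike = "Basal-like", Unclassifiable = "Unclassifiable",
           Unknown = "Unknown")
  if (call$kind == "Ambiguous") {
    paste(lab[call$candidates], collapse = " or ")
  } else {
    unname(lab[call$kind])
  }
}

#' Parse a printed phenotype label into a call
#'
#' Inverse of [format_phenotype()] for labels as printed in panel tables,
#' tolerating the `"HER 2"` spelling variant. `"X or Y"` labels become
#' Ambiguous calls.
#'
#' @param label Character vector of labels (`NA` allowed).
#' @return A list of `phenotype_call` objects (`NULL` where `label` is `NA`).
#' @export
parse_phenotype_label <- function(label) {
  lut <- c("Luminal A" = "LuminalA", "Luminal B" = "LuminalB",
           "HER2" = "HER2", "HER 2" = "HER2", "Basal-like" = "BasalLike",
           "Unclassifiable" = "Unclassifiable", "Unknown" = "Unknown")
  lapply(label, function(x) {
    if (is.na(x)) return(NULL)
    x <- trimws(x)
    if (grepl(" or ", x, fixed = TRUE)) {
      parts <- trimws(strsplit(x, " or ", fixed = TRUE)[[1]])
      kinds <- unname(lut[parts])
      if (anyNA(kinds)) stop("unrecognized phenotype label: ", x, call. = FALSE)
      return(phenotype_call("Ambiguous", candidates = sort(kinds)))
    }
    kind <- unname(lut[x])
    if (is.na(kind)) stop("unrecognized phenotype label: ", x, call. = FALSE)
    phenotype_call(kind)
  })
}

# Two calls are in the same family when they agree exactly, or when both are
# indefinite (Ambiguous/Unknown): a printed "Unknown" and a printed
# "Luminal A or Luminal B" both correspond to a panel the algorithm cannot
# pin down, and panel tables are not consistent about which label they use.
phenotype_family_match <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  if (identical(a$kind, b$kind) && identical(a$candidates, b$candidates)) {
    return(TRUE)
  }
  a$kind %in% c("Ambiguous", "Unknown") && b$kind %in% c("Ambiguous", "Unknown")
}

#' Classify every panel of a dataset
#'
#' A panel whose markers are all missing (an absent array result) yields no
#' entry; every other panel yields one call.
#'
#' @param ds A `tma_study`.
#' @param rules A [phenotype_rules()] object.
#' @return Data frame with columns `case_id`, `tma_id`, `kind`, `candidates`
#'   (pipe-separated, `NA` unless Ambiguous), `label` (display form),
#'   `printed_phenotype` (as carried in the dataset, possibly `NA`) and
#'   `matches_printed` (exact or Ambiguous/Unknown-family agreement; `NA`
#'   where no printed label exists).
#' @export
#' @examples
#' calls <- classify_dataset(read_dataset(tma_fixture_path()))
#' nrow(calls)
classify_dataset <- function(ds, rules = phenotype_rules()) {
  p <- ds$panels
  marker_cols <- c("er", "pr", "her2", "ck56", "egfr", "ki67_percent",
                   "ck_cocktail")
  absent <- apply(p[, marker_cols], 1, function(r) all(is.na(r)))
  p <- p[!absent, , drop = FALSE]
  rows <- lapply(seq_len(nrow(p)), function(i) {
    call <- classify(p[i, ], rules)
    printed <- parse_phenotype_label(p$printed_phenotype[i])[[1]]
    data.frame(
      case_id = p$case_id[i],
      tma_id = p$tma_id[i],
      kind = call$kind,
      candidates = if (length(call$candidates))
        paste(call$candidates, collapse = "|") else NA_character_,
      label = format_phenotype(call),
      printed_phenotype = p$printed_phenotype[i],
      matches_printed = if (is.null(printed)) NA
        else phenotype_family_match(call, printed),
      stringsAsFactors = FALSE
    )
  })
  if (length(rows)) do.call(rbind, rows) else data.frame(
    case_id = character(0), tma_id = character(0), kind = character(0),
    candidates = character(0), label = character(0),
    printed_phenotype = character(0), matches_printed = logical(0),
    stringsAsFactors = FALSE)
}
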