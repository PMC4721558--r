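# Core-to-TMA aggregation ----------------------------------------------------
#
# Each specimen contributes 3 cores (0.6 mm) per TMA. A core with no tissue
# carries an NA result; a marker with no tissue on any core is missing at the
# TMA level. Binary stains follow the any-positive rule; HER2 takes the
# maximum ordinal score across evaluable cores; Ki67 is the mean percent of
# positive cells across evaluable cores.

#' Aggregate binary immunostain cores to a TMA-level call
#'
#' A panel is positive if one or more cores stain positive, negative if at
#' least one core bears tissue and none is positive, and missing if no core
#' bears tissue.
#'
#' @param cores Character vector of per-core calls (`"pos"`, `"neg"`, or `NA`
#'   for a core with no evaluable tissue), length 1-3.
#' @return A single call: `"pos"`, `"neg"`, or `NA`.
#' @export
#' @examples
#' aggregate_binary_marker(c("pos", "neg", "neg"))
#' aggregate_binary_marker(c(NA, NA, NA))
aggregate_binary_marker <- function(cores) {
  if (length(cores) == 0) stop("no cores supplied", call. = FALSE)
  bad <- !is.na(cores) & !cores %in% MARKER_LEVELS
  if (any(bad)) {
    stop("invalid core call(s): ", paste(cores[bad], collapse = ", "),
         call. = FALSE)
  }
  if (any(cores == "pos", na.rm = TRUE)) return("pos")
  if (any(!is.na(cores))) return("neg")
  NA_character_
}

#' Aggregate HER2 cores to a TMA-level ordinal score
#'
#' The TMA-level HER2 score is the maximum ordinal score
#' (`neg < 1+ < 2+ < 3+`) among tissue-bearing cores, missing if none. This
#' generalizes the any-positive rule to an ordinal stain and yields a single
#' score per TMA replicate.
#'
#' @param cores Character vector of per-core HER2 scores (`"neg"`, `"1+"`,
#'   `"2+"`, `"3+"`, or `NA` for no tissue), length 1-3.
#' @return A single ordinal score or `NA`.
#' @export
#' @examples
#' aggregate_her2(c("2+", "neg", "neg"))
aggregate_her2 <- function(cores) {
  if (length(cores) == 0) stop("no cores supplied", call. = FALSE)
  bad <- !is.na(cores) & !cores %in% HER2_LEVELS
  if (any(bad)) {
    stop("invalid HER2 core score(s): ", paste(cores[bad], collapse = ", "),
         call. = FALSE)
  }
  present <- cores[!is.na(cores)]
  if (length(present) == 0) return(NA_character_)
  HER2_LEVELS[max(match(present, HER2_LEVELS))]
}

#' Aggregate Ki67 cores to a TMA-level percent
#'
#' The TMA-level Ki67 score is the arithmetic mean of the percent of positive
#' cells over tissue-bearing cores only (a core lost to dropout does not
#' dilute the mean); missing if no core bears tissue.
#'
#' @param cores Numeric vector of per-core percent positive values in
#'   `[0, 100]`, `NA` for no tissue; length 1-3.
#' @return Mean percent or `NA`.
#' @export
#' @examples
#' aggregate_ki67(c(1, 2, 3))
aggregate_ki67 <- function(cores) {
  if (length(cores) == 0) stop("no cores supplied", call. = FALSE)
  present <- cores[!is.na(cores)]
  if (any(present < 0 | present > 100)) {
    stop("Ki67 percent outside [0,100]", call. = FALSE)
  }
  if (length(present) == 0) return(NA_real_)
  mean(present)
}

#' Aggregate a core-level score table to TMA panels
#'
#' Takes core-level records in long form and applies the marker-appropriate
#' aggregation rule per (case, TMA, marker).
#'
#' @param cores Data frame with columns `case_id`, `tma_id`, `core_index`,
#'   `marker` (one of `ck_cocktail`, `er`, `pr`, `her2`, `ck56`, `egfr`,
#'   `ki67_percent`), `value` (character; percent values as decimal strings),
#'   `tissue_present` (logical). A core with `tissue_present = FALSE` must
#'   carry an `NA` value.
#' @return Data frame of panels, one row per (case, TMA), with the standard
#'   panel columns.
#' @export
aggregate_cores <- function(cores) {
  stopifnot(all(c("case_id", "tma_id", "core_index", "marker", "value",
                  "tissue_present") %in% names(cores)))
  if (any(!cores$tissue_present & !is.na(cores$value))) {
    stop("core without tissue carries a non-missing value", call. = FALSE)
  }
  key <- paste(cores$case_id, cores$tma_id, sep = "\r")
  groups <- split(seq_len(nrow(cores)), key)
  # preserve first-appearance order of (case, TMA)
  groups <- groups[unique(key)]
  rows <- lapply(groups, function(idx) {
    sub <- cores[idx, , drop = FALSE]
    one <- function(marker, fn, as_num = FALSE) {
      v <- sub$value[sub$marker == marker]
      if (length(v) == 0) return(if (as_num) NA_real_ else NA_character_)
      if (as_num) fn(as.numeric(v)) else fn(v)
    }
    data.frame(
      case_id = sub$case_id[1], tma_id = sub$tma_id[1],
      ck_cocktail = one("ck_cocktail", aggregate_binary_marker),
      er = one("er", aggregate_binary_marker),
      pr = one("pr", aggregate_binary_marker),
      her2 = one("her2", aggregate_her2),
      ck56 = one("ck56", aggregate_binary_marker),
      egfr = one("egfr", aggregate_binary_marker),
      ki67_percent = one("ki67_percent", aggregate_ki67, as_num = TRUE),
      printed_phenotype = NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Antigen-integrity check from the CK cocktail control stain
#'
#' The broad-spectrum cytokeratin cocktail acts as a control for antigen
#' preservation: every carcinoma should stain. Integrity is judged per case
#' across both TMA replicates: it fails only when at least one CK cocktail
#' call is definite and all definite calls are negative. A case whose CK
#' calls are all missing is not flagged (no evidence of degradation).
#'
#' @param ds A `tma_study`.
#' @return Data frame with columns `case_id`, `preserved` (logical), one row
#'   per case that has at least one panel.
#' @export
#' @examples
#' flags <- antigen_integrity(read_dataset(tma_fixture_path()))
#' sum(!flags$preserved)
antigen_integrity <- function(ds) {
  ids <- unique(ds$panels$case_id)
  preserved <- vapply(ids, function(id) {
    ck <- ds$panels$ck_cocktail[ds$panels$case_id == id]
    def <- ck[!is.na(ck)]
    if (length(def) == 0) return(TRUE)
    any(def == "pos")
  }, logical(1))
  data.frame(case_id = ids, preserved = unname(preserved),
             stringsAsFactors = FALSE)
}
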