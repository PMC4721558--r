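# Domain vocabulary ---------------------------------------------------------

#' Marker and stratum vocabulary
#'
#' Binary immunostain calls are coded `"pos"` / `"neg"` with `NA` meaning no
#' evaluable tissue. HER2 is kept on its ordinal immunohistochemistry scale
#' (`"neg" < "1+" < "2+" < "3+"`); Ki67 is a percent of positive cells in
#' `[0, 100]`. Cases are stratified into six diagnosis periods spanning
#' 1947-2009.
#'
#' @name tma-vocabulary
#' @keywords internal
NULL

MARKER_LEVELS <- c("pos", "neg")
HER2_LEVELS <- c("neg", "1+", "2+", "3+")
BINARY_MARKERS <- c("ck_cocktail", "er", "pr", "ck56", "egfr")
PANEL_MARKERS <- c(BINARY_MARKERS, "her2", "ki67_percent")

PANEL_COLUMNS <- c(
  "case_id", "tma_id", "year", "histology", "grade",
  "ck_cocktail", "er", "pr", "her2", "ck56", "egfr",
  "ki67_percent", "printed_phenotype"
)

#' Diagnosis-decade strata
#'
#' The six diagnosis periods used for stratified sampling. The first stratum
#' is longer than a calendar decade (1947-1959); the rest are true decades.
#'
#' @return A data frame with columns `stratum`, `start`, `end`.
#' @export
#' @examples
#' decade_strata()
decade_strata <- function() {
  data.frame(
    stratum = c("1947-1959", "1960-1969", "1970-1979",
                "1980-1989", "1990-1999", "2000-2009"),
    start = c(1947L, 1960L, 1970L, 1980L, 1990L, 2000L),
    end = c(1959L, 1969L, 1979L, 1989L, 1999L, 2009L),
    stringsAsFactors = FALSE
  )
}

#' Map a diagnosis year to its decade stratum
#'
#' @param year Integer vector of diagnosis years, each in 1947-2009.
#' @return Character vector of stratum labels (see [decade_strata()]).
#' @export
#' @examples
#' decade_of(c(1955, 1960, 2009))
decade_of <- function(year) {
  year <- as.integer(year)
  strata <- decade_strata()
  out <- rep(NA_character_, length(year))
  for (i in seq_len(nrow(strata))) {
    hit <- !is.na(year) & year >= strata$start[i] & year <= strata$end[i]
    out[hit] <- strata$stratum[i]
  }
  bad <- !is.na(year) & is.na(out)
  if (any(bad)) {
    stop("diagnosis year(s) outside 1947-2009: ",
         paste(year[bad], collapse = ", "), call. = FALSE)
  }
  out
}

# Dataset container ----------------------------------------------------------

#' Construct a TMA study dataset
#'
#' A study dataset couples case-level records (one row per tumor case) with
#' panel-level records (one row per case x TMA replicate, holding the
#' aggregated marker calls for that replicate). A case may have at most one
#' panel per TMA; a panel whose markers are all `NA` (no evaluable tissue on
#' any core of any stain) is legal and preserved through I/O.
#'
#' @param cases Data frame with columns `case_id`, `year`, `histology`,
#'   `grade`; a `decade` column is derived if absent.
#' @param panels Data frame with columns `case_id`, `tma_id`, the five binary
#'   markers (`ck_cocktail`, `er`, `pr`, `ck56`, `egfr` coded "pos"/"neg"/NA),
#'   `her2` ("neg"/"1+"/"2+"/"3+"/NA), `ki67_percent` (numeric or NA) and
#'   optionally `printed_phenotype` (opaque validation text, never a
#'   classifier input).
#' @return An object of class `tma_study`.
#' @export
study_dataset <- function(cases, panels) {
  cases <- as.data.frame(cases, stringsAsFactors = FALSE)
  panels <- as.data.frame(panels, stringsAsFactors = FALSE)
  if (!"printed_phenotype" %in% names(panels)) {
    panels$printed_phenotype <- NA_character_
  }
  if (!"decade" %in% names(cases)) {
    cases$decade <- if (nrow(cases)) decade_of(cases$year) else character(0)
  }
  cases$year <- as.integer(cases$year)
  cases$grade <- as.integer(cases$grade)
  panels$ki67_percent <- as.numeric(panels$ki67_percent)
  ds <- structure(list(cases = cases, panels = panels), class = "tma_study")
  issues <- validate_dataset(ds)
  if (nrow(issues)) {
    stop(format_issues(issues), call. = FALSE)
  }
  ds
}

#' @export
print.tma_study <- function(x, ...) {
  cat(sprintf("<tma_study> %d cases, %d panels\n",
              nrow(x$cases), nrow(x$panels)))
  if (nrow(x$cases)) {
    tab <- table(x$cases$decade)
    cat("  cases per stratum: ",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Validate a study dataset
#'
#' Checks structural invariants: unique case IDs, at most one panel per
#' (case, TMA), every panel resolving to a case, grades in 1-3, years inside
#' their stratum, marker codes in their vocabularies, Ki67 in `[0, 100]`.
#'
#' @param ds A `tma_study` (or a list with `cases` and `panels` data frames).
#' @return Data frame of issues with columns `where`, `row`, `problem`;
#'   zero rows when the dataset is valid.
#' @export
validate_dataset <- function(ds) {
  issues <- list()
  add <- function(where, row, problem) {
    issues[[length(issues) + 1L]] <<- data.frame(
      where = where, row = row, problem = problem, stringsAsFactors = FALSE)
  }
  cases <- ds$cases
  panels <- ds$panels

  dup <- duplicated(cases$case_id)
  for (i in which(dup)) {
    add("cases", i, sprintf("duplicate case_id '%s'", cases$case_id[i]))
  }
  for (i in seq_len(nrow(cases))) {
    g <- cases$grade[i]
    if (is.na(g) || !g %in% 1:3) {
      add("cases", i, sprintf("grade '%s' not in 1-3 (case %s)",
                              as.character(g), cases$case_id[i]))
    }
    y <- cases$year[i]
    str <- tryCatch(decade_of(y), error = function(e) NA_character_)
    if (is.na(str)) {
      add("cases", i, sprintf("year '%s' outside 1947-2009 (case %s)",
                              as.character(y), cases$case_id[i]))
    } else if (!is.null(cases$decade) && !is.na(cases$decade[i]) &&
               cases$decade[i] != str) {
      add("cases", i, sprintf("year %d not inside stratum %s (case %s)",
                              y, cases$decade[i], cases$case_id[i]))
    }
  }

  key <- paste(panels$case_id, panels$tma_id)
  for (i in which(duplicated(key))) {
    add("panels", i, sprintf("duplicate panel for (%s, %s)",
                             panels$case_id[i], panels$tma_id[i]))
  }
  orphan <- !panels$case_id %in% cases$case_id
  for (i in which(orphan)) {
    add("panels", i, sprintf("panel case_id '%s' has no case record",
                             panels$case_id[i]))
  }
  for (i in seq_len(nrow(panels))) {
    if (!panels$tma_id[i] %in% c("TMA1", "TMA2")) {
      add("panels", i, sprintf("tma_id '%s' is not TMA1/TMA2", panels$tma_id[i]))
    }
    for (m in BINARY_MARKERS) {
      v <- panels[[m]][i]
      if (!is.na(v) && !v %in% MARKER_LEVELS) {
        add("panels", i, sprintf("%s value '%s' not pos/neg/NA", m, v))
      }
    }
    h <- panels$her2[i]
    if (!is.na(h) && !h %in% HER2_LEVELS) {
      add("panels", i, sprintf("her2 value '%s' not neg/1+/2+/3+/NA", h))
    }
    k <- panels$ki67_percent[i]
    if (!is.na(k) && (k < 0 || k > 100)) {
      add("panels", i, sprintf("ki67_percent %s outside [0,100]",
                               format(k)))
    }
  }

  if (length(issues)) {
    do.call(rbind, issues)
  } else {
    data.frame(where = character(0), row = integer(0),
               problem = character(0), stringsAsFactors = FALSE)
  }
}

format_issues <- function(issues) {
  paste0("invalid dataset (", nrow(issues), " issue(s)):\n",
         paste(sprintf("  [%s row %d] %s", issues$where, issues$row,
                       issues$problem), collapse = "\n"))
}

# I/O ------------------------------------------------------------------------

#' Read a study dataset from a delimited panel table
#'
#' The file is comma-separated UTF-8 with one row per (case, TMA) and the
#' fixed header
#' `case_id,tma_id,year,histology,grade,ck_cocktail,er,pr,her2,ck56,egfr,ki67_percent,printed_phenotype`.
#' Binary marker cells use `pos`/`neg`/`NA`; HER2 uses `neg`/`1+`/`2+`/`3+`/`NA`;
#' `ki67_percent` is a decimal or `NA`. Validation problems are aggregated and
#' reported together with their row numbers.
#'
#' @param path Path to the CSV file.
#' @return A [study_dataset()] object.
#' @export
#' @examples
#' ds <- read_dataset(tma_fixture_path())
#' ds
read_dataset <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = "NA", stringsAsFactors = FALSE,
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0) {
    return(empty_dataset())
  }
  missing_cols <- setdiff(PANEL_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  # parse-level checks before typing, so bad cells are named by file row
  issues <- character(0)
  year_num <- suppressWarnings(as.integer(raw$year))
  grade_num <- suppressWarnings(as.integer(raw$grade))
  ki67_num <- suppressWarnings(as.numeric(raw$ki67_percent))
  for (i in seq_len(nrow(raw))) {
    if (is.na(year_num[i])) {
      issues <- c(issues, sprintf("row %d: malformed year '%s'", i, raw$year[i]))
    }
    if (is.na(grade_num[i])) {
      issues <- c(issues, sprintf("row %d: malformed grade '%s'", i, raw$grade[i]))
    }
    if (!is.na(raw$ki67_percent[i]) && is.na(ki67_num[i])) {
      issues <- c(issues, sprintf("row %d: malformed ki67_percent '%s'",
                                  i, raw$ki67_percent[i]))
    }
  }
  if (length(issues)) {
    stop("parse error:\n", paste0("  ", issues, collapse = "\n"), call. = FALSE)
  }

  cases <- unique(raw[, c("case_id", "year", "histology", "grade")])
  cases$year <- as.integer(cases$year)
  cases$grade <- as.integer(cases$grade)
  panels <- raw[, c("case_id", "tma_id", BINARY_MARKERS[1:3], "her2",
                    BINARY_MARKERS[4:5], "ki67_percent", "printed_phenotype")]
  panels <- panels[, c("case_id", "tma_id", "ck_cocktail", "er", "pr",
                       "her2", "ck56", "egfr", "ki67_percent",
                       "printed_phenotype")]
  panels$ki67_percent <- ki67_num
  study_dataset(cases, panels)
}

empty_dataset <- function() {
  cases <- data.frame(case_id = character(0), year = integer(0),
                      histology = character(0), grade = integer(0),
                      decade = character(0), stringsAsFactors = FALSE)
  panels <- data.frame(case_id = character(0), tma_id = character(0),
                       ck_cocktail = character(0), er = character(0),
                       pr = character(0), her2 = character(0),
                       ck56 = character(0), egfr = character(0),
                       ki67_percent = numeric(0),
                       printed_phenotype = character(0),
                       stringsAsFactors = FALSE)
  structure(list(cases = cases, panels = panels), class = "tma_study")
}

#' Write a study dataset to the delimited panel table format
#'
#' Inverse of [read_dataset()]: `read_dataset(write_dataset(ds, f))`
#' reproduces `ds` exactly on all typed values.
#'
#' @param ds A `tma_study`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  p <- ds$panels
  c_idx <- match(p$case_id, ds$cases$case_id)
  out <- data.frame(
    case_id = p$case_id,
    tma_id = p$tma_id,
    year = ds$cases$year[c_idx],
    histology = ds$cases$histology[c_idx],
    grade = ds$cases$grade[c_idx],
    ck_cocktail = p$ck_cocktail,
    er = p$er,
    pr = p$pr,
    her2 = p$her2,
    ck56 = p$ck56,
    egfr = p$egfr,
    ki67_percent = p$ki67_percent,
    printed_phenotype = p$printed_phenotype,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' Path to the packaged 30-case reference panel table
#'
#' A transcription of a published two-TMA immunostain panel for 30 breast
#' cancer cases, five per diagnosis decade from 1947-1959 through 2000-2009:
#' 60 panel slots, of which one (case 3-13, TMA1) is entirely missing and two
#' HER2 cells are missing because no tissue was present in any core.
#'
#' @return Path to the CSV file inside the installed package.
#' @export
tma_fixture_path <- function() {
  system.file("extdata", "table1_tma_panels.csv", package = "tmaretest",
              mustWork = TRUE)
}

#' Panels of a dataset in case order
#'
#' @param ds A `tma_study`.
#' @param tma_id Optional `"TMA1"` or `"TMA2"` filter.
#' @return Data frame of panels.
#' @keywords internal
panels_of <- function(ds, tma_id = NULL) {
  p <- ds$panels
  if (!is.null(tma_id)) p <- p[p$tma_id == tma_id, , drop = FALSE]
  p
}
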