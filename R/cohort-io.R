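COHORT_META_COLS <- c("study", "center", "participant", "visit", "time",
                      "age", "sex", "tiv", "group", "scanner", "cag")

#' Write a cohort table to CSV
#'
#' One row per participant-visit with the fixed header
#' `study,center,participant,visit,time,age,sex,tiv,group,scanner,cag`
#' followed by region and marker columns. Continuous values are rounded to 6
#' significant digits so that re-running a seeded pipeline reproduces the
#' file byte for byte; missing values are written as empty fields.
#'
#' @param table a `cohort_table` (or compatible `data.frame`).
#' @param path output file path.
#' @export
write_cohort_csv <- function(table, path) {
  missing_cols <- setdiff(COHORT_META_COLS, names(table))
  if (length(missing_cols))
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "))
  out <- table[, c(COHORT_META_COLS,
                   setdiff(names(table), COHORT_META_COLS)), drop = FALSE]
  num <- setdiff(names(out)[vapply(out, is.numeric, logical(1L))],
                 c("visit", "sex", "cag"))
  for (cn in num) out[[cn]] <- signif(out[[cn]], 6)
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Load and validate a cohort CSV
#'
#' Enforces the analysis inclusion rules: every participant must have one
#' record at every visit time present in the file (participants with missing
#' visits are excluded, with a message), and every participant must have been
#' measured on a single scanner at all visits (violations are an error,
#' reported with row numbers).
#'
#' @param path CSV path written by [write_cohort_csv()] or following the same
#'   column contract.
#' @return a `data.frame` of class `cohort_table`.
#' @export
load_cohort_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty cohort file: ", path)
  missing_cols <- setdiff(COHORT_META_COLS, names(tab))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))

  n_scanner <- tapply(tab$scanner, tab$participant,
                      function(s) length(unique(s)))
  bad_scan <- names(n_scanner)[n_scanner > 1]
  if (length(bad_scan)) {
    rows <- which(tab$participant %in% bad_scan)
    stop("scanner changes within participant(s) ",
         paste(bad_scan, collapse = ", "), " (rows ",
         paste(rows, collapse = ", "), ")")
  }

  times <- sort(unique(tab$time))
  full <- tapply(tab$time, tab$participant, function(tt)
    length(tt) == length(times) && !anyDuplicated(tt) &&
      all(sort(tt) == times))
  dropped <- names(full)[!full]
  if (length(dropped)) {
    message("excluding ", length(dropped),
            " participant(s) without complete visits: ",
            paste(dropped, collapse = ", "))
    tab <- tab[!(tab$participant %in% dropped), , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("no participants with complete visits in ", path)
  rownames(tab) <- NULL
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Names of outcome columns in a cohort table
#'
#' @param table a `cohort_table`.
#' @return character vector of region/marker column names (everything beyond
#'   the fixed metadata columns).
#' @export
outcome_columns <- function(table) {
  setdiff(names(table), COHORT_META_COLS)
}
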