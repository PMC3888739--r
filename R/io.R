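# Toxicity series container and CSV ingest/emit.

#' Construct a toxicity series
#'
#' A toxicity series holds the (LT50, LC50) observations for one species x
#' toxicant dataset, in canonical units (days, ug/L). Records are sorted by
#' exposure time; duplicate times are rejected, so replicate experiments must
#' be kept as separate datasets.
#'
#' @param species,toxicant non-empty name strings.
#' @param time_days numeric vector of exposure durations (days, > 0).
#' @param lc50_ugL numeric vector of median lethal concentrations (ug/L, >= 0).
#' @param reported_nlt_days optional literature normal life expectancy (days).
#' @param dataset_id optional identifier distinguishing datasets that share a
#'   species and toxicant.
#' @return an object of class `"toxicity_series"`: a list with elements
#'   `species`, `toxicant`, `dataset_id`, `records` (a data.frame with columns
#'   `time_days`, `lc50_ugL`) and `reported_nlt_days`.
#' @examples
#' toxicity_series("Oreochromis niloticus", "dimethoate",
#'                 time_days = c(1, 2, 3, 4),
#'                 lc50_ugL = c(36000, 30500, 27500, 25500))
#' @export
toxicity_series <- function(species, toxicant, time_days, lc50_ugL,
                            reported_nlt_days = NA_real_, dataset_id = NA) {
  if (!is.character(species) || length(species) != 1L || !nzchar(trimws(species)))
    rle_stop("'species' must be a non-empty string", "bad_input")
  if (!is.character(toxicant) || length(toxicant) != 1L || !nzchar(trimws(toxicant)))
    rle_stop("'toxicant' must be a non-empty string", "bad_input")
  time_days <- as.numeric(time_days)
  lc50_ugL <- as.numeric(lc50_ugL)
  if (length(time_days) != length(lc50_ugL))
    rle_stop("'time_days' and 'lc50_ugL' must have equal length", "bad_input")
  if (any(!is.finite(time_days) | time_days <= 0))
    rle_stop("all exposure times must be positive and finite", "bad_input")
  if (any(!is.finite(lc50_ugL) | lc50_ugL < 0))
    rle_stop("all LC50 values must be finite and non-negative", "bad_input")
  ord <- order(time_days)
  time_days <- time_days[ord]
  lc50_ugL <- lc50_ugL[ord]
  if (anyDuplicated(time_days))
    rle_stop("exposure times must be distinct within a series", "bad_input")
  if (!is.na(reported_nlt_days) && reported_nlt_days <= 0)
    rle_stop("'reported_nlt_days' must be positive when given", "bad_input")
  structure(list(
    species = species, toxicant = toxicant, dataset_id = dataset_id,
    records = data.frame(time_days = time_days, lc50_ugL = lc50_ugL),
    reported_nlt_days = as.numeric(reported_nlt_days)
  ), class = "toxicity_series")
}

#' @export
print.toxicity_series <- function(x, ...) {
  cat(sprintf("Toxicity series: %s / %s (%d records)\n",
              x$species, x$toxicant, nrow(x$records)))
  if (!is.na(x$reported_nlt_days))
    cat(sprintf("  reported NLT: %g days\n", x$reported_nlt_days))
  print(x$records, row.names = FALSE)
  invisible(x)
}

.series_cols <- c("species", "toxicant", "time_value", "time_unit",
                  "conc_value", "conc_unit")

#' Read toxicity series from a CSV file
#'
#' Reads a comma-separated, header-rowed UTF-8 file with columns `species`,
#' `toxicant`, `time_value`, `time_unit`, `conc_value`, `conc_unit` and
#' optionally `dataset_id` and `reported_nlt_days`. Units are canonicalized to
#' days and ug/L at ingest; rows are grouped into one series per
#' (species, toxicant, dataset_id). Malformed rows abort the read with their
#' file line numbers (the header is line 1).
#'
#' @param path path to the CSV file.
#' @param columns optional named character vector remapping expected column
#'   names to the names actually used in the file, e.g.
#'   `c(conc_value = "LC50", conc_unit = "LC50_unit")`.
#' @return a list of [toxicity_series()] objects (empty, with a warning, for a
#'   file holding only a header).
#' @export
read_series_csv <- function(path, columns = NULL) {
  if (!file.exists(path)) rle_stop(sprintf("file not found: %s", path), "io")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  # apply user column remapping (names = canonical, values = file headers)
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      if (columns[[canon]] %in% names(raw))
        names(raw)[names(raw) == columns[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(.series_cols, names(raw))
  if (length(missing_cols))
    rle_stop(sprintf("missing required column(s): %s",
                     paste(missing_cols, collapse = ", ")), "io")
  if (nrow(raw) == 0L) {
    warning("no data rows in ", path)
    return(list())
  }
  if (!"dataset_id" %in% names(raw)) raw$dataset_id <- ""
  if (!"reported_nlt_days" %in% names(raw)) raw$reported_nlt_days <- ""

  line_no <- seq_len(nrow(raw)) + 1L
  problems <- character(0)
  num <- function(s) suppressWarnings(as.numeric(s))
  tv <- num(raw$time_value); cv <- num(raw$conc_value)
  nlt <- num(ifelse(nzchar(trimws(raw$reported_nlt_days)), raw$reported_nlt_days, NA))
  bad_t <- is.na(tv); bad_c <- is.na(cv)
  if (any(bad_t))
    problems <- c(problems, sprintf("line %d: unparseable time_value '%s'",
                                    line_no[bad_t], raw$time_value[bad_t]))
  if (any(bad_c))
    problems <- c(problems, sprintf("line %d: unparseable conc_value '%s'",
                                    line_no[bad_c], raw$conc_value[bad_c]))
  for (i in which(!bad_t)) {
    r <- tryCatch({ tv[i] <- normalize_time(tv[i], raw$time_unit[i]); NULL },
                  rletox_error = function(e) conditionMessage(e))
    if (!is.null(r)) problems <- c(problems, sprintf("line %d: %s", line_no[i], r))
  }
  for (i in which(!bad_c)) {
    r <- tryCatch({ cv[i] <- normalize_concentration(cv[i], raw$conc_unit[i]); NULL },
                  rletox_error = function(e) conditionMessage(e))
    if (!is.null(r)) problems <- c(problems, sprintf("line %d: %s", line_no[i], r))
  }
  if (length(problems))
    rle_stop(paste0("malformed rows in ", path, ":\n  ",
                    paste(problems, collapse = "\n  ")), "io")

  key <- paste(raw$species, raw$toxicant, raw$dataset_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(raw)), factor(key, levels = unique(key))),
                function(idx) {
    toxicity_series(
      species = raw$species[idx[1]], toxicant = raw$toxicant[idx[1]],
      time_days = tv[idx], lc50_ugL = cv[idx],
      reported_nlt_days = if (all(is.na(nlt[idx]))) NA_real_ else nlt[idx][!is.na(nlt[idx])][1],
      dataset_id = if (nzchar(raw$dataset_id[idx[1]])) raw$dataset_id[idx[1]] else NA
    )
  })
  unname(out)
}

#' Write toxicity series to a CSV file
#'
#' Emits the same schema [read_series_csv()] reads (canonical units: days and
#' ug/L), so a write/read round trip reproduces the series exactly.
#'
#' @param series_list a list of [toxicity_series()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series_list, path) {
  if (inherits(series_list, "toxicity_series")) series_list <- list(series_list)
  rows <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    data.frame(
      species = s$species, toxicant = s$toxicant,
      dataset_id = if (is.na(s$dataset_id)) i else s$dataset_id,
      time_value = sprintf("%.17g", s$records$time_days), time_unit = "days",
      conc_value = sprintf("%.17g", s$records$lc50_ugL), conc_unit = "ug/L",
      reported_nlt_days = if (is.na(s$reported_nlt_days)) "" else
        sprintf("%.17g", s$reported_nlt_days)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
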