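#' @keywords internal
.mt_required_cols <- c("role", "series_id", "level_index", "replicate_index",
                       "nominal_concentration", "response")
.mt_optional_cols <- c(matrix = "aqueous", fat_content = NA_real_,
                       reagent = NA_character_)
.mt_key_cols <- c("role", "series_id", "level_index", "replicate_index",
                  "matrix", "fat_content", "reagent")

#' Assemble a measurement table
#'
#' A measurement table is the long-format container for calibration and
#' validation standard responses. Each record carries its role
#' (`"calibration"` or `"validation"`), series (day), level, replicate,
#' nominal concentration and instrument response, plus optional matrix
#' metadata (`matrix`, `fat_content`, `reagent`).
#'
#' @param records A data.frame with at least the columns `role`, `series_id`,
#'   `level_index`, `replicate_index`, `nominal_concentration`, `response`.
#' @param design Optional `validation_design`; inferred from the records when
#'   omitted (series count, replicate count, sorted unique concentrations).
#' @param beta,lambda Passed to the inferred design when `design` is `NULL`.
#'
#' @return An object of class `"measurement_table"`: a data.frame of records
#'   with the design stored in `attr(x, "design")`.
#'
#' @details Invariants enforced: finite responses, strictly positive nominal
#'   concentrations, uniqueness of the
#'   (role, series, level, replicate, matrix, fat, reagent) key, and record
#'   concentrations being a subset of the design concentrations.
#' @seealso [read_measurements()], [validate_design()]
#' @export
measurement_table <- function(records, design = NULL, beta = 0.95, lambda = 15) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a non-empty data.frame", call. = FALSE)
  missing_cols <- setdiff(.mt_required_cols, names(records))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in names(.mt_optional_cols)) {
    if (is.null(records[[col]])) records[[col]] <- .mt_optional_cols[[col]]
  }
  records$role <- as.character(records$role)
  bad_role <- setdiff(unique(records$role), c("calibration", "validation"))
  if (length(bad_role))
    stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  if (!is.numeric(records$response))
    stop("'response' must be numeric", call. = FALSE)
  if (any(!is.finite(records$response)))
    stop("non-finite response in row(s) ",
         paste(which(!is.finite(records$response)), collapse = ", "), call. = FALSE)
  if (any(!is.finite(records$nominal_concentration) |
          records$nominal_concentration <= 0))
    stop("nominal concentrations must be finite and > 0", call. = FALSE)

  key <- do.call(paste, c(records[.mt_key_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), .mt_key_cols[1:4], drop = FALSE]
    stop("duplicate measurement key(s), e.g. role=", dup$role[1],
         " series=", dup$series_id[1], " level=", dup$level_index[1],
         " replicate=", dup$replicate_index[1], call. = FALSE)
  }

  if (is.null(design)) {
    conc <- sort(unique(records$nominal_concentration))
    design <- validation_design(
      n_series = length(unique(records$series_id)),
      n_replicates = max(records$replicate_index),
      nominal_concentrations = conc,
      beta = beta, lambda = lambda
    )
  }
  extra <- setdiff(unique(records$nominal_concentration),
                   design$nominal_concentrations)
  if (length(extra))
    stop("record concentration(s) not in the design: ",
         paste(extra, collapse = ", "), call. = FALSE)
  structure(records, design = design,
            class = c("measurement_table", "data.frame"))
}

#' Read calibration/validation standards from a CSV file
#'
#' Reads a long-format CSV of standard responses and assembles a
#' [measurement_table()]. Column names can be remapped through `schema`,
#' a named character vector `c(canonical = "file_column")`; the canonical
#' names are `role`, `series_id`, `level_index`, `replicate_index`,
#' `nominal_concentration`, `response` and optionally `matrix`,
#' `fat_content`, `reagent`.
#'
#' @param path Path to a CSV file (UTF-8, header row).
#' @param schema Optional named character vector remapping file columns to
#'   canonical names.
#' @param design Optional `validation_design`; inferred when omitted.
#' @return A `measurement_table`.
#' @examples
#' tab <- simulate_validation_dataset(default_truth_spec(), seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write.csv(tab, f, row.names = FALSE)
#' tab2 <- read_measurements(f)
#' attr(tab2, "design")
#' @export
read_measurements <- function(path, schema = NULL, design = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(raw) == 0L)
    stop("no data rows in '", path, "'", call. = FALSE)
  if (!is.null(schema)) {
    if (is.null(names(schema)) || any(names(schema) == ""))
      stop("'schema' must be a named character vector", call. = FALSE)
    absent <- setdiff(unname(schema), names(raw))
    if (length(absent))
      stop("schema column(s) not in file: ", paste(absent, collapse = ", "),
           call. = FALSE)
    for (canonical in names(schema)) names(raw)[names(raw) == schema[[canonical]]] <- canonical
  }
  missing_cols <- setdiff(.mt_required_cols, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  resp <- suppressWarnings(as.numeric(raw$response))
  bad <- which(is.na(resp) & !is.na(raw$response) & raw$response != "")
  if (length(bad))
    stop("non-numeric response at data row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  raw$response <- resp
  measurement_table(raw, design = design)
}

#' Check a measurement table against its design
#'
#' Compares the table to the balanced series x level x replicate grid implied
#' by its design, separately for each role present, and reports departures as
#' findings rather than errors: missing cells, missing replicates, and extra
#' replicates.
#'
#' @param table A `measurement_table`.
#' @param roles Roles to check; defaults to the roles present in the table.
#' @return A character vector of findings; `character(0)` when the table is
#'   complete and balanced.
#' @export
validate_design <- function(table, roles = unique(table$role)) {
  stopifnot(inherits(table, "measurement_table"))
  design <- attr(table, "design")
  series <- sort(unique(table$series_id))
  findings <- character(0)
  if (length(series) != design$n_series)
    findings <- c(findings, sprintf(
      "table has %d series, design expects %d", length(series), design$n_series))
  for (role in roles) {
    sub <- table[table$role == role, , drop = FALSE]
    for (s in series) {
      for (lev in seq_len(design$n_levels)) {
        k <- sum(sub$series_id == s & sub$level_index == lev)
        if (k == 0L)
          findings <- c(findings, sprintf(
            "%s: missing cell (series %s, level %d)", role, s, lev))
        else if (k < design$n_replicates)
          findings <- c(findings, sprintf(
            "%s: missing replicate(s) in (series %s, level %d): %d of %d present",
            role, s, lev, k, design$n_replicates))
        else if (k > design$n_replicates)
          findings <- c(findings, sprintf(
            "%s: extra replicate(s) in (series %s, level %d): %d of %d present",
            role, s, lev, k, design$n_replicates))
      }
    }
  }
  findings
}
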