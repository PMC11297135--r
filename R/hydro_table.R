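#' @name hydro_table
#' @title Hydrographic sample tables
#'
#' @description
#' A hydrographic table is a plain data.frame with one row per discrete
#' sample and the fixed column set
#' `station_id, latitude, longitude, depth_m, date, year_decimal, week,
#' temperature_c, salinity, phosphate_umol_kg, nitrate_umol_kg,
#' silicate_umol_kg, ph, ta_umol_kg`.
#' Units: degrees N / degrees E (negative W), metres, decimal years,
#' ISO week 1-52, deg C, practical salinity, umol kg^-1 for nutrients and
#' alkalinity, total-scale pH. `ph` and `ta_umol_kg` are optional labels
#' (`NA` when unmeasured); a *training* table must label every row with at
#' least one of them.
NULL

hydro_columns <- c("station_id", "latitude", "longitude", "depth_m", "date",
                   "year_decimal", "week", "temperature_c", "salinity",
                   "phosphate_umol_kg", "nitrate_umol_kg", "silicate_umol_kg",
                   "ph", "ta_umol_kg")

#' Validate and order a hydrographic table
#'
#' Checks column presence and the physical invariants (non-negative
#' salinity, nutrients and depth; week in 1..53) and returns the table with
#' columns in canonical order.
#'
#' @param x data.frame.
#' @param training if `TRUE`, additionally require every row to carry a
#'   `ph` or `ta_umol_kg` label.
#' @return the validated data.frame (class `hydro_table`, data.frame).
#' @export
as_hydro_table <- function(x, training = FALSE) {
  missing_cols <- setdiff(hydro_columns, names(x))
  if (length(missing_cols)) {
    stop("hydro table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, hydro_columns]
  if (!inherits(x$date, "Date")) x$date <- as.Date(x$date)
  bad <- function(cond, msg) if (any(cond, na.rm = TRUE)) {
    stop("invalid hydro table: ", msg, call. = FALSE)
  }
  bad(x$salinity < 0, "salinity must be >= 0")
  bad(x$depth_m < 0, "depth must be >= 0")
  bad(x$phosphate_umol_kg < 0 | x$nitrate_umol_kg < 0 | x$silicate_umol_kg < 0,
      "nutrient concentrations must be >= 0")
  bad(x$week < 1 | x$week > 53, "week must be in 1..53")
  if (training) {
    unlabelled <- is.na(x$ph) & is.na(x$ta_umol_kg)
    bad(unlabelled, "training rows must carry a ph or ta label")
  }
  class(x) <- c("hydro_table", "data.frame")
  x
}

#' Write / read a hydrographic table as delimited text
#'
#' Comma-separated UTF-8 with a header row; numeric cells carry enough
#' digits (default 12 significant) that a write/read round trip reproduces
#' values to formatting precision; missing optional labels are written as
#' empty fields.
#'
#' @param table a hydrographic table.
#' @param path file path.
#' @param digits significant digits used when formatting numeric columns.
#' @return `write_hydro_table` returns `path` invisibly; `read_hydro_table`
#'   returns the table.
#' @export
write_hydro_table <- function(table, path, digits = 12) {
  table <- as_hydro_table(table)
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), "", formatC(v, digits = digits, format = "g"))
  })
  out$date <- format(table$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_hydro_table
#' @param training passed to [as_hydro_table()].
#' @export
read_hydro_table <- function(path, training = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(hydro_columns, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("cannot parse '%s': missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(names(raw), hydro_columns)
  if (length(unknown)) {
    stop(sprintf("cannot parse '%s': unknown column(s) %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  numeric_cols <- setdiff(hydro_columns, c("station_id", "date", "week"))
  for (cn in numeric_cols) {
    v <- raw[[cn]]
    v[v == ""] <- NA
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s' at line %d of %s",
                   v[bad[1]], cn, bad[1] + 1L, path), call. = FALSE)
    }
    raw[[cn]] <- parsed
  }
  raw$week <- as.integer(raw$week)
  raw$date <- as.Date(raw$date)
  as_hydro_table(raw, training = training)
}
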