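# Tabular I/O. CSV dialect: comma-separated, dot decimal, UTF-8, header
# required, units encoded as column-name suffixes (time_s, height_mm,
# pressure_mmHg by default) with an explicit override. All values are SI
# internally; conversion happens only here.

.TIME_UNITS <- c(s = 1, min = 60, h = 3600)
.HEIGHT_UNITS <- c(m = 1, mm = 1e-3, um = 1e-6)
.PRESSURE_UNITS <- c(Pa = 1, kPa = 1000, mmHg = 133.322)

.unit_factor <- function(unit, table, what) {
  if (!unit %in% names(table)) {
    stop("unknown ", what, " unit '", unit, "'; supported: ",
         paste(names(table), collapse = ", "))
  }
  unname(table[unit])
}

.find_column <- function(nms, stem) {
  hit <- grep(paste0("^", stem, "(_[A-Za-z]+)?$"), nms, value = TRUE)
  if (length(hit) != 1L) {
    stop("expected exactly one column named '", stem, "_<unit>', found ",
         if (length(hit) == 0L) "none" else paste(hit, collapse = ", "))
  }
  hit
}

.column_unit <- function(colname, stem, default) {
  if (colname == stem) default else sub(paste0("^", stem, "_"), "", colname)
}

#' Read a height/pressure time series from CSV
#'
#' Expects header columns `time_<unit>`, `height_<unit>`,
#' `pressure_<unit>`; units are taken from the suffixes (defaults `s`,
#' `mm`, `mmHg`) unless overridden through `units`. Values are converted
#' to SI on read. Validation rejects missing columns, non-monotone time
#' and negative heights, naming the offending row.
#'
#' @param path CSV file path.
#' @param units optional named list/vector overriding the suffix units,
#'   e.g. `c(time = "min")`. Supported units: time s/min/h; height
#'   m/mm/um; pressure Pa/kPa/mmHg.
#' @return a tibble with SI columns `time_s`, `height_m`, `pressure_pa`.
#' @export
read_timeseries <- function(path, units = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  nms <- names(raw)
  col_t <- .find_column(nms, "time")
  col_h <- .find_column(nms, "height")
  col_p <- .find_column(nms, "pressure")
  u_t <- if (!is.null(units) && "time" %in% names(units)) units[["time"]]
         else .column_unit(col_t, "time", "s")
  u_h <- if (!is.null(units) && "height" %in% names(units)) units[["height"]]
         else .column_unit(col_h, "height", "mm")
  u_p <- if (!is.null(units) && "pressure" %in% names(units)) units[["pressure"]]
         else .column_unit(col_p, "pressure", "mmHg")
  out <- tibble::tibble(
    time_s = raw[[col_t]] * .unit_factor(u_t, .TIME_UNITS, "time"),
    height_m = raw[[col_h]] * .unit_factor(u_h, .HEIGHT_UNITS, "height"),
    pressure_pa = raw[[col_p]] * .unit_factor(u_p, .PRESSURE_UNITS, "pressure")
  )
  if (nrow(out) > 1L) {
    bad <- which(diff(out$time_s) <= 0)
    if (length(bad) > 0L) {
      stop("time must be strictly increasing; first violation at row ", bad[1] + 1L)
    }
  }
  neg <- which(out$height_m < 0)
  if (length(neg) > 0L) {
    stop("negative height at row ", neg[1])
  }
  out
}

#' Write a time series to CSV
#'
#' Inverse of [read_timeseries()]: converts the SI series to the requested
#' output units and writes unit-suffixed headers, so a write/read
#' round-trip reproduces the series to full double precision.
#'
#' @param series a tibble with columns `time_s`, `height_m`, `pressure_pa`.
#' @param path output CSV path.
#' @param units named vector of output units; default
#'   `c(time = "s", height = "mm", pressure = "mmHg")`.
#' @return the path, invisibly.
#' @export
write_timeseries <- function(series, path,
                             units = c(time = "s", height = "mm", pressure = "mmHg")) {
  need <- c("time_s", "height_m", "pressure_pa")
  if (!all(need %in% names(series))) {
    stop("`series` must have columns time_s, height_m, pressure_pa")
  }
  out <- data.frame(
    series$time_s / .unit_factor(units[["time"]], .TIME_UNITS, "time"),
    series$height_m / .unit_factor(units[["height"]], .HEIGHT_UNITS, "height"),
    series$pressure_pa / .unit_factor(units[["pressure"]], .PRESSURE_UNITS, "pressure")
  )
  names(out) <- paste(c("time", "height", "pressure"),
                      c(units[["time"]], units[["height"]], units[["pressure"]]),
                      sep = "_")
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read clinical bleb observations from CSV
#'
#' Expected columns: `id`, `radius_mm`, `height_mm`, and optionally
#' `iop_mmHg`, `n_drop_types` (0-4), `leaking` (0/1 or logical).
#'
#' @param path CSV file path.
#' @return a tibble of observations.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  need <- c("radius_mm", "height_mm")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("observations file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) stop("observations file has no rows: ", path)
  bad <- which(raw$radius_mm <= 0 | raw$height_mm <= 0)
  if (length(bad) > 0L) {
    stop("non-positive radius or height at row ", bad[1])
  }
  if ("leaking" %in% names(raw)) raw$leaking <- as.logical(raw$leaking)
  if ("n_drop_types" %in% names(raw)) {
    if (any(raw$n_drop_types < 0 | raw$n_drop_types > 4)) {
      stop("n_drop_types must be between 0 and 4")
    }
  }
  tibble::as_tibble(raw)
}

#' Write clinical bleb observations (or graded observations) to CSV
#'
#' @param observations a data frame of observations, e.g. from
#'   [generate_clinical_blebs()] or [grade_blebs()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_observations <- function(observations, path) {
  out <- as.data.frame(observations)
  if ("leaking" %in% names(out)) out$leaking <- as.integer(out$leaking)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
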