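#' Read a tidy long-format uric acid dataset
#'
#' Reads the package's CSV dialect: one row per record with columns
#' `group`, `time_h`, `record` (one of `dose`, `drug_conc`, `serum_ua`,
#' `urine_ua`), `value`, `units`, and for urine rows `interval_start`
#' and `interval_end`. Values are normalised to the internal unit system
#' on input: serum concentrations given in mg/dL are converted to mg/L
#' and creatinine clearances in mL/min to L/h. Invalid rows (negative
#' time, missing value, urine rows without interval bounds) are dropped;
#' the row numbers and reasons are attached as attribute `rejected` and
#' reported in a message.
#'
#' @param path CSV file path.
#' @return data frame in internal units, with attribute `rejected`.
#' @export
read_ua_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("group", "time_h", "record", "value", "units")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"interval_start" %in% names(df)) df$interval_start <- NA_real_
  if (!"interval_end" %in% names(df)) df$interval_end <- NA_real_
  rejected <- data.frame(row = integer(0), reason = character(0))
  reject <- function(idx, reason) {
    if (any(idx)) {
      rejected <<- rbind(rejected,
                         data.frame(row = which(idx), reason = reason))
    }
    !idx
  }
  keep <- rep(TRUE, nrow(df))
  keep <- keep & reject(!is.finite(df$time_h) | df$time_h < 0,
                        "negative or missing time")
  keep <- keep & reject(!is.finite(df$value), "missing value")
  is_urine <- df$record == "urine_ua"
  keep <- keep & reject(is_urine & (!is.finite(df$interval_start) |
                                      !is.finite(df$interval_end)),
                        "urine row without interval bounds")
  df <- df[keep, , drop = FALSE]
  # unit normalisation to mg, L, h
  to_mgL <- df$units == "mg/dL"
  df$value[to_mgL] <- convert_units(df$value[to_mgL], "mg/dL", "mg/L")
  df$units[to_mgL] <- "mg/L"
  to_Lh <- df$units == "mL/min"
  df$value[to_Lh] <- convert_units(df$value[to_Lh], "mL/min", "L/h")
  df$units[to_Lh] <- "L/h"
  if (nrow(rejected)) {
    message(nrow(rejected), " row(s) rejected while reading ", path)
  }
  attr(df, "rejected") <- rejected
  rownames(df) <- NULL
  df
}

#' Write a tidy uric acid dataset
#'
#' Writes the CSV dialect read back by [read_ua_dataset()].
#'
#' @param data data frame (e.g. the `data` element of
#'   [generate_trial()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ua_dataset <- function(data, path) {
  required <- c("group", "time_h", "record", "value", "units")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
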