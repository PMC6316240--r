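#' Write / read measurement tables
#'
#' Long-format CSV with header
#' `run_id,time_h,variable,value,replicate,censored`; the round trip is
#' lossless including censoring flags. Reading validates variable names and
#' numeric fields; values with locale-style decimal commas are rejected with
#' their line numbers rather than silently parsed.
#'
#' @param table a measurement `data.frame`
#' @param path CSV path
#' @export
write_measurements <- function(table, path) {
  need <- c("run_id", "time_h", "variable", "value", "replicate", "censored")
  stopifnot(all(need %in% names(table)))
  utils::write.csv(table[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("run_id", "time_h", "variable", "value", "replicate", "censored")
  if (!identical(names(raw), need)) {
    stop("measurement CSV must have header ", paste(need, collapse = ","),
         call. = FALSE)
  }
  known <- c("biomass", "glucose", "ethanol", "EAv", "pH", "DOT", "volume", "base")
  bad_var <- !raw$variable %in% known
  if (any(bad_var)) {
    stop("unknown variable name(s): ",
         paste(unique(raw$variable[bad_var]), collapse = ", "), call. = FALSE)
  }
  for (col in c("run_id", "time_h", "value", "replicate")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v) & nzchar(raw[[col]])
    if (any(bad)) {
      stop("malformed numeric field `", col, "` at line(s): ",
           paste(which(bad) + 1L, collapse = ", "),
           " (decimal commas are not accepted)", call. = FALSE)
    }
    raw[[col]] <- v
  }
  raw$censored <- raw$censored %in% c("TRUE", "true", "1")
  raw$run_id <- as.integer(raw$run_id)
  raw$replicate <- as.integer(raw$replicate)
  raw
}

#' Write an unfolded matrix with a two-line header
#'
#' First header line: variable per column; second: grid time per column; then
#' one row per run (run id in the first field).
#'
#' @param m an `unfolded_matrix`
#' @param path CSV path
#' @export
write_unfolded_csv <- function(m, path) {
  meta <- attr(m, "col_meta")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("variable", meta$variable), collapse = ","), con)
  writeLines(paste(c("time_h", meta$time), collapse = ","), con)
  utils::write.table(cbind(run_id = rownames(m), as.data.frame(unclass(m))),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
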