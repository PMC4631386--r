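# Plate-reader dose-response tables (TSV: concentration, signal, replicate).

#' Dose-response plate table
#'
#' @param concentration analyte concentration in molar (>= 0).
#' @param signal measured signal (arbitrary fluorescence units).
#' @param replicate integer replicate label.
#' @return a data.frame of class `plate_table`.
#' @export
plate_table <- function(concentration, signal, replicate = 1L) {
  concentration <- as.numeric(concentration)
  if (any(concentration < 0) || any(!is.finite(concentration)))
    stop("concentrations must be finite and >= 0")
  if (length(unique(concentration)) < 2L)
    stop("a plate table needs at least 2 distinct concentrations")
  df <- data.frame(concentration = concentration,
                   signal = as.numeric(signal),
                   replicate = as.integer(replicate))
  class(df) <- c("plate_table", "data.frame")
  df
}

#' @export
print.plate_table <- function(x, ...) {
  cat(sprintf("plate_table: %d wells, %d concentrations, %d replicate(s)\n",
              nrow(x), length(unique(x$concentration)),
              length(unique(x$replicate))))
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Read a plate table (TSV with header `concentration signal replicate`)
#' @param path input file.
#' @return a [plate_table()].
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#")
  need <- c("concentration", "signal")
  if (!all(need %in% names(df)))
    stop("plate table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  plate_table(df$concentration, df$signal,
              if ("replicate" %in% names(df)) df$replicate else 1L)
}

#' Write a plate table (TSV)
#' @param table a [plate_table()].
#' @param path output file.
#' @export
write_plate_table <- function(table, path) {
  stopifnot(inherits(table, "plate_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
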