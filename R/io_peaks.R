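# Assigned 2D peak tables: one table per titration point, plain TSV with a
# '#ratio' header directive.  Chosen over vendor peak-list formats so that
# fixtures are small, diffable and generator-friendly.

#' Assigned HSQC peak table at one titration point
#'
#' @param residue_index integer residue numbers (unique within the table).
#' @param residue_kind one-letter amino-acid codes.
#' @param h_shift,n_shift amide 1H and 15N chemical shifts (ppm).
#' @param ratio_label ligand:protein molar ratio of this titration point.
#' @return a data.frame of class `peak_table` with attribute `ratio`.
#' @export
peak_table <- function(residue_index, residue_kind, h_shift, n_shift,
                       ratio_label = 0) {
  residue_index <- as.integer(residue_index)
  if (anyDuplicated(residue_index))
    stop("duplicate residue index in peak table: ",
         paste(unique(residue_index[duplicated(residue_index)]), collapse = ", "))
  if (!all(is.finite(h_shift)) || !all(is.finite(n_shift)))
    stop("non-finite chemical shifts")
  if (!is.finite(ratio_label) || ratio_label < 0)
    stop("ratio_label must be a finite number >= 0")
  df <- data.frame(residue_index = residue_index,
                   residue_kind = toupper(as.character(residue_kind)),
                   h_shift = as.numeric(h_shift),
                   n_shift = as.numeric(n_shift),
                   stringsAsFactors = FALSE)
  attr(df, "ratio") <- as.numeric(ratio_label)
  class(df) <- c("peak_table", "data.frame")
  df
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("peak_table: %d residues at ligand:protein ratio %g\n",
              nrow(x), attr(x, "ratio")))
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Read an assigned peak table (TSV)
#'
#' Whitespace- or tab-separated columns `residue kind H N`; lines starting
#' with `#` are comments, except a `#ratio <value>` directive which sets the
#' titration ratio (a `ratio` argument overrides it).
#'
#' @param path input file.
#' @param ratio optional ligand:protein ratio overriding the file directive.
#' @return a [peak_table()].
#' @export
read_peak_table <- function(path, ratio = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  ratio_line <- grep("^#\\s*ratio\\b", lines, value = TRUE)
  file_ratio <- if (length(ratio_line))
    as.numeric(sub("^#\\s*ratio[[:space:]=]+", "", ratio_line[1L])) else NA
  data_lines <- grep("^\\s*(#|$)", lines, invert = TRUE)
  if (!length(data_lines)) stop("no peaks in ", path)
  rows <- vector("list", length(data_lines))
  for (k in seq_along(data_lines)) {
    ln <- data_lines[k]
    f <- strsplit(trimws(lines[ln]), "[\t ]+")[[1L]]
    if (length(f) != 4L)
      stop("malformed line ", ln, " in ", path, ": expected 4 fields, got ",
           length(f))
    h <- suppressWarnings(as.numeric(f[3L]))
    n <- suppressWarnings(as.numeric(f[4L]))
    ri <- suppressWarnings(as.integer(f[1L]))
    if (is.na(ri) || is.na(h) || is.na(n))
      stop("malformed line ", ln, " in ", path, ": non-numeric field")
    rows[[k]] <- list(ri, f[2L], h, n)
  }
  use_ratio <- if (!is.null(ratio)) ratio else file_ratio
  if (is.na(use_ratio))
    stop("no '#ratio' directive in ", path, " and no ratio argument given")
  peak_table(vapply(rows, `[[`, integer(1L), 1L),
             vapply(rows, `[[`, character(1L), 2L),
             vapply(rows, `[[`, numeric(1L), 3L),
             vapply(rows, `[[`, numeric(1L), 4L),
             ratio_label = use_ratio)
}

#' Write an assigned peak table (TSV)
#'
#' @param table a [peak_table()].
#' @param path output file.
#' @export
write_peak_table <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#ratio %.10g", attr(table, "ratio")),
               "# residue kind H N"), con)
  writeLines(sprintf("%d\t%s\t%.5f\t%.5f", table$residue_index,
                     table$residue_kind, table$h_shift, table$n_shift), con)
  invisible(path)
}

#' Read a titration series of peak tables
#'
#' @param paths character vector of peak-table files.
#' @return list of [peak_table()]s sorted by ascending ratio.
#' @export
read_titration_series <- function(paths) {
  tabs <- lapply(paths, read_peak_table)
  tabs[order(vapply(tabs, attr, numeric(1L), "ratio"))]
}
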