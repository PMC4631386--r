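# Distance-restraint tables and their on-disk dialect: one X-PLOR-style
# "assign" line per restraint with explicit lower and upper bounds in
# Angstrom.  The same reader serves as importer for deposited restraint
# files written in this dialect.

#' Distance restraint table
#'
#' @param atom_i,atom_j atom identifiers `"<resid>.<name>"`
#'   (e.g. `"65.HB2"`).
#' @param lower,upper distance bounds in Angstrom, `0 < lower <= upper`.
#' @return a data.frame of class `restraint_table`.
#' @export
restraint_table <- function(atom_i = character(), atom_j = character(),
                            lower = numeric(), upper = numeric()) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (any(lower <= 0) || any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("restraint bounds must be finite and positive")
  bad <- which(lower > upper)
  if (length(bad))
    stop("lower > upper in restraint row(s) ", paste(bad, collapse = ", "))
  df <- data.frame(atom_i = as.character(atom_i),
                   atom_j = as.character(atom_j),
                   lower = lower, upper = upper, stringsAsFactors = FALSE)
  class(df) <- c("restraint_table", "data.frame")
  df
}

#' @export
print.restraint_table <- function(x, ...) {
  cat(sprintf("restraint_table: %d distance restraints\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

.split_atom_id <- function(id) {
  m <- regmatches(id, regexec("^([0-9]+)\\.([A-Za-z0-9']+)$", id))[[1L]]
  if (length(m) != 3L) stop("malformed atom identifier: ", id)
  list(resid = as.integer(m[2L]), name = m[3L])
}

#' Write a restraint table in the "assign" dialect
#'
#' Each row is serialized as
#' `assign (resid R1 and name A1)(resid R2 and name A2) LOWER UPPER`.
#'
#' @param table a [restraint_table()].
#' @param path output file.
#' @export
write_restraint_table <- function(table, path) {
  stopifnot(inherits(table, "restraint_table"))
  lines <- character(nrow(table))
  for (k in seq_len(nrow(table))) {
    ai <- .split_atom_id(table$atom_i[k]); aj <- .split_atom_id(table$atom_j[k])
    lines[k] <- sprintf(
      "assign (resid %d and name %s)(resid %d and name %s) %.2f %.2f",
      ai$resid, ai$name, aj$resid, aj$name, table$lower[k], table$upper[k])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a restraint table in the "assign" dialect
#'
#' @param path input file; blank lines and `!`/`#` comments are skipped.
#' @return a [restraint_table()].
#' @export
read_restraint_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- grep("^\\s*($|[!#])", lines, invert = TRUE)
  pat <- paste0("^\\s*assign\\s*\\(\\s*resid\\s+([0-9]+)\\s+and\\s+name\\s+",
                "([A-Za-z0-9']+)\\s*\\)\\s*\\(\\s*resid\\s+([0-9]+)\\s+and\\s+",
                "name\\s+([A-Za-z0-9']+)\\s*\\)\\s+([0-9.eE+-]+)\\s+([0-9.eE+-]+)")
  out <- list()
  for (ln in keep) {
    m <- regmatches(lines[ln], regexec(pat, lines[ln]))[[1L]]
    if (length(m) != 7L)
      stop("cannot parse restraint line ", ln, " in ", path, ": ", lines[ln])
    lo <- as.numeric(m[6L]); up <- as.numeric(m[7L])
    if (lo > up)
      stop("lower > upper on line ", ln, " in ", path)
    out[[length(out) + 1L]] <-
      data.frame(atom_i = paste0(m[2L], ".", m[3L]),
                 atom_j = paste0(m[4L], ".", m[5L]),
                 lower = lo, upper = up, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(restraint_table())
  df <- do.call(rbind, out)
  restraint_table(df$atom_i, df$atom_j, df$lower, df$upper)
}

#' Check that restraint atoms resolve against a sequence roster
#' @noRd
check_restraints_resolvable <- function(table, sequence) {
  topo <- peptide_topology(as_peptide_sequence(sequence))
  ids <- atom_ids(topo$atoms)
  for (k in seq_len(nrow(table))) {
    for (a in c(table$atom_i[k], table$atom_j[k]))
      if (!a %in% ids)
        stop("restraint row ", k, ": atom ", a,
             " not resolvable against the sequence")
  }
  invisible(TRUE)
}
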