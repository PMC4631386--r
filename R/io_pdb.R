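# Multi-MODEL PDB writer/reader for conformer ensembles (PDB v3.3 fixed
# columns, coordinates to 3 decimals).

.pdb_atom_line <- function(serial, name, resname, resid, xyz, elem) {
  # v3.3 alignment: names of 1-3 characters start in column 14
  aname <- if (nchar(name) < 4L) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, aname, resname, resid, xyz[1L], xyz[2L], xyz[3L], elem)
}

#' Write a conformer ensemble as a multi-MODEL PDB file
#'
#' One `MODEL`/`ENDMDL` block per conformer, all sharing the same atom
#' roster; coordinates in Angstrom to three decimals.
#'
#' @param ensemble a [conformer_ensemble()] (or a single [conformer()]).
#' @param path output file.
#' @export
write_ensemble <- function(ensemble, path) {
  if (inherits(ensemble, "conformer"))
    ensemble <- conformer_ensemble(list(ensemble))
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  confs <- ensemble$conformers
  if (!length(confs)) stop("empty ensemble")
  ref <- atom_ids(confs[[1L]]$atoms)
  for (c in confs)
    if (!identical(atom_ids(c$atoms), ref))
      stop("conformers do not share a common atom roster")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   cspfold ensemble, %d model(s)", length(confs)),
             con)
  for (m in seq_along(confs)) {
    cf <- confs[[m]]
    if (ncol(cf$coords) != 3L)
      stop("conformer ", m, " is not three-dimensional")
    writeLines(sprintf("MODEL     %4d", m), con)
    at <- cf$atoms
    lines <- vapply(seq_len(nrow(at)), function(i)
      .pdb_atom_line(i, at$name[i], .AA3[[at$reskind[i]]], at$resid[i],
                     cf$coords[i, ], at$elem[i]), character(1L))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-MODEL PDB file into a conformer ensemble
#'
#' A minimal fixed-column reader for files written by [write_ensemble()] and
#' other single-chain peptide PDB files.  Files without MODEL records are
#' read as a single conformer.
#'
#' @param path input PDB file.
#' @return a [conformer_ensemble()].
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  aa1 <- stats::setNames(names(.AA3), .AA3)
  models <- list(); cur <- NULL
  push <- function() {
    if (!is.null(cur) && length(cur)) models[[length(models) + 1L]] <<- cur
    cur <<- NULL
  }
  for (ln in lines) {
    tag <- substr(ln, 1L, 6L)
    if (tag == "MODEL ") { push(); cur <- list() }
    else if (tag == "ENDMDL") push()
    else if (tag %in% c("ATOM  ", "HETATM")) {
      if (is.null(cur)) cur <- list()
      cur[[length(cur) + 1L]] <- ln
    }
  }
  push()
  if (!length(models)) stop("no coordinates in ", path)
  confs <- lapply(seq_along(models), function(m) {
    ls <- unlist(models[[m]])
    resname <- trimws(substr(ls, 18L, 20L))
    kind <- aa1[resname]
    if (anyNA(kind))
      stop("non-standard residue in ", path, ": ",
           paste(unique(resname[is.na(kind)]), collapse = ", "))
    atoms <- data.frame(
      resid = as.integer(substr(ls, 23L, 26L)),
      reskind = unname(kind),
      name = trimws(substr(ls, 13L, 16L)),
      elem = trimws(substr(ls, 77L, 78L)),
      stringsAsFactors = FALSE)
    atoms$elem[atoms$elem == ""] <- substr(atoms$name[atoms$elem == ""], 1L, 1L)
    coords <- cbind(as.numeric(substr(ls, 31L, 38L)),
                    as.numeric(substr(ls, 39L, 46L)),
                    as.numeric(substr(ls, 47L, 54L)))
    conformer(coords, atoms, metadata = list(source = path, model = m))
  })
  conformer_ensemble(confs)
}
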