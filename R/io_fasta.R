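#' Peptide sequence with a numbering offset
#'
#' A minimal container for a one-letter amino-acid sequence whose residues
#' are numbered `first_index, first_index + 1, ...` — numbering from the
#' parent protein is preserved throughout the pipeline and never reset.
#'
#' @param residues character vector of one-letter codes (or a single string).
#' @param first_index integer residue number of the first residue.
#' @return an object of class `peptide_sequence`.
#' @examples
#' peptide_sequence("VRRFDLLKRILK", first_index = 62)
#' @export
peptide_sequence <- function(residues, first_index = 1L) {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1L]]
  residues <- toupper(as.character(residues))
  if (!length(residues)) stop("empty sequence")
  bad <- setdiff(residues, names(.AA3))
  if (length(bad))
    stop("illegal residue code(s): ", paste(unique(bad), collapse = ", "))
  structure(list(residues = residues, first_index = as.integer(first_index)),
            class = "peptide_sequence")
}

as_peptide_sequence <- function(x) {
  if (inherits(x, "peptide_sequence")) return(x)
  if (is.character(x)) return(peptide_sequence(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a peptide sequence")
}

#' @export
print.peptide_sequence <- function(x, ...) {
  n <- length(x$residues)
  cat(sprintf("peptide_sequence: %d residues (%d-%d)\n  %s\n", n,
              x$first_index, x$first_index + n - 1L,
              paste(x$residues, collapse = "")))
  invisible(x)
}

#' @export
as.character.peptide_sequence <- function(x, ...) paste(x$residues, collapse = "")

#' @export
length.peptide_sequence <- function(x) length(x$residues)

#' Residue numbers of a peptide sequence
#' @param sequence a [peptide_sequence()].
#' @return integer vector of residue numbers.
#' @export
residue_numbers <- function(sequence) {
  sequence <- as_peptide_sequence(sequence)
  seq(sequence$first_index, length.out = length(sequence$residues))
}

#' Read a single-record FASTA peptide sequence
#'
#' The header may carry a `start=N` token setting the numbering offset of
#' the first residue (e.g. `>R4 start=62`); otherwise numbering starts at 1.
#' Lowercase sequence letters are upcased.  Multi-record files are rejected:
#' the pipeline operates on one peptide at a time.
#'
#' @param path path to a FASTA file.
#' @return a [peptide_sequence()].
#' @export
read_sequence <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0L) stop("no sequence records in ", path)
  if (length(recs) > 1L)
    stop("expected a single-record FASTA, found ", length(recs),
         " records in ", path)
  ann <- attr(recs[[1L]], "Annot")
  start <- 1L
  m <- regmatches(ann, regexpr("start=([-0-9]+)", ann))
  if (length(m) && nzchar(m)) start <- as.integer(sub("start=", "", m))
  peptide_sequence(as.character(recs[[1L]]), first_index = start)
}

#' Write a peptide sequence as FASTA
#'
#' @param sequence a [peptide_sequence()].
#' @param path output path.
#' @param name record name (the `start=` token is appended automatically).
#' @export
write_sequence <- function(sequence, path, name = "peptide") {
  sequence <- as_peptide_sequence(sequence)
  writeLines(c(sprintf(">%s start=%d", name, sequence$first_index),
               as.character(sequence)), path)
  invisible(path)
}
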