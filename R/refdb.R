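#' Reference entry and reference database
#'
#' A reference entry couples an amino-acid sequence with its three-state
#' domain/hinge/boundary labels; a reference database is a collection of
#' entries with unique ids against which queries are aligned to derive DHB
#' profiles.
#'
#' @param id Character identifier.
#' @param sequence Amino-acid string (20-letter alphabet plus `X`).
#' @param labels3 Integer labels over `{0,1,2}`, one per residue.
#' @return `reference_entry()` returns a `reference_entry`;
#'   `build_reference_db()` a `reference_db`.
#' @export
reference_entry <- function(id, sequence, labels3) {
  sequence <- toupper(as.character(sequence))
  check_aa(sequence)
  if (nchar(sequence) != length(labels3))
    stop("sequence and labels3 lengths differ for ", id)
  if (any(labels3 < 0L | labels3 > 2L))
    stop("labels3 must be over {0,1,2}")
  structure(list(id = as.character(id), sequence = sequence,
                 labels3 = as.integer(labels3)),
            class = "reference_entry")
}

AA_ALPHABET20X <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                    "F","P","S","T","W","Y","V","X")

check_aa <- function(sequence) {
  chars <- unique(strsplit(sequence, "")[[1L]])
  bad <- setdiff(chars, AA_ALPHABET20X)
  if (length(bad)) stop("non-amino-acid characters in sequence: ",
                        paste(bad, collapse = ""))
  invisible(sequence)
}

#' @rdname reference_entry
#' @param entries List of `reference_entry` objects.
#' @param exclude_exact_of Optional character vector of sequences; entries
#'   whose sequence exactly matches one of them are dropped (used to remove
#'   reference chains identical to evaluation targets).
#' @export
build_reference_db <- function(entries, exclude_exact_of = NULL) {
  ids <- vapply(entries, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate reference ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(exclude_exact_of)) {
    keep <- !vapply(entries, function(e) e$sequence %in% exclude_exact_of, TRUE)
    entries <- entries[keep]
    ids <- ids[keep]
  }
  seqs <- Biostrings::AAStringSet(vapply(entries, `[[`, "", "sequence"))
  names(seqs) <- ids
  structure(list(entries = stats::setNames(entries, ids), seqs = seqs,
                 total_residues = sum(Biostrings::width(seqs))),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("reference_db:", length(x$entries), "entries,",
      x$total_residues, "residues\n")
  invisible(x)
}

#' @export
length.reference_db <- function(x) length(x$entries)

#' Write / read a reference database
#'
#' On disk a database is a FASTA file of the sequences plus a parallel label
#' TSV (see [write_labels()]) with the same ids.
#'
#' @param db A `reference_db`.
#' @param fasta,labels File paths for the FASTA and label files.
#' @export
write_reference_db <- function(db, fasta, labels) {
  Biostrings::writeXStringSet(db$seqs, fasta)
  write_labels(lapply(db$entries, `[[`, "labels3"), labels)
  invisible(db)
}

#' @rdname write_reference_db
#' @export
read_reference_db <- function(fasta, labels) {
  seqs <- Biostrings::readAAStringSet(fasta)
  labs <- read_labels(labels, arity = 3L)
  if (!setequal(names(seqs), names(labs)))
    stop("FASTA and label files carry different chain ids")
  entries <- lapply(names(seqs), function(id)
    reference_entry(id, as.character(seqs[[id]]), labs[[id]]))
  build_reference_db(entries)
}

#' Search parameters for reference-database alignment
#'
#' Hit selection follows the profile-construction recipe: keep alignments
#' with e-value at most `e_max`, rank ascending by e-value and retain the
#' top `top_s` (fewer when fewer qualify).
#'
#' @param e_max E-value ceiling, default 0.1.
#' @param top_s Maximum number of hits kept, default 10.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param matrix Substitution matrix name understood by Biostrings.
#' @return An object of class `search_params`.
#' @export
search_params <- function(e_max = 0.1, top_s = 10L, gap_open = 11,
                          gap_extend = 1, matrix = "BLOSUM62") {
  if (e_max <= 0) stop("e_max must be positive")
  top_s <- as.integer(top_s)
  if (top_s < 1L) stop("top_s must be at least 1")
  structure(list(e_max = e_max, top_s = top_s, gap_open = gap_open,
                 gap_extend = gap_extend, matrix = matrix),
            class = "search_params")
}
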