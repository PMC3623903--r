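#' Compute the DHB profile of a query from its alignment hits
#'
#' For every query position `p` and state `s` (domain, hinge, boundary),
#' counts the hits whose alignment maps `p` onto a subject residue labeled
#' `s`, and normalizes by the total number of hits aligning `p`, so each
#' covered row of the profile is the empirical three-state frequency among
#' aligned homologs. Positions aligned by no hit are all-zero and flagged
#' uncovered (no homology evidence).
#'
#' @param query_length Integer length of the query.
#' @param hits List of `alignment_hit` objects (already filtered and ranked
#'   by the search contract).
#' @param db The `reference_db` the hits refer to.
#' @return An object of class `dhb_profile`: list with `values` (L x 3
#'   matrix, columns `P_domain`, `P_hinge`, `P_boundary`) and `covered`
#'   (logical vector of length L).
#' @export
compute_dhb_profile <- function(query_length, hits, db) {
  L <- as.integer(query_length)
  counts <- matrix(0, nrow = L, ncol = 3L,
                   dimnames = list(NULL, c("P_domain", "P_hinge", "P_boundary")))
  for (h in hits) {
    labs <- db$entries[[h$subject_id]]$labels3
    if (is.null(labs)) stop("hit references unknown subject ", h$subject_id)
    if (max(h$pairs[, 2L]) > length(labs))
      stop("aligned pair beyond label string of subject ", h$subject_id)
    if (max(h$pairs[, 1L]) > L)
      stop("aligned pair beyond query length")
    # label codes (0 domain, 1 boundary, 2 hinge) -> columns (D, H, B)
    s <- c(1L, 3L, 2L)[labs[h$pairs[, 2L]] + 1L]
    idx <- cbind(h$pairs[, 1L], s)
    for (r in seq_len(nrow(idx)))
      counts[idx[r, 1L], idx[r, 2L]] <- counts[idx[r, 1L], idx[r, 2L]] + 1
  }
  tot <- rowSums(counts)
  covered <- tot > 0
  values <- counts
  values[covered, ] <- counts[covered, , drop = FALSE] / tot[covered]
  structure(list(values = values, covered = covered), class = "dhb_profile")
}

#' @export
print.dhb_profile <- function(x, ...) {
  cat("dhb_profile:", nrow(x$values), "positions,",
      sum(x$covered), "covered\n")
  invisible(x)
}

#' Write / read a DHB profile as TSV
#'
#' Columns: `position`, `residue`, `P_domain`, `P_hinge`, `P_boundary`
#' (frequencies written with 4 decimal places).
#'
#' @param profile A `dhb_profile`.
#' @param sequence The query sequence (for the `residue` column).
#' @param path File path.
#' @export
write_dhb_profile <- function(profile, sequence, path) {
  df <- data.frame(position = seq_len(nrow(profile$values)),
                   residue = strsplit(sequence, "")[[1L]],
                   P_domain = sprintf("%.4f", profile$values[, 1L]),
                   P_hinge = sprintf("%.4f", profile$values[, 2L]),
                   P_boundary = sprintf("%.4f", profile$values[, 3L]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dhb_profile
#' @export
read_dhb_profile <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, c("P_domain", "P_hinge", "P_boundary")])
  dimnames(values) <- list(NULL, c("P_domain", "P_hinge", "P_boundary"))
  structure(list(values = values, covered = rowSums(values) > 0),
            class = "dhb_profile")
}
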