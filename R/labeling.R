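#' Domain annotation for a protein chain
#'
#' Bundles the chain length with an ordered list of domains, each domain a
#' set of residue segments in 1-based inclusive coordinates (CATH-style;
#' discontinuous domains carry more than one segment).
#'
#' @param chain_id Character identifier of the chain.
#' @param length Integer chain length (number of residues).
#' @param domains List of domains; each domain is a two-column matrix (or a
#'   list of `c(start, end)` pairs) of residue segments, 1-based inclusive.
#' @return An object of class `domain_annotation`.
#' @examples
#' ann <- domain_annotation("chainA", 30, list(cbind(5, 26)))
#' assign_two_state_labels(ann)
#' @export
domain_annotation <- function(chain_id, length, domains = list()) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("chain length must be a positive integer")
  domains <- lapply(domains, function(d) {
    if (is.list(d)) d <- do.call(rbind, d)
    d <- matrix(as.integer(d), ncol = 2L)
    colnames(d) <- c("start", "end")
    d[order(d[, 1L]), , drop = FALSE]
  })
  ann <- structure(list(chain_id = as.character(chain_id), length = length,
                        domains = domains),
                   class = "domain_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  L <- ann$length
  occ <- integer(L)
  for (d in ann$domains) {
    if (any(d[, 1L] > d[, 2L]) || any(d[, 1L] < 1L) || any(d[, 2L] > L))
      stop("segment coordinates must satisfy 1 <= start <= end <= length")
    for (i in seq_len(nrow(d))) occ[d[i, 1L]:d[i, 2L]] <- occ[d[i, 1L]:d[i, 2L]] + 1L
  }
  if (any(occ > 1L)) stop("domain segments overlap at residue ",
                          which(occ > 1L)[1L])
  invisible(ann)
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat("domain_annotation", x$chain_id, "- length", x$length, "-",
      length(x$domains), "domain(s)\n")
  invisible(x)
}

#' Two-state boundary labels from a domain annotation
#'
#' Labels every residue as boundary (`1`) or domain (`0`). Boundary residues
#' are (i) residues outside all domain segments and (ii) the first and last
#' residue of every domain segment, so that when two domains touch, the two
#' contacted residues are both boundaries.
#'
#' @param annotation A [domain_annotation()].
#' @return Integer vector of 0/1 codes, one per residue, with attribute
#'   `arity = 2`.
#' @export
assign_two_state_labels <- function(annotation) {
  validate_annotation(annotation)
  lab <- rep(1L, annotation$length)
  for (d in annotation$domains)
    for (i in seq_len(nrow(d)))
      lab[d[i, 1L]:d[i, 2L]] <- 0L
  for (d in annotation$domains)
    for (i in seq_len(nrow(d)))
      lab[c(d[i, 1L], d[i, 2L])] <- 1L
  structure(lab, arity = 2L)
}

#' Hinge-region configuration
#'
#' @param R Hinge half-width in residues: each domain-segment terminus seeds
#'   a window of `2R` residues, `R` on the domain side and `R` on the
#'   boundary side. Default 10.
#' @return An object of class `hinge_config`.
#' @export
hinge_config <- function(R = 10L) {
  R <- as.integer(R)
  if (is.na(R) || R < 0L) stop("R must be a non-negative integer")
  structure(list(R = R), class = "hinge_config")
}

#' Three-state domain/hinge/boundary labels
#'
#' Overlays hinge regions (`2`) on the two-state labels. For a segment
#' N-terminus at position `t` the window covers `t-R .. t+R-1`; for a
#' C-terminus at `t` it covers `t-R+1 .. t+R`, so each window straddles the
#' terminus with `R` residues on the domain side and `R` on the boundary
#' side. Windows are truncated at the chain ends and overlapping windows
#' take their union; hinge overrides both other codes.
#'
#' @param labels2 Two-state labels from [assign_two_state_labels()] on the
#'   same annotation.
#' @param annotation The [domain_annotation()].
#' @param cfg A [hinge_config()].
#' @return Integer vector over `{0,1,2}` with attribute `arity = 3`.
#' @export
assign_hinge_labels <- function(labels2, annotation, cfg = hinge_config()) {
  stopifnot(length(labels2) == annotation$length)
  lab <- as.integer(labels2)
  R <- cfg$R
  L <- annotation$length
  if (R > 0L) {
    for (d in annotation$domains) {
      for (i in seq_len(nrow(d))) {
        nw <- max(1L, d[i, 1L] - R):min(L, d[i, 1L] + R - 1L)
        cw <- max(1L, d[i, 2L] - R + 1L):min(L, d[i, 2L] + R)
        lab[nw] <- 2L
        lab[cw] <- 2L
      }
    }
  }
  structure(lab, arity = 3L)
}

#' Convert label codes to/from their one-character-per-residue string form
#'
#' @param labels Integer label vector.
#' @return `labels_to_string()` returns a single string like `"0012210"`;
#'   `labels_from_string()` returns the integer vector, carrying an `arity`
#'   attribute.
#' @param s A label string.
#' @param arity 2 or 3.
#' @export
labels_to_string <- function(labels) paste(labels, collapse = "")

#' @rdname labels_to_string
#' @export
labels_from_string <- function(s, arity = 3L) {
  codes <- as.integer(strsplit(s, "")[[1L]])
  if (anyNA(codes) || any(codes >= arity) || any(codes < 0L))
    stop("label string contains codes outside the declared alphabet")
  structure(codes, arity = as.integer(arity))
}

#' Read and write domain annotations
#'
#' The annotation file is a TSV with one row per domain segment and columns
#' `chain_id`, `domain_index` (1-based), `seg_start`, `seg_end` (1-based
#' inclusive). Chain lengths come from `lengths`, a named integer vector
#' (typically `width()` of the FASTA records with matching ids).
#'
#' @param path File path.
#' @param lengths Named integer vector of chain lengths.
#' @return A named list of [domain_annotation()] objects.
#' @export
read_annotations <- function(path, lengths) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chain_id", "domain_index", "seg_start", "seg_end")
  if (!all(need %in% names(df))) stop("annotation file must have columns: ",
                                      paste(need, collapse = ", "))
  out <- list()
  for (id in unique(df$chain_id)) {
    if (!id %in% names(lengths)) stop("no sequence length for chain ", id)
    rows <- df[df$chain_id == id, , drop = FALSE]
    idx <- factor(rows$domain_index, levels = sort(unique(rows$domain_index)))
    doms <- unname(lapply(split(rows, idx),
                          function(r) cbind(r$seg_start, r$seg_end)))
    out[[id]] <- domain_annotation(id, lengths[[id]], doms)
  }
  out
}

#' @rdname read_annotations
#' @param annotations Named list of [domain_annotation()] objects.
#' @export
write_annotations <- function(annotations, path) {
  rows <- list()
  for (ann in annotations)
    for (di in seq_along(ann$domains)) {
      d <- ann$domains[[di]]
      for (i in seq_len(nrow(d)))
        rows[[length(rows) + 1L]] <-
          data.frame(chain_id = ann$chain_id, domain_index = di,
                     seg_start = d[i, 1L], seg_end = d[i, 2L])
    }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain_id = character(), domain_index = integer(),
               seg_start = integer(), seg_end = integer())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write per-chain label strings
#'
#' TSV with columns `chain_id` and `labels` (a string over `{0,1,2}` aligned
#' to the sequence).
#'
#' @param path File path.
#' @param arity Label alphabet size, 2 or 3.
#' @return Named list of integer label vectors.
#' @export
read_labels <- function(path, arity = 3L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  out <- lapply(df$labels, labels_from_string, arity = arity)
  names(out) <- df$chain_id
  out
}

#' @rdname read_labels
#' @param labels Named list of label vectors.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(chain_id = names(labels),
                   labels = vapply(labels, labels_to_string, ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
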