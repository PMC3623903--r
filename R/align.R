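#' Local alignment search against a reference database
#'
#' Smith-Waterman local alignment with affine gaps of a query against every
#' entry of a [build_reference_db()] database, with Karlin-Altschul
#' e-values. Hits with `evalue <= e_max` are ranked ascending by e-value
#' (ties by bit score descending, then subject id) and truncated to the top
#' `top_s`; one alignment (the best-scoring) is kept per subject.
#'
#' @param query Amino-acid string.
#' @param db A `reference_db`.
#' @param params A [search_params()].
#' @return List of `alignment_hit` objects, each with `subject_id`,
#'   `evalue`, `bits`, `score`, and `pairs` (two-column integer matrix of
#'   aligned `(query_pos, subject_pos)` residue pairs, 1-based, strictly
#'   increasing in both coordinates, gap columns omitted).
#' @export
local_align_search <- function(query, db, params = search_params()) {
  query <- toupper(as.character(query))
  if (nchar(query) < 1L) stop("query must have length >= 1")
  check_aa(query)
  if (length(db$entries) == 0L) return(list())

  scores <- Biostrings::pairwiseAlignment(
    db$seqs, query, type = "local",
    substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE)
  ev <- karlin_altschul_evalue(scores, nchar(query), db$total_residues)
  bits <- karlin_altschul_bits(scores)

  keep <- which(ev <= params$e_max)
  if (!length(keep)) return(list())
  ids <- names(db$seqs)[keep]
  ord <- order(ev[keep], -bits[keep], ids)
  keep <- keep[ord][seq_len(min(params$top_s, length(keep)))]

  aln <- Biostrings::pairwiseAlignment(
    db$seqs[keep], query, type = "local",
    substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  s_gapped <- as.character(Biostrings::pattern(aln))
  q_gapped <- as.character(Biostrings::subject(aln))
  s_starts <- Biostrings::start(Biostrings::pattern(aln))
  q_starts <- Biostrings::start(Biostrings::subject(aln))
  lapply(seq_along(keep), function(i) {
    k <- keep[i]
    pairs <- aligned_pairs(q_gapped[i], s_gapped[i],
                           q_start = q_starts[i], s_start = s_starts[i])
    alignment_hit(names(db$seqs)[k], ev[k], pairs,
                  bits = bits[k], score = scores[k])
  })
}

#' @rdname local_align_search
#' @param subject_id,evalue,pairs,bits,score Hit fields; `pairs` is the
#'   two-column matrix of aligned `(query_pos, subject_pos)` residue pairs.
#' @export
alignment_hit <- function(subject_id, evalue, pairs, bits = NA_real_,
                          score = NA_real_) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  colnames(pairs) <- c("query_pos", "subject_pos")
  if (nrow(pairs) == 0L) stop("alignment hit must align at least one pair")
  if (any(diff(pairs[, 1L]) <= 0L) || any(diff(pairs[, 2L]) <= 0L))
    stop("aligned pairs must be strictly increasing in both coordinates")
  if (evalue <= 0) stop("evalue must be positive")
  structure(list(subject_id = as.character(subject_id),
                 evalue = as.numeric(evalue), bits = bits, score = score,
                 pairs = pairs),
            class = "alignment_hit")
}

# Walk two gapped aligned strings and emit 1-based (query, subject)
# coordinates of the match/mismatch columns.
aligned_pairs <- function(q_gapped, s_gapped, q_start, s_start) {
  qc <- strsplit(q_gapped, "")[[1L]]
  sc <- strsplit(s_gapped, "")[[1L]]
  qi <- q_start - 1L + cumsum(qc != "-")
  si <- s_start - 1L + cumsum(sc != "-")
  both <- qc != "-" & sc != "-"
  cbind(qi[both], si[both])
}

# Karlin-Altschul statistics for BLOSUM62 with affine gaps 11/1 (standard
# gapped approximation; constants as used by protein BLAST for this
# scoring system). E = K * m * n * exp(-lambda * S).
KA_LAMBDA <- 0.267
KA_K <- 0.041

karlin_altschul_evalue <- function(score, m, n) {
  # floor far below any usable threshold keeps strong hits representable
  pmax(KA_K * m * n * exp(-KA_LAMBDA * score), 1e-300)
}

karlin_altschul_bits <- function(score) {
  (KA_LAMBDA * score - log(KA_K)) / log(2)
}

#' Import externally computed alignment hits
#'
#' Reads a tab-separated hit table (e.g. derived from BLAST output) and
#' applies the same filtering/ranking contract as [local_align_search()].
#' Expected columns: `query_id`, `subject_id`, `evalue`, `bits`, `blocks`,
#' where `blocks` lists ungapped aligned blocks as
#' `qstart-qend/sstart-send` separated by `;` (1-based inclusive).
#'
#' @param path Path to the hit table.
#' @param db A `reference_db`; every subject id must be present.
#' @param params A [search_params()] (only `e_max` and `top_s` are used).
#' @return Named list (by query id) of lists of `alignment_hit` objects.
#' @export
import_tabular_hits <- function(path, db, params = search_params()) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("query_id", "subject_id", "evalue", "bits", "blocks")
  if (!all(need %in% names(df)))
    stop("hit table must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(unique(df$subject_id), names(db$entries))
  if (length(missing))
    stop("subject id(s) absent from reference db: ",
         paste(missing, collapse = ", "))
  out <- list()
  for (qid in unique(df$query_id)) {
    rows <- df[df$query_id == qid & df$evalue <= params$e_max, , drop = FALSE]
    if (!nrow(rows)) { out[[qid]] <- list(); next }
    rows <- rows[order(rows$evalue, -rows$bits, rows$subject_id), , drop = FALSE]
    rows <- rows[seq_len(min(params$top_s, nrow(rows))), , drop = FALSE]
    out[[qid]] <- lapply(seq_len(nrow(rows)), function(i)
      alignment_hit(rows$subject_id[i], rows$evalue[i],
                    parse_blocks(rows$blocks[i]), bits = rows$bits[i]))
  }
  out
}

parse_blocks <- function(blocks) {
  parts <- strsplit(blocks, ";", fixed = TRUE)[[1L]]
  pairs <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\d+)-(\\d+)/(\\d+)-(\\d+)$", p))[[1L]]
    if (length(m) != 5L) stop("malformed alignment block: ", p)
    v <- as.integer(m[-1L])
    if (v[2L] - v[1L] != v[4L] - v[3L])
      stop("block query and subject spans differ in length: ", p)
    cbind(v[1L]:v[2L], v[3L]:v[4L])
  })
  do.call(rbind, pairs)
}

format_blocks <- function(pairs) {
  brk <- c(0L, which(diff(pairs[, 1L]) != 1L | diff(pairs[, 2L]) != 1L),
           nrow(pairs))
  paste(vapply(seq_len(length(brk) - 1L), function(i) {
    a <- brk[i] + 1L; b <- brk[i + 1L]
    sprintf("%d-%d/%d-%d", pairs[a, 1L], pairs[b, 1L],
            pairs[a, 2L], pairs[b, 2L])
  }, ""), collapse = ";")
}

#' Write alignment hits to the tabular format read by [import_tabular_hits()]
#'
#' @param hits Named list (by query id) of lists of `alignment_hit` objects.
#' @param path Output path.
#' @export
write_tabular_hits <- function(hits, path) {
  rows <- list()
  for (qid in names(hits))
    for (h in hits[[qid]])
      rows[[length(rows) + 1L]] <-
        data.frame(query_id = qid, subject_id = h$subject_id,
                   evalue = h$evalue, bits = h$bits,
                   blocks = format_blocks(h$pairs))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), subject_id = character(),
               evalue = numeric(), bits = numeric(), blocks = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
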