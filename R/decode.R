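#' Decision-threshold configuration for two-state decoding
#'
#' Residues in predicted hinge regions are called boundary when their
#' posterior hinge probability exceeds `t_hinge` (default 0.4, the value
#' that maximizes the weighted score in threshold sweeps); residues in
#' predicted domain regions are called domain when their posterior domain
#' probability exceeds `t_domain` (default 0.75). `mode` selects which
#' rules are active: `hinge_only` (default, matching the large-scale
#' operating point), `domain_only`, or `both`.
#'
#' @param t_hinge,t_domain Thresholds in `[0, 1]`.
#' @param mode One of `"hinge_only"`, `"domain_only"`, `"both"`.
#' @return An object of class `decode_config`.
#' @export
decode_config <- function(t_hinge = 0.4, t_domain = 0.75,
                          mode = c("hinge_only", "domain_only", "both")) {
  mode <- match.arg(mode)
  if (t_hinge < 0 || t_hinge > 1 || t_domain < 0 || t_domain > 1)
    stop("thresholds must be in [0, 1]")
  structure(list(t_hinge = t_hinge, t_domain = t_domain, mode = mode),
            class = "decode_config")
}

#' Segment marginals into maximal same-state argmax regions
#'
#' @param marginals An L x 3 marginal matrix (see [posterior_marginals()]).
#' @return Data frame with columns `state` (0 domain, 1 boundary, 2 hinge
#'   -- the label codes), `start`, `end` (1-based inclusive); the regions
#'   partition `1..L`. Argmax ties break toward the lower label code.
#' @export
argmax_regions <- function(marginals) {
  # column order of the marginal matrix is (domain, hinge, boundary) =
  # codes (0, 2, 1); map argmax columns back to label codes with the tie
  # broken toward the lower code (domain < boundary < hinge)
  code_by_col <- c(0L, 2L, 1L)
  ord <- c(1L, 3L, 2L)  # scan columns in code order 0,1,2
  am <- code_by_col[ord][max.col(marginals[, ord, drop = FALSE],
                                 ties.method = "first")]
  r <- rle(am)
  ends <- cumsum(r$lengths)
  data.frame(state = r$values,
             start = ends - r$lengths + 1L,
             end = ends)
}

#' Decode marginals into final two-state boundary calls
#'
#' Residues in argmax-boundary regions are always called boundary (1).
#' Residues in argmax-hinge regions are called boundary when
#' `P_hinge > t_hinge` (modes `hinge_only` and `both`); in mode
#' `domain_only` the hinge rule is inactive and hinge-region residues are
#' called boundary when their combined hinge+boundary mass exceeds the
#' domain mass. Residues in argmax-domain regions are called domain (0),
#' except in modes `domain_only` and `both`, where they are called domain
#' only when `P_domain > t_domain`. The per-residue ROC score is
#' `1 - P_domain` (boundary plus hinge mass as boundary evidence).
#'
#' @param marginals An L x 3 marginal matrix.
#' @param regions Regions from [argmax_regions()] on the same marginals.
#' @param cfg A [decode_config()].
#' @return An object of class `boundary_prediction`: list with `calls2`
#'   (0/1 integer vector, arity 2) and `scores` (numeric in `[0, 1]`).
#' @export
decide_two_state <- function(marginals, regions, cfg = decode_config()) {
  L <- nrow(marginals)
  calls <- integer(L)
  for (i in seq_len(nrow(regions))) {
    idx <- regions$start[i]:regions$end[i]
    st <- regions$state[i]
    if (st == 1L) {
      calls[idx] <- 1L
    } else if (st == 0L) {
      calls[idx] <- if (cfg$mode %in% c("domain_only", "both"))
        as.integer(!(marginals[idx, 1L] > cfg$t_domain)) else 0L
    } else {
      calls[idx] <- if (cfg$mode %in% c("hinge_only", "both"))
        as.integer(marginals[idx, 2L] > cfg$t_hinge)
      else
        as.integer(marginals[idx, 2L] + marginals[idx, 3L] >
                     marginals[idx, 1L])
    }
  }
  structure(list(calls2 = structure(calls, arity = 2L),
                 scores = 1 - marginals[, 1L]),
            class = "boundary_prediction")
}

#' Write a per-residue prediction table
#'
#' TSV with columns `position`, `residue`, `P_domain`, `P_hinge`,
#' `P_boundary`, `score`, `call`; a `#`-prefixed header line records the
#' thresholds and mode.
#'
#' @param prediction A `boundary_prediction`.
#' @param marginals The marginal matrix the prediction came from.
#' @param sequence Query sequence.
#' @param path File path.
#' @param cfg The [decode_config()] used.
#' @param model_id Identifier recorded in the header.
#' @export
write_prediction <- function(prediction, marginals, sequence, path,
                             cfg = decode_config(), model_id = "unnamed") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# model=%s t_hinge=%g t_domain=%g mode=%s",
                     model_id, cfg$t_hinge, cfg$t_domain, cfg$mode), con)
  df <- data.frame(position = seq_len(nrow(marginals)),
                   residue = strsplit(sequence, "")[[1L]],
                   P_domain = sprintf("%.4f", marginals[, 1L]),
                   P_hinge = sprintf("%.4f", marginals[, 2L]),
                   P_boundary = sprintf("%.4f", marginals[, 3L]),
                   score = sprintf("%.4f", prediction$scores),
                   call = prediction$calls2)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
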