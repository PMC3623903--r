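#' Shape strings
#'
#' One character per residue over the 8-letter backbone shape alphabet
#' (`R,S,U,V,K,A,T,G`, from Ramachandran-space clustering of phi/psi
#' angles), with `-` for unknown. A missing shape string is represented as
#' all `-`, which lets profile-only models run.
#'
#' @param symbols A string (or character vector of single characters).
#' @param length Expected length (checked when given).
#' @return Character vector of single symbols, class `shape_string`.
#' @export
shape_string <- function(symbols, length = NULL) {
  if (is.character(symbols) && base::length(symbols) == 1L)
    symbols <- strsplit(symbols, "")[[1L]]
  bad <- setdiff(unique(symbols), c(SHAPE_ALPHABET, "-"))
  if (base::length(bad)) stop("symbols outside the shape alphabet: ",
                              paste(bad, collapse = ""))
  if (!is.null(length) && base::length(symbols) != length)
    stop("shape string length ", base::length(symbols),
         " does not match expected length ", length)
  structure(symbols, class = "shape_string")
}

#' @rdname shape_string
#' @format NULL
#' @export
SHAPE_ALPHABET <- c("R", "S", "U", "V", "K", "A", "T", "G")

#' @rdname shape_string
#' @export
blank_shape <- function(length) shape_string(rep("-", length))

#' Read and write shape-string files
#'
#' TSV with columns `chain_id` and `shape` (one symbol per residue).
#'
#' @param path File path.
#' @return Named list of `shape_string` objects.
#' @export
read_shapes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  out <- lapply(df$shape, shape_string)
  names(out) <- df$chain_id
  out
}

#' @rdname read_shapes
#' @param shapes Named list of `shape_string` objects.
#' @export
write_shapes <- function(shapes, path) {
  df <- data.frame(chain_id = names(shapes),
                   shape = vapply(shapes, paste, "", collapse = ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Unigram feature-template configuration
#'
#' The template traverses all four observation columns (three DHB profile
#' columns plus the shape string) and, for each position, emits one
#' categorical feature per column per offset in
#' `[-window_back, +window_fwd]`. Numeric profile values are discretized to
#' a grid of width `bin_width` (round-half-up), mirroring the categorical
#' treatment of feature strings in CRF toolkits.
#'
#' @param window_back,window_fwd Window extents (defaults 4 and 4).
#' @param bin_width Bin width in `(0, 1]` with `1/bin_width` integral;
#'   default 0.1.
#' @return An object of class `template_config`.
#' @export
template_config <- function(window_back = 4L, window_fwd = 4L,
                            bin_width = 0.1) {
  window_back <- as.integer(window_back); window_fwd <- as.integer(window_fwd)
  if (window_back < 0L || window_fwd < 0L) stop("window sizes must be >= 0")
  if (bin_width <= 0 || bin_width > 1) stop("bin_width must be in (0, 1]")
  if (abs(1 / bin_width - round(1 / bin_width)) > 1e-9)
    stop("1/bin_width must be an integer")
  structure(list(window_back = window_back, window_fwd = window_fwd,
                 bin_width = bin_width), class = "template_config")
}

bin_category <- function(v, bin_width) {
  digits <- max(0L, ceiling(-log10(bin_width) - 1e-9))
  sprintf(paste0("%.", digits, "f"),
          floor(v / bin_width + 0.5) * bin_width)
}

#' Expand profile and shape columns into windowed categorical features
#'
#' For each position `i`, each column `c` in `{D, H, B, S}` (the three DHB
#' profile columns and the shape string) and each offset `o` in
#' `[-window_back, +window_fwd]`, emits the feature id `"c:o:cat"`, where
#' `cat` is the binned value (numeric columns) or shape symbol at `i + o`.
#' Offsets falling before the first or past the last residue emit the
#' sentinel categories `_BOS_` / `_EOS_`.
#'
#' @param profile A `dhb_profile`.
#' @param shape A [shape_string()] of the same length.
#' @param cfg A [template_config()].
#' @return Character matrix with one row per position and
#'   `(window_back + 1 + window_fwd) * 4` feature ids per row, class
#'   `feature_sequence`.
#' @export
encode_features <- function(profile, shape, cfg = template_config()) {
  L <- nrow(profile$values)
  if (length(shape) != L)
    stop("profile and shape lengths differ (", L, " vs ", length(shape), ")")
  cols <- list(D = bin_category(profile$values[, 1L], cfg$bin_width),
               H = bin_category(profile$values[, 2L], cfg$bin_width),
               B = bin_category(profile$values[, 3L], cfg$bin_width),
               S = as.character(shape))
  offsets <- seq.int(-cfg$window_back, cfg$window_fwd)
  out <- matrix("", nrow = L, ncol = length(offsets) * length(cols))
  j <- 0L
  for (cn in names(cols)) {
    v <- cols[[cn]]
    for (o in offsets) {
      j <- j + 1L
      idx <- seq_len(L) + o
      cat <- ifelse(idx < 1L, "_BOS_", ifelse(idx > L, "_EOS_",
                    v[pmin(pmax(idx, 1L), L)]))
      out[, j] <- paste0(cn, ":", o, ":", cat)
    }
  }
  structure(out, class = "feature_sequence")
}
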