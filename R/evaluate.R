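#' Residue-level confusion counts
#'
#' Boundary (label 1) is the positive class.
#'
#' @param pred,truth Two-state label vectors of equal length.
#' @return An object of class `confusion`: list with `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("prediction and truth lengths differ")
  if (any(pred < 0L | pred > 1L) || any(truth < 0L | truth > 1L))
    stop("confusion counts require two-state (0/1) labels")
  structure(list(TP = sum(pred == 1L & truth == 1L),
                 FP = sum(pred == 1L & truth == 0L),
                 TN = sum(pred == 0L & truth == 0L),
                 FN = sum(pred == 0L & truth == 1L)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

add_confusions <- function(cs) {
  structure(list(TP = sum(vapply(cs, `[[`, 0, "TP")),
                 FP = sum(vapply(cs, `[[`, 0, "FP")),
                 TN = sum(vapply(cs, `[[`, 0, "TN")),
                 FN = sum(vapply(cs, `[[`, 0, "FN"))),
            class = "confusion")
}

#' Scalar classification metrics from a confusion
#'
#' Sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, accuracy
#' `Ac = (TP+TN)/total`, Matthews correlation coefficient, and the weighted
#' score `Sw = Sn + Sp - 1` (equal to twice the balanced accuracy minus
#' one). A metric whose denominator is zero is reported as `NA` and named
#' in `undefined` rather than silently set to 0.
#'
#' @param c A `confusion`.
#' @return List with `Sn`, `Sp`, `Ac`, `MCC`, `Sw`, and a character vector
#'   `undefined` naming metrics with zero denominators.
#' @export
scalar_metrics <- function(c) {
  undef <- character(0)
  div <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(NA_real_) }
    num / den
  }
  Sn <- div(c$TP, c$TP + c$FN, "Sn")
  Sp <- div(c$TN, c$TN + c$FP, "Sp")
  Ac <- div(c$TP + c$TN, c$TP + c$FP + c$TN + c$FN, "Ac")
  mden <- sqrt(c$TP + c$FP) * sqrt(c$TP + c$FN) *
    sqrt(c$TN + c$FP) * sqrt(c$TN + c$FN)
  MCC <- if (mden == 0) { undef <- c(undef, "MCC"); NA_real_ } else
    (c$TP * c$TN - c$FP * c$FN) / mden
  Sw <- if (is.na(Sn) || is.na(Sp)) { undef <- c(undef, "Sw"); NA_real_ } else
    Sn + Sp - 1
  list(Sn = Sn, Sp = Sp, Ac = Ac, MCC = MCC, Sw = Sw,
       undefined = unique(undef))
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation; tied scores contribute 1/2.
#'
#' @param scores Per-residue real scores (higher = more boundary-like).
#' @param truth Two-state labels (1 = boundary = positive).
#' @return AUC in `[0, 1]`, or `NA` when truth has a single class.
#' @export
roc_auc <- function(scores, truth) {
  if (length(scores) != length(truth))
    stop("scores and truth lengths differ")
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap standard error of a metric over targets
#'
#' Draws `reps` bootstrap resamples of `ceiling(frac * n)` targets (with
#' replacement) and reports the sample standard deviation of the metric
#' recomputed on each resample. Resamples on which the metric is undefined
#' are redrawn (up to `reps` extra draws).
#'
#' @param targets List of per-target objects (whatever `metric` consumes).
#' @param metric Function mapping a list of targets to a scalar.
#' @param frac Fraction of targets per resample, default 0.8.
#' @param reps Number of resamples, default 1000.
#' @param seed Integer seed; fixing it makes the estimate reproducible.
#' @return Standard error (sample standard deviation across resamples).
#' @export
bootstrap_se <- function(targets, metric, frac = 0.8, reps = 1000L,
                         seed = 1L) {
  n <- length(targets)
  if (n < 2L) stop("bootstrap requires at least 2 targets")
  k <- ceiling(frac * n)
  vals <- numeric(reps)
  redraws <- 0L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (i in seq_len(reps)) {
    repeat {
      v <- metric(targets[sample.int(n, k, replace = TRUE)])
      if (!is.na(v)) break
      redraws <- redraws + 1L
      if (redraws > reps) stop("metric undefined on too many resamples")
    }
    vals[i] <- v
  }
  stats::sd(vals)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Full metric report for a set of per-target predictions
#'
#' Pools residue-level confusions across targets for `Sn`, `Sp`, `Ac`,
#' `MCC`, `Sw`, computes `AUC` from the pooled scores, and (optionally)
#' attaches bootstrap standard errors for each metric.
#'
#' @param targets List of per-target lists, each with elements `calls2`,
#'   `truth2`, and `scores`.
#' @param se Logical: compute bootstrap standard errors?
#' @param reps,frac,seed Passed to [bootstrap_se()].
#' @return List of metrics (and `SE`, a named numeric vector, when
#'   `se = TRUE`).
#' @export
metric_report <- function(targets, se = FALSE, reps = 1000L, frac = 0.8,
                          seed = 1L) {
  pooled <- function(tg) {
    cs <- lapply(tg, function(t) confusion_counts(t$calls2, t$truth2))
    m <- scalar_metrics(add_confusions(cs))
    m$AUC <- roc_auc(unlist(lapply(tg, `[[`, "scores")),
                     unlist(lapply(tg, `[[`, "truth2")))
    m
  }
  rep <- pooled(targets)
  if (se) {
    rep$SE <- vapply(c("Sn", "Sp", "Ac", "MCC", "Sw", "AUC"), function(nm)
      bootstrap_se(targets, function(tg) pooled(tg)[[nm]],
                   frac = frac, reps = reps, seed = seed),
      0)
  }
  rep
}

#' Write a metric report as JSON and aligned text
#'
#' @param report A [metric_report()] result.
#' @param json_path,txt_path Output paths (either may be `NULL`).
#' @export
write_metric_report <- function(report, json_path = NULL, txt_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(txt_path)) {
    nms <- c("Sn", "Sp", "Ac", "MCC", "Sw", "AUC")
    lines <- vapply(nms, function(nm) {
      v <- report[[nm]]
      se <- if (!is.null(report$SE)) sprintf("  SE %.4f", report$SE[[nm]]) else ""
      sprintf("%-4s %s%s", nm,
              if (is.null(v) || is.na(v)) "undefined" else sprintf("%.4f", v),
              se)
    }, "")
    writeLines(lines, txt_path)
  }
  invisible(report)
}
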