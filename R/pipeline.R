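#' Featurize a query chain
#'
#' Runs the feature stage of the pipeline for one query: local-alignment
#' search against the reference database, DHB profile construction, and
#' windowed template expansion together with the shape string.
#'
#' @param sequence Query amino-acid string.
#' @param shape A [shape_string()] (use [blank_shape()] when no predicted
#'   shape string is available).
#' @param db A `reference_db`.
#' @param sparams A [search_params()].
#' @param tcfg A [template_config()].
#' @return List with `features` (a `feature_sequence`), `profile`, and
#'   `hits`.
#' @export
featurize_query <- function(sequence, shape, db,
                            sparams = search_params(),
                            tcfg = template_config()) {
  hits <- local_align_search(sequence, db, sparams)
  profile <- compute_dhb_profile(nchar(sequence), hits, db)
  list(features = encode_features(profile, shape, tcfg),
       profile = profile, hits = hits)
}

#' Train the full boundary-prediction model
#'
#' Featurizes every training chain against the reference database and fits
#' the chain CRF on the three-state labels. The returned object bundles
#' the CRF with the search and template configurations so prediction uses
#' the same feature pipeline.
#'
#' @param chains List of training chains, each a list with `sequence`,
#'   `shape`, and `labels3`.
#' @param db A `reference_db`.
#' @param sparams,tcfg Search and template configurations.
#' @param traincfg A [train_config()].
#' @param progress Print a note every 25 chains while featurizing.
#' @return An object of class `boundary_model`.
#' @export
train_boundary_model <- function(chains, db, sparams = search_params(),
                                 tcfg = template_config(),
                                 traincfg = train_config(),
                                 progress = FALSE) {
  x_list <- vector("list", length(chains))
  for (i in seq_along(chains)) {
    x_list[[i]] <- featurize_query(chains[[i]]$sequence, chains[[i]]$shape,
                                   db, sparams, tcfg)$features
    if (progress && i %% 25L == 0L)
      message("featurized ", i, "/", length(chains), " chains")
  }
  y_list <- lapply(chains, function(ch) as.integer(ch$labels3))
  crf <- train_crf(x_list, y_list, traincfg)
  structure(list(crf = crf, search = sparams, template = tcfg),
            class = "boundary_model")
}

#' @export
print.boundary_model <- function(x, ...) {
  cat("boundary_model: CRF over", length(x$crf$features),
      "feature ids; e_max", x$search$e_max, "top_s", x$search$top_s, "\n")
  invisible(x)
}

#' Predict boundaries for a set of query chains
#'
#' For each query: search, profile, feature encoding, posterior marginals,
#' argmax-region segmentation and threshold decoding.
#'
#' @param model A [train_boundary_model()] result.
#' @param queries List of query chains, each with `sequence` and `shape`
#'   (and optionally `id`).
#' @param db The `reference_db` to align against.
#' @param dcfg A [decode_config()].
#' @return List (named by query id when present) of per-query results:
#'   `marginals`, `regions`, `prediction` (a `boundary_prediction`).
#' @export
predict_boundaries <- function(model, queries, db, dcfg = decode_config()) {
  out <- lapply(queries, function(q) {
    feat <- featurize_query(q$sequence, q$shape, db, model$search,
                            model$template)
    marg <- posterior_marginals(model$crf, feat$features)
    regions <- argmax_regions(marg)
    list(marginals = marg, regions = regions,
         prediction = decide_two_state(marg, regions, dcfg))
  })
  ids <- vapply(queries, function(q) q$id %||% NA_character_, "")
  if (!anyNA(ids)) names(out) <- ids
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate predictions against truth labels
#'
#' @param predictions A [predict_boundaries()] result.
#' @param truths List of two-state truth label vectors, parallel to
#'   `predictions`.
#' @param se,reps,frac,seed Passed to [metric_report()].
#' @return A [metric_report()].
#' @export
evaluate_predictions <- function(predictions, truths, se = FALSE,
                                 reps = 1000L, frac = 0.8, seed = 1L) {
  targets <- Map(function(p, t)
    list(calls2 = p$prediction$calls2, truth2 = as.integer(t),
         scores = p$prediction$scores),
    predictions, truths)
  metric_report(targets, se = se, reps = reps, frac = frac, seed = seed)
}

#' Sweep a decision threshold and trace the metric curve
#'
#' Re-decodes fixed marginals over a grid of thresholds and reports pooled
#' Sn, Sp, Sw and the number of residues called boundary at each value --
#' the curve used to pick the operating thresholds.
#'
#' @param predictions A [predict_boundaries()] result (its `marginals` and
#'   `regions` are reused; decoding is recomputed per threshold).
#' @param truths List of two-state truth label vectors.
#' @param thresholds Numeric grid in `[0, 1]`.
#' @param which `"hinge"` sweeps `t_hinge` (mode `hinge_only`); `"domain"`
#'   sweeps `t_domain` (mode `domain_only`).
#' @return Data frame with columns `threshold`, `Sn`, `Sp`, `Sw`,
#'   `n_boundary_calls`.
#' @export
sweep_threshold <- function(predictions, truths,
                            thresholds = seq(0, 1, by = 0.05),
                            which = c("hinge", "domain")) {
  which <- match.arg(which)
  rows <- lapply(thresholds, function(t) {
    cfg <- if (which == "hinge")
      decode_config(t_hinge = t, mode = "hinge_only")
    else
      decode_config(t_domain = t, mode = "domain_only")
    calls <- Map(function(p, tr) {
      pr <- decide_two_state(p$marginals, p$regions, cfg)
      list(calls2 = pr$calls2, truth2 = as.integer(tr))
    }, predictions, truths)
    conf <- add_confusions(lapply(calls, function(x)
      confusion_counts(x$calls2, x$truth2)))
    m <- scalar_metrics(conf)
    data.frame(threshold = t, Sn = m$Sn, Sp = m$Sp, Sw = m$Sw,
               n_boundary_calls = conf$TP + conf$FP)
  })
  do.call(rbind, rows)
}

#' Assign chains to cross-validation folds
#'
#' Random equal split with seeded shuffling.
#'
#' @param n Number of chains.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold index (1..k) per chain.
#' @export
kfold_assign <- function(n, k, seed = 1L) {
  if (k > n) stop("fold count exceeds chain count")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}
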