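# Shared pipeline fixtures, built once per test run and cached. The
# high-signal fixture mirrors the study conditions: 3 families, 300
# reference chains, 100 training + 50 test queries, mutation rate 0.05,
# shape noise 0.1, hinge half-width R = 10. The high-noise twin uses
# mutation 0.45 and fully randomized shape strings.

.fixture_cache <- new.env(parent = emptyenv())

fixture_pipeline <- function(noise = c("low", "high")) {
  noise <- match.arg(noise)
  key <- paste0("pipeline_", noise)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- if (noise == "low")
    synth_config(seed = 42L)
  else
    synth_config(seed = 42L, mutation_rate = 0.45, shape_noise = 1.0)
  ds <- generate_dataset(cfg)
  db <- build_reference_db(ds$reference)
  train <- ds$queries[1:100]
  test <- ds$queries[101:150]
  model <- train_boundary_model(train, db)
  preds <- predict_boundaries(model, test, db)
  truths <- lapply(test, `[[`, "labels2")
  out <- list(cfg = cfg, dataset = ds, db = db, train = train, test = test,
              model = model, preds = preds, truths = truths,
              report = evaluate_predictions(preds, truths))
  .fixture_cache[[key]] <- out
  out
}

# A small, fast dataset for plumbing tests (round trips, CLI-level ops).
fixture_small <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  cfg <- synth_config(seed = 7L, n_families = 2L, n_ref = 40L,
                      n_query = 12L, domain_len_range = c(60L, 90L))
  ds <- generate_dataset(cfg)
  out <- list(cfg = cfg, dataset = ds, db = build_reference_db(ds$reference))
  .fixture_cache$small <- out
  out
}
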