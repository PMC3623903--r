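test_that("marginals, partition function and Viterbi agree with exhaustive enumeration", {
  set.seed(41)
  for (i in 1:25) {
    inst <- random_crf_instance(L = sample(2:8, 1),
                                n_feature_types = sample(3:6, 1))
    E <- hingecrf:::crf_emissions(inst$model, inst$x)
    ref <- enum_chain(E, inst$model$trans)

    # marginal columns are presented in (domain, hinge, boundary) order,
    # i.e. label codes (0, 2, 1)
    marg <- posterior_marginals(inst$model, inst$x)
    expect_equal(unname(marg), ref$marginals[, c(1, 3, 2)], tolerance = 1e-9)
    expect_true(all(abs(rowSums(marg) - 1) < 1e-9))

    fb <- hingecrf:::crf_forward_backward(E, inst$model$trans, nrow(E))
    expect_equal(fb$logZ, ref$logZ, tolerance = 1e-9)
    # forward and backward recursions give the same partition function
    expect_equal(hingecrf:::crf_logz_backward(E, inst$model$trans, nrow(E)),
                 ref$logZ, tolerance = 1e-9)

    expect_identical(as.integer(viterbi_path(inst$model, inst$x)),
                     as.integer(ref$viterbi))
  }
})

test_that("analytic gradient matches central finite differences", {
  set.seed(42)
  for (i in 1:20) {
    L <- sample(3:5, 1)
    pool <- paste0("f", 1:4)
    x <- matrix(sample(pool, L * 2, replace = TRUE), nrow = L)
    y <- sample(0:2, L, replace = TRUE)
    prob <- hingecrf:::crf_build_problem(list(x), list(y), l2_sigma = 1.0)
    w <- rnorm(prob$n_par, sd = 0.5)
    g <- prob$gr(w)
    h <- 1e-5
    for (j in sample(prob$n_par, min(10, prob$n_par))) {
      wp <- w; wp[j] <- wp[j] + h
      wm <- w; wm[j] <- wm[j] - h
      fd <- (prob$fn(wp) - prob$fn(wm)) / (2 * h)
      expect_equal(g[j], fd, tolerance = 1e-5)
    }
  }
})

test_that("training fits a linearly separable toy problem exactly", {
  set.seed(43)
  mk <- function() {
    y <- sample(0:2, 12, replace = TRUE)
    x <- matrix(paste0("x:0:", c("A", "B", "C")[y + 1]), ncol = 1)
    list(x = x, y = y)
  }
  data <- replicate(6, mk(), simplify = FALSE)
  model <- train_crf(lapply(data, `[[`, "x"), lapply(data, `[[`, "y"),
                     train_config(l2_sigma = 10, max_iter = 200))
  for (d in data)
    expect_identical(as.integer(viterbi_path(model, d$x)), d$y)
})

test_that("an untrained model is uniform and decodes to the lowest label", {
  x <- matrix(paste0("x:0:", LETTERS[1:5]), ncol = 1)
  y <- c(0L, 1L, 2L, 0L, 1L)
  model <- train_crf(list(x), list(y), train_config(max_iter = 0))
  expect_true(all(model$W == 0) && all(model$trans == 0))
  marg <- posterior_marginals(model, x)
  expect_equal(unname(marg), matrix(1 / 3, 5, 3), tolerance = 1e-12)
  expect_identical(as.integer(viterbi_path(model, x)), rep(0L, 5))
})

test_that("length-1 marginals reduce to a softmax over summed label weights", {
  set.seed(44)
  x <- matrix(c("a", "b"), ncol = 2)
  model <- train_crf(list(x), list(0L), train_config(max_iter = 0))
  model$W[] <- rnorm(length(model$W))
  scores <- colSums(model$W[match(c("a", "b"), model$features), ])
  softmax <- exp(scores) / sum(exp(scores))
  expect_equal(as.vector(posterior_marginals(model, x)),
               unname(softmax[c(1, 3, 2)]), tolerance = 1e-12)
})

test_that("the penalized objective improves monotonically to the optimum", {
  fx <- fixture_small()
  ds <- fx$dataset
  x <- lapply(ds$queries[1:6], function(q)
    featurize_query(q$sequence, q$shape, fx$db)$features)
  y <- lapply(ds$queries[1:6], function(q) as.integer(q$labels3))
  model <- train_crf(x, y, train_config(max_iter = 60))
  tr <- model$objective_trace
  expect_gt(length(tr), 2)
  # the first evaluation is the zero-weight objective; the best value is
  # reached at the end of the trace (L-BFGS line searches may overshoot in
  # between, but accepted iterates never regress)
  expect_lt(min(tr), tr[1])
  expect_equal(min(tr), tr[length(tr)], tolerance = 1e-6)
  # tolerant decode: training-set Viterbi mostly reproduces the labels
  acc <- mean(unlist(Map(function(xi, yi)
    viterbi_path(model, xi) == yi, x, y)))
  expect_gt(acc, 0.9)
})

test_that("mismatched feature and label lengths are rejected", {
  x <- matrix("f", nrow = 3, ncol = 1)
  expect_error(train_crf(list(x), list(c(0L, 1L))), "lengths differ")
  expect_error(train_crf(list(x), list(c(0L, 1L, 3L))), "\\{0,1,2\\}")
})

test_that("models round-trip through JSON without loss", {
  set.seed(45)
  inst <- random_crf_instance()
  path <- withr::local_tempfile(fileext = ".json")
  write_crf_model(inst$model, path)
  back <- read_crf_model(path)
  expect_identical(back$features, inst$model$features)
  expect_equal(back$W, inst$model$W, tolerance = 0)
  expect_equal(back$trans, inst$model$trans, tolerance = 0)
  expect_equal(posterior_marginals(back, inst$x),
               posterior_marginals(inst$model, inst$x), tolerance = 0)
})
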