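# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration over all label paths for the CRF,
# a hand-written Gotoh dynamic program for local alignment, and the
# all-pairs definition of AUC.

# Exhaustive enumeration over all 3^L label paths given log emission
# scores E (L x 3) and transition log-potentials Tw (3 x 3).
enum_chain <- function(E, Tw) {
  L <- nrow(E)
  paths <- as.matrix(expand.grid(rep(list(1:3), L)))
  scores <- apply(paths, 1L, function(y) {
    s <- sum(E[cbind(seq_len(L), y)])
    if (L > 1L) s <- s + sum(Tw[cbind(y[-L], y[-1L])])
    s
  })
  m <- max(scores)
  logZ <- m + log(sum(exp(scores - m)))
  post <- exp(scores - logZ)
  marg <- matrix(0, L, 3L)
  for (i in seq_len(L))
    for (k in 1:3)
      marg[i, k] <- sum(post[paths[, i] == k])
  list(logZ = logZ, marginals = marg,
       viterbi = paths[which.max(scores), ] - 1L)
}

# Random tiny CRF instance: feature matrix over a small id pool plus a
# model with random weights (built through train_crf at zero iterations so
# the dictionary comes from the instance itself).
random_crf_instance <- function(L = 6L, n_feature_types = 6L, n_cols = 2L) {
  pool <- paste0("f", seq_len(n_feature_types))
  x <- matrix(sample(pool, L * n_cols, replace = TRUE), nrow = L)
  class(x) <- "feature_sequence"
  y <- sample(0:2, L, replace = TRUE)
  model <- train_crf(list(x), list(y), train_config(max_iter = 0L))
  model$W[] <- rnorm(length(model$W), sd = 0.8)
  model$trans[] <- rnorm(9L, sd = 0.8)
  list(x = x, y = y, model = model)
}

# Hand-written Smith-Waterman with affine gaps (Gotoh), scores only.
# A gap of length k costs open + k * extend, matching the package's
# alignment settings.
sw_score_oracle <- function(a, b, mat, open = 11, extend = 1) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (vertical)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (horizontal)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      X[i, j] <- max(M[i - 1L, j] - open - extend, X[i - 1L, j] - extend)
      Y[i, j] <- max(M[i, j - 1L] - open - extend, Y[i, j - 1L] - extend)
      M[i, j] <- max(0,
                     max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                         Y[i - 1L, j - 1L]) + mat[a[i - 1L], b[j - 1L]])
      best <- max(best, M[i, j])
    }
  }
  best
}

random_aa_string <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), n, replace = TRUE), collapse = "")
}

# All-pairs (Mann-Whitney) AUC: ties count 1/2.
auc_oracle <- function(scores, truth) {
  pos <- scores[truth == 1L]; neg <- scores[truth == 0L]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Quick literal constructor for label vectors in tests.
lab <- function(s, arity = 3L) labels_from_string(s, arity)
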