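#' Training configuration for the chain CRF
#'
#' @param l2_sigma Standard deviation of the Gaussian prior on the weights
#'   (the penalty is `||w||^2 / (2 sigma^2)`). Default 1.
#' @param max_iter Maximum L-BFGS iterations, default 200.
#' @param grad_tol Projected-gradient tolerance, default 1e-5.
#' @param seed Integer seed, reserved for data shuffling by callers; the
#'   objective is concave and training starts from zero weights, so the fit
#'   itself is deterministic.
#' @return An object of class `train_config`.
#' @export
train_config <- function(l2_sigma = 1.0, max_iter = 200L, grad_tol = 1e-5,
                         seed = 1L) {
  if (l2_sigma <= 0) stop("l2_sigma must be positive")
  if (grad_tol <= 0) stop("grad_tol must be positive")
  structure(list(l2_sigma = l2_sigma, max_iter = as.integer(max_iter),
                 grad_tol = grad_tol, seed = as.integer(seed)),
            class = "train_config")
}

CRF_STATES <- c("P_domain", "P_hinge", "P_boundary")
# weight-matrix columns follow the label codes 0, 1, 2
CRF_LABELS <- c("domain", "boundary", "hinge")

# Assemble the penalized negative log-likelihood and its gradient for a
# labeled dataset. Weights are packed as c(emission F x 3, transition 3 x 3).
# Forward-backward results are cached per weight vector because optim()
# evaluates fn and gr at the same point.
crf_build_problem <- function(x_list, y_list, l2_sigma,
                              features = NULL) {
  stopifnot(length(x_list) == length(y_list), length(x_list) > 0L)
  for (i in seq_along(x_list)) {
    if (nrow(x_list[[i]]) != length(y_list[[i]]))
      stop("feature sequence and label lengths differ in instance ", i)
    if (any(y_list[[i]] < 0L | y_list[[i]] > 2L))
      stop("labels must be over {0,1,2}")
  }
  if (is.null(features)) features <- sort(unique(unlist(x_list)))
  lens <- vapply(x_list, nrow, 0L)
  N <- sum(lens)
  nf <- ncol(x_list[[1L]])
  ids <- matrix(match(unlist(lapply(x_list, t)), features),
                ncol = nf, byrow = TRUE)
  keep <- !is.na(ids)
  M <- Matrix::sparseMatrix(i = row(ids)[keep], j = ids[keep], x = 1,
                            dims = c(N, length(features)))
  y <- unlist(y_list, use.names = FALSE)
  Y <- Matrix::sparseMatrix(i = seq_len(N), j = y + 1L, x = 1,
                            dims = c(N, 3L))
  emis_emp <- as.matrix(Matrix::crossprod(M, Y))
  trans_emp <- matrix(0, 3L, 3L)
  off <- 0L
  for (l in lens) {
    if (l > 1L) {
      a <- y[(off + 1L):(off + l - 1L)] + 1L
      b <- y[(off + 2L):(off + l)] + 1L
      for (i in seq_along(a)) trans_emp[a[i], b[i]] <- trans_emp[a[i], b[i]] + 1
    }
    off <- off + l
  }
  Fn <- length(features)
  yidx <- cbind(seq_len(N), y + 1L)
  cache <- new.env(parent = emptyenv())
  fb_at <- function(w) {
    if (!is.null(cache$w) && identical(cache$w, w)) return(cache$fb)
    W <- matrix(w[seq_len(3L * Fn)], Fn, 3L)
    Tm <- matrix(w[3L * Fn + 1:9], 3L, 3L)
    E <- as.matrix(M %*% W)
    fb <- crf_forward_backward(E, Tm, lens)
    fb$E <- E; fb$W <- W; fb$Tm <- Tm
    cache$w <- w; cache$fb <- fb
    fb
  }
  fn <- function(w) {
    fb <- fb_at(w)
    ll <- sum(fb$E[yidx]) + sum(trans_emp * fb$Tm) - sum(fb$logZ)
    -ll + sum(w^2) / (2 * l2_sigma^2)
  }
  gr <- function(w) {
    fb <- fb_at(w)
    gW <- -(emis_emp - as.matrix(Matrix::crossprod(M, fb$marginals))) +
      fb$W / l2_sigma^2
    gT <- -(trans_emp - fb$trans_exp) + fb$Tm / l2_sigma^2
    c(as.vector(gW), as.vector(gT))
  }
  list(fn = fn, gr = gr, features = features, n_par = 3L * Fn + 9L,
       n_positions = N)
}

#' Train the linear-chain CRF
#'
#' Maximizes the L2-penalized conditional log-likelihood
#' `sum log P(y|x) - ||w||^2 / (2 sigma^2)` by L-BFGS from a zero start.
#' The objective is concave, so the optimum does not depend on any random
#' initialization. Emission weights are tied per feature id across
#' positions (one weight per feature id and label); transitions are
#' label-pair parameters independent of the observations.
#'
#' @param x_list List of `feature_sequence` matrices from
#'   [encode_features()].
#' @param y_list List of three-state label vectors (same lengths).
#' @param cfg A [train_config()].
#' @return An object of class `hinge_crf` with elements `features`
#'   (feature-id dictionary), `W` (emission weight matrix, features x 3),
#'   `trans` (3 x 3 transition weights), `cfg`, and optimizer diagnostics.
#' @export
train_crf <- function(x_list, y_list, cfg = train_config()) {
  prob <- crf_build_problem(x_list, y_list, cfg$l2_sigma)
  trace <- numeric(0)
  fn_traced <- function(w) {
    v <- prob$fn(w)
    trace[length(trace) + 1L] <<- v
    v
  }
  w0 <- numeric(prob$n_par)
  if (cfg$max_iter > 0L) {
    opt <- stats::optim(w0, fn_traced, prob$gr, method = "L-BFGS-B",
                        control = list(maxit = cfg$max_iter,
                                       pgtol = cfg$grad_tol))
    w <- opt$par
    conv <- opt$convergence
  } else {
    w <- w0
    conv <- NA_integer_
  }
  Fn <- length(prob$features)
  structure(list(features = prob$features,
                 W = matrix(w[seq_len(3L * Fn)], Fn, 3L,
                            dimnames = list(NULL, CRF_LABELS)),
                 trans = matrix(w[3L * Fn + 1:9], 3L, 3L),
                 cfg = cfg,
                 objective_trace = trace,
                 convergence = conv,
                 n_train = length(x_list)),
            class = "hinge_crf")
}

#' @export
print.hinge_crf <- function(x, ...) {
  cat("hinge_crf:", length(x$features), "feature ids,",
      x$n_train, "training chains\n")
  invisible(x)
}

# Emission log-score matrix for one feature sequence; feature ids unseen
# during training contribute nothing.
crf_emissions <- function(model, x) {
  ids <- match(x, model$features)
  keep <- !is.na(ids)
  M <- Matrix::sparseMatrix(i = row(x)[keep], j = ids[keep], x = 1,
                            dims = c(nrow(x), length(model$features)))
  as.matrix(M %*% model$W)
}

#' Posterior per-position state marginals
#'
#' Forward-backward in log space; row `i` of the result is
#' `P(y_i = s | x)` for `s` in (domain, hinge, boundary).
#'
#' @param model A trained [train_crf()] model.
#' @param x A `feature_sequence`.
#' @return L x 3 matrix with columns `P_domain`, `P_hinge`, `P_boundary`;
#'   rows sum to 1.
#' @export
posterior_marginals <- function(model, x) {
  E <- crf_emissions(model, x)
  fb <- crf_forward_backward(E, model$trans, nrow(E))
  # internal state columns follow the label codes (0 domain, 1 boundary,
  # 2 hinge); present them in (domain, hinge, boundary) order
  m <- fb$marginals[, c(1L, 3L, 2L), drop = FALSE]
  colnames(m) <- CRF_STATES
  m
}

#' Most probable label path (Viterbi decoding)
#'
#' Ties are broken toward the lower label code, so an untrained (all-zero)
#' model yields the all-domain path.
#'
#' @inheritParams posterior_marginals
#' @return Integer vector over `{0,1,2}` with attribute `arity = 3`.
#' @export
viterbi_path <- function(model, x) {
  E <- crf_emissions(model, x)
  structure(as.integer(crf_viterbi(E, model$trans, nrow(E))), arity = 3L)
}

#' Save / load a CRF model as JSON
#'
#' The round trip is loss-free: weights are written at full precision.
#'
#' @param model A `hinge_crf`.
#' @param path File path.
#' @export
write_crf_model <- function(model, path) {
  # weights are stored as %.17g strings: decimal round trip at 17
  # significant digits reproduces every double exactly
  obj <- list(format = "hinge_crf", version = 1L,
              features = model$features,
              W = sprintf("%.17g", as.vector(model$W)),
              trans = sprintf("%.17g", as.vector(model$trans)),
              l2_sigma = model$cfg$l2_sigma,
              max_iter = model$cfg$max_iter,
              grad_tol = model$cfg$grad_tol,
              n_train = model$n_train)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_crf_model
#' @export
read_crf_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hinge_crf"))
    stop("not a hinge_crf model file: ", path)
  Fn <- length(obj$features)
  structure(list(features = obj$features,
                 W = matrix(as.numeric(obj$W), Fn, 3L,
                            dimnames = list(NULL, CRF_LABELS)),
                 trans = matrix(as.numeric(obj$trans), 3L, 3L),
                 cfg = train_config(obj$l2_sigma, obj$max_iter, obj$grad_tol),
                 objective_trace = numeric(0),
                 convergence = NA_integer_,
                 n_train = obj$n_train),
            class = "hinge_crf")
}
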