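# Digital-twin predictors: an ensemble of linear-nonlinear Poisson encoders
# (ELU + 1 output nonlinearity) trained by minimizing the Poisson loss, plus
# the reliability metrics CC_abs / CC_max / CC_norm used to evaluate them.

elu <- function(z) ifelse(z > 0, z, exp(z) - 1)
elu_grad <- function(z) ifelse(z > 0, 1, exp(z))

#' Poisson loss
#'
#' `mean(pred - obs * log(pred))`, the negative Poisson log-likelihood up to
#' terms independent of the prediction.
#'
#' @param pred positive predicted rates
#' @param obs nonnegative observed responses
#' @return scalar loss
#' @export
poisson_loss <- function(pred, obs) {
  if (any(pred <= 0)) stop("predictions must be positive inside the log")
  mean(pred - obs * log(pred))
}

#' Fit a digital twin to image-response data
#'
#' Trains `n_members` linear-nonlinear Poisson encoders (response =
#' ELU(w.x + b) + 1, guaranteeing positivity) by minimizing the ridge-
#' penalized Poisson loss with L-BFGS, each member from a different random
#' initialization; the ensemble prediction is the member mean.
#'
#' @param images list of image matrices or (npx x n) matrix
#' @param responses nonnegative response vector (or 1-column matrix), one per image
#' @param shape image grid c(rows, cols)
#' @param n_members ensemble size (default 4)
#' @param seed RNG seed (mandatory)
#' @param config list: maxit (500 L-BFGS iterations), smooth (1e-3 Laplacian
#'   smoothness penalty on the weight map, the usual receptive-field prior),
#'   l2 (1e-5 ridge)
#' @return object of class `ensemble_twin`
#' @export
fit_digital_twin <- function(images, responses, shape = default_shape(),
                             n_members = 4, seed,
                             config = list()) {
  cfg <- utils::modifyList(list(maxit = 500, l2 = 1e-5, smooth = 1e-3),
                           config)
  X <- as_image_batch(images)
  r <- as.numeric(responses)
  stopifnot(length(r) == ncol(X), all(r >= 0), n_members >= 1)
  npx <- nrow(X)
  m <- length(r)
  lap <- function(wm) {       # discrete Laplacian, replicated edges
    nr <- nrow(wm); nc <- ncol(wm)
    4 * wm - rbind(wm[1, ], wm[-nr, ]) - rbind(wm[-1, ], wm[nr, ]) -
      cbind(wm[, 1], wm[, -nc]) - cbind(wm[, -1], wm[, nc])
  }
  obj <- function(par) {
    w <- par[seq_len(npx)]
    z <- as.vector(crossprod(X, w)) + par[npx + 1]
    rhat <- elu(z) + 1
    L <- lap(matrix(w, shape[1], shape[2]))
    mean(rhat - r * log(rhat)) + cfg$smooth * sum(L^2) / 2 +
      cfg$l2 * sum(w^2) / 2
  }
  grd <- function(par) {
    w <- par[seq_len(npx)]
    z <- as.vector(crossprod(X, w)) + par[npx + 1]
    rhat <- elu(z) + 1
    dz <- (1 - r / rhat) * elu_grad(z) / m
    L <- lap(matrix(w, shape[1], shape[2]))
    c(as.vector(X %*% dz) + cfg$smooth * as.vector(lap(L)) + cfg$l2 * w,
      sum(dz))
  }
  withr_seed(seed)
  members <- lapply(seq_len(n_members), function(k) {
    par0 <- c(stats::rnorm(npx, sd = 1e-2 / sqrt(npx)), log(mean(r) + 1e-3))
    fit <- stats::optim(par0, obj, grd, method = "L-BFGS-B",
                        control = list(maxit = cfg$maxit))
    list(w = fit$par[seq_len(npx)], b = fit$par[npx + 1])
  })
  structure(list(members = members, shape = shape, config = cfg),
            class = "ensemble_twin")
}

member_predict <- function(member, X) elu(as.vector(crossprod(X, member$w)) + member$b) + 1

#' Predict responses from an ensemble twin
#'
#' @param object an `ensemble_twin`
#' @param images list of matrices or (npx x n) matrix
#' @param ... unused
#' @return numeric vector, the mean of member predictions
#' @export
predict.ensemble_twin <- function(object, images, ...) {
  X <- as_image_batch(images)
  preds <- vapply(object$members, function(m) member_predict(m, X),
                  numeric(ncol(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = ncol(X))
  rowMeans(preds)
}

#' @export
print.ensemble_twin <- function(x, ...) {
  cat("<ensemble_twin>", length(x$members), "member LN Poisson encoder(s) on",
      x$shape[1], "x", x$shape[2], "grid\n")
  invisible(x)
}

#' Wrap an ensemble twin as a differentiable model neuron
#'
#' @param twin an `ensemble_twin`
#' @param label free text
#' @return a `model_neuron` whose response/gradient are the ensemble mean
#' @export
twin_neuron <- function(twin, label = "digital twin") {
  shape <- twin$shape
  W <- vapply(twin$members, `[[`, numeric(length(twin$members[[1]]$w)), "w")
  if (is.null(dim(W))) W <- matrix(W, ncol = length(twin$members))
  bs <- vapply(twin$members, `[[`, numeric(1), "b")
  K <- ncol(W)
  eval_batch <- function(X) {
    Z <- sweep(crossprod(W, X), 1, bs, `+`)   # K x n
    R <- elu(Z) + 1
    r <- colMeans(R)
    G <- W %*% (elu_grad(Z) / K)
    list(r = r, G = G)
  }
  model_neuron(
    respond = function(img) eval_batch(matrix(as.vector(img)))$r,
    grad = function(img) matrix(eval_batch(matrix(as.vector(img)))$G,
                                shape[1], shape[2]),
    shape = shape, label = label, eval_batch = eval_batch)
}

#' Twin evaluation metrics
#'
#' CC_abs is the Pearson correlation between predictions and repeat-averaged
#' responses; CC_max is the reliability ceiling
#' sqrt((N Var(ybar) - mean_t Var(y_t)) / ((N - 1) Var(ybar))) with N repeats
#' (variances across images, unbiased); CC_norm = CC_abs / CC_max.
#'
#' @param twin an `ensemble_twin` (or any object with a predict method)
#' @param test_images held-out images (list or npx x n matrix)
#' @param repeated_responses matrix n_images x N of repeated responses, N >= 2
#' @return object of class `response_stats`: cc_abs, cc_max, cc_norm
#' @export
evaluate_twin <- function(twin, test_images, repeated_responses) {
  Y <- as.matrix(repeated_responses)
  N <- ncol(Y)
  stopifnot(N >= 2)
  pred <- stats::predict(twin, test_images)
  stopifnot(length(pred) == nrow(Y))
  response_stats(pred, Y)
}

#' Reliability statistics from predictions and repeated responses
#'
#' @param pred predicted responses, one per image
#' @param Y matrix n_images x N of repeats
#' @return `response_stats` object
#' @export
response_stats <- function(pred, Y) {
  Y <- as.matrix(Y)
  N <- ncol(Y)
  ybar <- rowMeans(Y)
  cc_abs <- if (stats::sd(pred) == 0 || stats::sd(ybar) == 0) NA_real_ else
    stats::cor(pred, ybar)
  v_bar <- stats::var(ybar)
  mean_var <- mean(apply(Y, 2, stats::var))
  cc_max <- if (v_bar > 0) {
    val <- (N * v_bar - mean_var) / ((N - 1) * v_bar)
    if (val < 0) NA_real_ else sqrt(val)
  } else NA_real_
  cc_norm <- if (!is.na(cc_abs) && !is.na(cc_max) && cc_max > 0)
    cc_abs / cc_max else NA_real_
  structure(list(cc_abs = cc_abs, cc_max = cc_max, cc_norm = cc_norm),
            class = "response_stats")
}

#' @export
print.response_stats <- function(x, ...) {
  cat(sprintf("CC_abs = %.3f  CC_max = %.3f  CC_norm = %.3f\n",
              x$cc_abs, x$cc_max, x$cc_norm))
  invisible(x)
}
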