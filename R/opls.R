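#' Orthogonal projections to latent structures (single response)
#'
#' A self-contained OPLS implementation for one response vector: unit
#' variance (UV) scaling, removal of a chosen number of components of X
#' variation orthogonal to y (orthogonal signal correction), a single
#' predictive PLS component on the filtered matrix, standardized regression
#' coefficients mapped back through the filter, and VIP scores over the
#' predictive component.
#'
#' For each orthogonal component on the current (filtered) matrix `X`:
#' `w = X'y / |X'y|`; `t = Xw`; `p = X't / t't`;
#' `w_o = p - (w'p) w` normalized; `t_o = X w_o`; `p_o = X't_o / t_o't_o`;
#' `X <- X - t_o p_o'`. Each `t_o` is orthogonal to `y` by construction.
#' The predictive component on the filtered matrix then gives `w`, `t`,
#' `p`, and `q = y't / t't`; predictions are `t q`.
#'
#' @name opls-module
NULL

#' Autoscale a predictor matrix and response
#'
#' Mean-centers and unit-variance scales each column (UV scaling). Columns
#' with zero variance — e.g. the reference peak's column of a relative-area
#' matrix — cannot be scaled; they are dropped with a warning, recorded in
#' the returned parameters, and reported downstream with coefficient and VIP
#' equal to 0.
#'
#' @param X Numeric matrix, at least 3 rows, no missing values.
#' @param y Optional numeric response to scale the same way.
#' @param scaling `"uv"` (default), `"center"`, or `"none"`.
#' @return List with `X` (scaled, constant columns removed), `y` (scaled, if
#'   given), and `params`: `means`, `sds`, `kept`, `dropped` (column indices),
#'   `y_mean`, `y_sd`, `scaling`.
#' @export
autoscale <- function(X, y = NULL, scaling = c("uv", "center", "none")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 rows", call. = FALSE)
  if (anyNA(X)) stop("X contains missing values", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  means <- colMeans(X)
  dropped <- integer(0)
  if (scaling == "uv") {
    dropped <- which(sds == 0)
    if (length(dropped) == ncol(X))
      stop("all columns are constant; nothing to scale", call. = FALSE)
    if (length(dropped))
      warning(sprintf("dropping %d constant column(s): %s",
                      length(dropped),
                      paste(colnames(X)[dropped] %||% dropped, collapse = ", ")),
              call. = FALSE)
  }
  kept <- setdiff(seq_len(ncol(X)), dropped)
  Xs <- X[, kept, drop = FALSE]
  Xs <- switch(scaling,
               uv = scale(Xs, center = means[kept], scale = sds[kept]),
               center = scale(Xs, center = means[kept], scale = FALSE),
               none = Xs)
  attr(Xs, "scaled:center") <- NULL
  attr(Xs, "scaled:scale") <- NULL
  params <- list(means = means, sds = sds, kept = kept, dropped = dropped,
                 scaling = scaling)
  if (!is.null(y)) {
    params$y_mean <- if (scaling == "none") 0 else mean(y)
    params$y_sd <- if (scaling == "uv") stats::sd(y) else 1
    if (scaling == "uv" && params$y_sd == 0)
      stop("response has zero variance", call. = FALSE)
    y <- (y - params$y_mean) / params$y_sd
  }
  list(X = Xs, y = y, params = params)
}

#' Fit a single-response OPLS model
#'
#' @param X Batches x peaks numeric matrix (raw or relative areas), or a
#'   `common_peak_matrix`.
#' @param y Numeric response (one efficacy index per batch).
#' @param n_orthogonal Number of orthogonal components to remove; default 1.
#'   `0` reduces the model to one-component PLS1. Must be smaller than the
#'   rank of the scaled matrix.
#' @param scaling Passed to [autoscale()]; default `"uv"`.
#' @return Object of class `opls`: list with predictive `w` (unit norm), `t`,
#'   `p`, `q`; `W_orth`, `T_orth`, `P_orth` (matrices with one column per
#'   removed component, or `NULL`); `coefficients_scaled` (length = ncol(X),
#'   dropped columns 0); `vip` (same length); `r2y`; `fitted` (original y
#'   units); `params` (scaling parameters); `n_orthogonal`; `peaks` (column
#'   labels).
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X %*% c(1, -0.5, 0) + rnorm(20, sd = 0.1)
#' fit_opls1(X, y, n_orthogonal = 1)
#' @export
fit_opls1 <- function(X, y, n_orthogonal = 1, scaling = "uv") {
  X <- as_batch_matrix(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), n_orthogonal >= 0)
  if (nrow(X) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(y) == 0) stop("response has zero variance", call. = FALSE)
  peaks <- colnames(X) %||% as.character(seq_len(ncol(X)))
  sc <- autoscale(X, y, scaling = scaling)
  Xs <- sc$X; ys <- sc$y
  if (n_orthogonal >= qr(Xs)$rank)
    stop("`n_orthogonal` must be smaller than the rank of the scaled matrix",
         call. = FALSE)

  p_kept <- ncol(Xs)
  Xf <- Xs
  filt <- diag(p_kept)             # accumulates (I - w_o p_o') products
  W_o <- T_o <- P_o <- NULL
  for (k in seq_len(n_orthogonal)) {
    w <- drop(crossprod(Xf, ys)); w <- w / sqrt(sum(w^2))
    tt <- drop(Xf %*% w)
    p <- drop(crossprod(Xf, tt)) / sum(tt^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break         # no orthogonal variation left
    wo <- wo / nwo
    to <- drop(Xf %*% wo)
    po <- drop(crossprod(Xf, to)) / sum(to^2)
    Xf <- Xf - tcrossprod(to, po)
    filt <- filt %*% (diag(p_kept) - tcrossprod(wo, po))
    W_o <- cbind(W_o, wo); T_o <- cbind(T_o, to); P_o <- cbind(P_o, po)
  }

  # predictive component on the filtered matrix
  w <- drop(crossprod(Xf, ys)); w <- w / sqrt(sum(w^2))
  tt <- drop(Xf %*% w)
  p <- drop(crossprod(Xf, tt)) / sum(tt^2)
  q <- sum(ys * tt) / sum(tt^2)

  b_kept <- drop(filt %*% w) * q   # coefficients on the scaled original X
  fitted_s <- drop(Xs %*% b_kept)
  r2y <- 1 - sum((ys - fitted_s)^2) / sum(ys^2)

  pr <- sc$params
  coef_full <- vip_full <- stats::setNames(numeric(length(peaks)), peaks)
  coef_full[pr$kept] <- b_kept
  vip_full[pr$kept] <- sqrt(p_kept) * abs(w)
  structure(list(w = w, t = tt, p = p, q = q,
                 W_orth = W_o, T_orth = T_o, P_orth = P_o,
                 coefficients_scaled = coef_full, vip = vip_full,
                 r2y = r2y,
                 fitted = fitted_s * pr$y_sd + pr$y_mean,
                 y = y, params = pr, n_orthogonal = n_orthogonal,
                 peaks = peaks),
            class = "opls")
}

#' @export
print.opls <- function(x, ...) {
  cat(sprintf("<opls: %d peaks (%d modelled), %d orthogonal component(s), R2Y = %.4f>\n",
              length(x$peaks), length(x$params$kept),
              if (is.null(x$T_orth)) 0L else ncol(x$T_orth), x$r2y))
  top <- order(x$vip, decreasing = TRUE)[seq_len(min(3L, length(x$vip)))]
  cat(sprintf("  top VIP: %s\n",
              paste(sprintf("%s = %.2f (b %+.3f)", x$peaks[top], x$vip[top],
                            x$coefficients_scaled[top]), collapse = ", ")))
  invisible(x)
}

#' Variable importance in projection
#'
#' VIP over the predictive component(s):
#' `VIP_j = sqrt(p * sum_a SSY_a (w_aj/|w_a|)^2 / sum_a SSY_a)`, which for
#' the single predictive component reduces to `sqrt(p) * |w_j|` with unit
#' `w`. Orthogonal components are excluded: VIP here measures importance for
#' the response. `sum(VIP^2)` equals the number of modelled (non-constant)
#' variables; dropped columns report 0.
#'
#' @param model A fitted [fit_opls1()] model.
#' @return Named numeric vector of VIP scores, one per input column.
#' @export
vip <- function(model) {
  if (!inherits(model, "opls") || is.null(model$w))
    stop("`vip` needs a fitted opls model", call. = FALSE)
  model$vip
}

#' Cross-validated predictive ability (Q2)
#'
#' K-fold cross-validation with per-fold rescaling: scaling parameters and
#' the OPLS filter are re-estimated on each training split and applied to the
#' held-out samples. `Q2 = 1 - PRESS / SS(y)` with SS about the overall mean.
#' Fold assignment is deterministic (samples interleaved in order), so
#' repeated calls agree.
#'
#' @inheritParams fit_opls1
#' @param folds Number of folds, between 2 and `nrow(X)`; default
#'   `nrow(X)` (leave-one-out).
#' @return `Q2` (scalar). Can be negative when the model predicts worse than
#'   the mean.
#' @export
cross_validate <- function(X, y, n_orthogonal = 1, scaling = "uv",
                           folds = nrow(as_batch_matrix(X))) {
  X <- as_batch_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (folds < 2L || folds > n)
    stop("`folds` must be between 2 and the number of samples", call. = FALSE)
  fold_of <- rep_len(seq_len(folds), n)
  press <- 0
  for (f in seq_len(folds)) {
    test <- which(fold_of == f)
    fit <- fit_opls1(X[-test, , drop = FALSE], y[-test],
                     n_orthogonal = n_orthogonal, scaling = scaling)
    pr <- fit$params
    Xt <- X[test, pr$kept, drop = FALSE]
    Xt <- sweep(Xt, 2L, pr$means[pr$kept], "-")
    if (pr$scaling == "uv") Xt <- sweep(Xt, 2L, pr$sds[pr$kept], "/")
    b <- fit$coefficients_scaled[pr$kept]
    pred <- drop(Xt %*% b) * pr$y_sd + pr$y_mean
    press <- press + sum((y[test] - pred)^2)
  }
  1 - press / sum((y - mean(y))^2)
}
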