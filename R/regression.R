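#' NIPALS PLS1, modified PLS and principal component regression
#'
#' Low-level fitters operating on a treated spectra matrix `X` (samples in
#' rows) and a single response `y`. `X` and `y` are mean-centered
#' internally and not variance-scaled (spectroscopy convention); MPLS
#' applies its own residual standardization. All fitters return nested
#' coefficient paths, so predictions with any number of latent variables up
#' to `n_pcs` come from one fit.
#'
#' `fit_pls()` is PLS1 by NIPALS with deflation of both the X- and
#' y-residuals. `fit_mpls()` is the modified-PLS variant in which, after
#' each latent variable is extracted, the X-residual columns and the
#' y-residual are rescaled by their current standard deviations before the
#' next factor is extracted; this reduces domination by high-variance
#' spectral regions. `fit_pcr()` regresses `y` on the leading principal
#' component scores of centered `X`.
#'
#' @param X numeric matrix of treated spectra (n samples x p wavelengths).
#' @param y numeric response vector of length n.
#' @param n_pcs number of latent variables / principal components.
#' @return a `latent_fit` with fields `method`, `n_pcs` (as fitted),
#'   `x_mean`, `y_mean`, `coef_path` (p x n_pcs cumulative coefficient
#'   matrix on centered data), `coef` (final column), `scores`
#'   (n x n_pcs), `fitted`, `residuals`.
#' @export
fit_pls <- function(X, y, n_pcs) {
  fit_latent(X, y, n_pcs, method = "pls")
}

#' @rdname fit_pls
#' @export
fit_mpls <- function(X, y, n_pcs) {
  fit_latent(X, y, n_pcs, method = "mpls")
}

#' @rdname fit_pls
#' @export
fit_pcr <- function(X, y, n_pcs) {
  fit_latent(X, y, n_pcs, method = "pcr")
}

fit_latent <- function(X, y, n_pcs, method = c("pls", "mpls", "pcr")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n_pcs >= 1)
  if (n <= n_pcs) stop("need more samples (", n, ") than components (", n_pcs, ")")
  if (stats::sd(y) < 1e-12) stop("response has zero variance")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  A <- min(n_pcs, n - 1L, p)
  core <- switch(method,
                 pls = pls_core(Xc, yc, A),
                 mpls = mpls_core(Xc, yc, A),
                 pcr = pcr_core(Xc, yc, A))
  A <- core$n_pcs
  fitted <- as.numeric(Xc %*% core$coef_path[, A]) + y_mean
  structure(list(method = method, n_pcs = A,
                 x_mean = x_mean, y_mean = y_mean,
                 coef_path = core$coef_path,
                 coef = core$coef_path[, A],
                 scores = core$scores,
                 fitted = fitted,
                 residuals = y - fitted),
            class = "latent_fit")
}

pls_core <- function(Xc, yc, A) {
  n <- nrow(Xc); p <- ncol(Xc)
  E <- Xc; f <- yc
  Rmat <- matrix(0, p, A)     # T = Xc %*% Rmat
  Pmat <- matrix(0, p, A)
  scores <- matrix(0, n, A)
  qvec <- numeric(A)
  a <- 0L
  for (k in seq_len(A)) {
    w <- as.numeric(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- as.numeric(E %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    p_ <- as.numeric(crossprod(E, t_)) / tt
    q_ <- sum(f * t_) / tt
    r <- w
    if (k > 1) {
      for (j in seq_len(k - 1L)) r <- r - Rmat[, j] * sum(Pmat[, j] * w)
    }
    a <- k
    Rmat[, k] <- r; Pmat[, k] <- p_; qvec[k] <- q_; scores[, k] <- t_
    E <- E - tcrossprod(t_, p_)
    f <- f - q_ * t_
  }
  if (a == 0L) stop("NIPALS extracted no latent structure (degenerate data)")
  coef_path <- matrix(0, p, a)
  b <- numeric(p)
  for (k in seq_len(a)) {
    b <- b + qvec[k] * Rmat[, k]
    coef_path[, k] <- b
  }
  list(coef_path = coef_path, scores = scores[, seq_len(a), drop = FALSE],
       n_pcs = a)
}

# Modified PLS: residual standardization between factor extractions.
# The per-factor scalings and deflations compose into a linear map, so the
# final model is still a coefficient vector on the original centered grid:
#   t_a = Xc M_a w_a,  M_a = D_1 (I - w_1 p_1')D_2 ... (I - w_{a-1}p_{a-1}')D_a
# and M_a x is applied operator-by-operator in O(a*p).
mpls_core <- function(Xc, yc, A) {
  n <- nrow(Xc); p <- ncol(Xc)
  E <- Xc; f <- yc
  Ws <- vector("list", A); Ps <- vector("list", A); Ds <- vector("list", A)
  scores <- matrix(0, n, A)
  qvec <- numeric(A)
  sy_cum <- numeric(A)
  sy_running <- 1
  a <- 0L
  apply_M <- function(k, x) {
    y_ <- Ds[[k]] * x
    if (k > 1) {
      for (j in (k - 1L):1L) {
        y_ <- y_ - Ws[[j]] * sum(Ps[[j]] * y_)
        y_ <- Ds[[j]] * y_
      }
    }
    y_
  }
  for (k in seq_len(A)) {
    sx <- apply(E, 2, stats::sd)
    zero_sx <- sx < 1e-12
    if (any(zero_sx) && !all(zero_sx)) {
      warning(sum(zero_sx), " X-residual column(s) with zero SD dropped ",
              "from MPLS rescaling")
    }
    sx[zero_sx] <- 1
    sy <- stats::sd(f)
    if (sy < 1e-12) break
    E <- sweep(E, 2, sx, "/")
    f <- f / sy
    sy_running <- sy_running * sy
    Ds[[k]] <- 1 / sx
    w <- as.numeric(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- as.numeric(E %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    p_ <- as.numeric(crossprod(E, t_)) / tt
    q_ <- sum(f * t_) / tt
    a <- k
    Ws[[k]] <- w; Ps[[k]] <- p_
    qvec[k] <- q_; scores[, k] <- t_; sy_cum[k] <- sy_running
    E <- E - tcrossprod(t_, p_)
    f <- f - q_ * t_
  }
  if (a == 0L) stop("MPLS extracted no latent structure (degenerate data)")
  coef_path <- matrix(0, p, a)
  b <- numeric(p)
  for (k in seq_len(a)) {
    b <- b + sy_cum[k] * qvec[k] * apply_M(k, Ws[[k]])
    coef_path[, k] <- b
  }
  list(coef_path = coef_path, scores = scores[, seq_len(a), drop = FALSE],
       n_pcs = a)
}

pcr_core <- function(Xc, yc, A) {
  sv <- svd(Xc, nu = A, nv = A)
  pos <- sv$d[seq_len(A)] > max(sv$d) * 1e-10
  a <- max(which(pos))
  U <- sv$u[, seq_len(a), drop = FALSE]
  V <- sv$v[, seq_len(a), drop = FALSE]
  d <- sv$d[seq_len(a)]
  g <- as.numeric(crossprod(U, yc)) / d   # regression weight per PC
  coef_path <- matrix(0, ncol(Xc), a)
  b <- numeric(ncol(Xc))
  for (k in seq_len(a)) {
    b <- b + V[, k] * g[k]
    coef_path[, k] <- b
  }
  list(coef_path = coef_path,
       scores = sweep(U, 2, d, "*"),
       n_pcs = a)
}

#' Predict from a latent fit
#' @param object a `latent_fit`.
#' @param newdata matrix on the same treated grid.
#' @param n_pcs number of components to use (default: all fitted).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.latent_fit <- function(object, newdata, n_pcs = object$n_pcs, ...) {
  newdata <- as.matrix(newdata)
  k <- min(n_pcs, object$n_pcs)
  as.numeric(sweep(newdata, 2, object$x_mean) %*% object$coef_path[, k]) +
    object$y_mean
}

#' Block cross-validation for latent-variable count selection
#'
#' Contiguous-block group cross-validation (deterministic, no random
#' folds): the sample order is cut into `n_groups` blocks, each block held
#' out in turn, and SECV(k) is the RMSE of the pooled held-out predictions
#' with k components. The chosen component count is the SECV minimizer
#' subject to the cap `n_pcs_max` (default 5).
#'
#' @param X treated spectra matrix.
#' @param y response vector.
#' @param method `"pls"`, `"mpls"` or `"pcr"`.
#' @param n_pcs_max component cap (default 5).
#' @param n_groups number of contiguous blocks (default 4).
#' @return list with `secv` (vector over 1..n_pcs_max), `n_pcs` (chosen).
#' @export
cross_validate <- function(X, y, method = "pls", n_pcs_max = 5, n_groups = 4) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- length(y)
  stopifnot(n_groups >= 2, nrow(X) == n)
  bounds <- round(seq(0, n, length.out = n_groups + 1))
  sizes <- diff(bounds)
  if (any(sizes < 2)) stop("cross-validation group with fewer than 2 samples")
  groups <- rep(seq_len(n_groups), times = sizes)
  preds <- matrix(NA_real_, n, n_pcs_max)
  for (g in seq_len(n_groups)) {
    hold <- which(groups == g)
    fit <- fit_latent(X[-hold, , drop = FALSE], y[-hold],
                      n_pcs = n_pcs_max, method = method)
    for (k in seq_len(n_pcs_max)) {
      preds[hold, k] <- predict(fit, X[hold, , drop = FALSE],
                                n_pcs = min(k, fit$n_pcs))
    }
  }
  secv <- sqrt(colMeans((y - preds)^2))
  list(secv = secv, n_pcs = which.min(secv))
}

#' Iterative calibration outlier elimination
#'
#' Samples with a standardized y-residual exceeding `t_limit` or a
#' Mahalanobis-type leverage in latent-score space (GH, scaled so its
#' expectation is about 1) exceeding `gh_limit` are removed and the model
#' refit, for at most `max_passes` passes. Total removals are capped at
#' `max_remove_frac` of n; hitting the cap stops elimination with a
#' warning, never an error.
#'
#' @param X treated spectra matrix.
#' @param y response vector.
#' @param method regression method.
#' @param n_pcs components for the working fit.
#' @param t_limit standardized-residual limit (default 2.5).
#' @param gh_limit leverage limit (default 3.0).
#' @param max_passes elimination passes (default 2).
#' @param max_remove_frac cap on the fraction removed (default 0.10).
#' @param ids optional sample ids for reporting.
#' @return list with `keep` (row indices kept), `removed` (data.frame of
#'   id, pass, reason), `fit` (final `latent_fit` on kept rows).
#' @export
remove_outliers <- function(X, y, method = "pls", n_pcs = 5,
                            t_limit = 2.5, gh_limit = 3.0, max_passes = 2,
                            max_remove_frac = 0.10, ids = NULL) {
  stopifnot(t_limit > 0, gh_limit > 0)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- length(y)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  cap <- floor(max_remove_frac * n)
  keep <- seq_len(n)
  removed <- data.frame(id = character(), pass = integer(),
                        reason = character(), stringsAsFactors = FALSE)
  fit <- fit_latent(X, y, n_pcs = n_pcs, method = method)
  for (pass in seq_len(max_passes)) {
    e <- fit$residuals
    sde <- stats::sd(e)
    if (sde < 1e-12) break
    tstat <- abs(e) / sde
    sc <- fit$scores
    sc_sd <- apply(sc, 2, stats::sd)
    sc_sd[sc_sd < 1e-12] <- 1
    gh <- rowMeans(sweep(sc, 2, sc_sd, "/")^2)
    flag <- which(tstat > t_limit | gh > gh_limit)
    if (!length(flag)) break
    budget <- cap - nrow(removed)
    if (budget <= 0) {
      warning("outlier removal cap (", cap, ") reached; stopping elimination")
      break
    }
    truncated <- length(flag) > budget
    flag <- flag[order(pmax(tstat[flag] / t_limit, gh[flag] / gh_limit),
                       decreasing = TRUE)][seq_len(min(length(flag), budget))]
    reason <- ifelse(tstat[flag] > t_limit,
                     ifelse(gh[flag] > gh_limit, "t+gh", "t"), "gh")
    removed <- rbind(removed,
                     data.frame(id = ids[keep][flag], pass = pass,
                                reason = reason, stringsAsFactors = FALSE))
    keep <- keep[-flag]
    fit <- fit_latent(X[keep, , drop = FALSE], y[keep],
                      n_pcs = n_pcs, method = method)
    if (truncated) {
      warning("outlier removal cap (", cap, ") reached; stopping elimination")
      break
    }
  }
  list(keep = keep, removed = removed, fit = fit)
}
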