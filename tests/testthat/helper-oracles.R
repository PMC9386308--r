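# Independent brute-force oracles used to pin down the fast implementations.

# Literal math-treatment operator on a single spectrum, written from the
# definition with explicit loops: boxcar smooth width s1 (even widths use
# the left-center window i-w/2 .. i+w/2-1), d centered gap differences
# y[i] = x[i+g/2] - x[i-g/2], boxcar smooth width s2; edges trimmed.
brute_treatment <- function(x, d, g, s1, s2) {
  smooth <- function(v, w) {
    if (w <= 1) return(v)
    if (w %% 2 == 0) { left <- w / 2; right <- w / 2 - 1 }
    else left <- right <- (w - 1) / 2
    out <- numeric(0)
    for (i in seq_along(v)) {
      if (i - left >= 1 && i + right <= length(v)) {
        acc <- 0
        for (j in (i - left):(i + right)) acc <- acc + v[j]
        out <- c(out, acc / w)
      }
    }
    out
  }
  deriv <- function(v, gap) {
    h <- gap / 2
    out <- numeric(0)
    for (i in seq_along(v)) {
      if (i - h >= 1 && i + h <= length(v)) out <- c(out, v[i + h] - v[i - h])
    }
    out
  }
  v <- smooth(x, s1)
  if (d >= 1) for (k in seq_len(d)) v <- deriv(v, g)
  smooth(v, s2)
}

# O(n^3) Ward agglomeration via Lance-Williams updates on squared
# Euclidean distances; returns flat labels at k clusters.
brute_ward_labels <- function(mat, k) {
  n <- nrow(mat)
  D <- as.matrix(stats::dist(mat))^2
  diag(D) <- Inf
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  while (sum(active) > k) {
    idx <- which(active)
    best <- c(NA, NA); bestd <- Inf
    for (a in idx) for (b in idx) {
      if (a < b && D[a, b] < bestd) { bestd <- D[a, b]; best <- c(a, b) }
    }
    i <- best[1]; j <- best[2]
    ni <- sizes[i]; nj <- sizes[j]
    for (m in idx) {
      if (m == i || m == j) next
      nm <- sizes[m]
      D[i, m] <- D[m, i] <-
        ((ni + nm) * D[i, m] + (nj + nm) * D[j, m] - nm * D[i, j]) /
        (ni + nj + nm)
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- ni + nj
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
  }
  labels <- integer(n)
  cl <- 0L
  for (a in which(active)) { cl <- cl + 1L; labels[members[[a]]] <- cl }
  labels
}

# Two flat clusterings describe the same partition iff their co-membership
# relations agree.
same_partition <- function(a, b) {
  identical(outer(a, a, "=="), outer(b, b, "=="))
}

# Literal block cross-validation: separate fit per held-out block and
# component count, pooled RMSE.
brute_block_cv <- function(X, y, n_pcs_max, n_groups) {
  n <- length(y)
  bounds <- round(seq(0, n, length.out = n_groups + 1))
  groups <- rep(seq_len(n_groups), times = diff(bounds))
  secv <- numeric(n_pcs_max)
  for (k in seq_len(n_pcs_max)) {
    sse <- 0
    for (g in seq_len(n_groups)) {
      hold <- which(groups == g)
      fit <- fit_pls(X[-hold, , drop = FALSE], y[-hold], n_pcs = k)
      pred <- predict(fit, X[hold, , drop = FALSE])
      sse <- sse + sum((y[hold] - pred)^2)
    }
    secv[k] <- sqrt(sse / n)
  }
  secv
}

# Small synthetic scan sets for unit tests.
small_fixture <- function(n = 60, seed = 1, noise_sd = 3e-4,
                          scatter_slope_sd = 0.05, scatter_offset_sd = 0.02) {
  cfg <- simulation_config(n_samples = n, noise_sd = noise_sd,
                           scatter_slope_sd = scatter_slope_sd,
                           scatter_offset_sd = scatter_offset_sd)
  ref <- simulate_compositions(cfg, seed = seed)
  sp <- simulate_spectra(ref, config = cfg, seed = seed + 1000)
  list(spectra = sp, reference = ref, config = cfg)
}

# vector with an exact mean and exact sample SD
vector_with_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  v <- rnorm(n)
  v <- (v - mean(v)) / stats::sd(v)
  mean + sd * v
}

toy_spectra <- function(mat, wl = NULL, ids = NULL) {
  if (is.null(wl)) wl <- seq_len(ncol(mat))
  spectra_set(mat, wl, ids)
}
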