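ols_coef <- function(X, y) {
  # independent oracle: ordinary least squares with intercept
  fit <- lm.fit(cbind(1, X), y)
  fit$coefficients
}

test_that("one-component noiseless data is fit exactly by one latent variable", {
  set.seed(41)
  t_ <- rnorm(20)
  p_ <- runif(6)
  X <- outer(t_, p_)
  y <- 3 * t_ + 5
  for (f in list(fit_pls, fit_mpls)) {
    fit <- f(X, y, n_pcs = 1)
    expect_equal(fit$fitted, y, tolerance = 1e-8)
    expect_gt(rsq(fit$fitted, y), 1 - 1e-10)
  }
  # MPLS with a single factor predicts like PLS
  expect_equal(fit_pls(X, y, 1)$fitted, fit_mpls(X, y, 1)$fitted,
               tolerance = 1e-8)
})

test_that("PLS and PCR at full rank equal ordinary least squares", {
  set.seed(43)
  X <- matrix(rnorm(30), 10, 3)
  y <- drop(X %*% c(1.5, -2, 0.5)) + rnorm(10, 0, 0.3) + 4
  beta <- ols_coef(X, y)
  for (f in list(fit_pls, fit_pcr)) {
    fit <- f(X, y, n_pcs = 3)
    b_full <- c(fit$y_mean - sum(fit$coef * fit$x_mean), fit$coef)
    expect_equal(unname(b_full), unname(beta), tolerance = 1e-8)
  }
})

test_that("PCR needs the response-bearing component and has orthogonal scores", {
  set.seed(47)
  n <- 40
  pc1 <- rnorm(n, 0, 10)   # dominant direction, unrelated to y
  pc2 <- rnorm(n, 0, 1)
  V <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
  X <- pc1 %*% t(V[, 1]) + pc2 %*% t(V[, 2])
  y <- 2 * pc2
  f1 <- fit_pcr(X, y, 1)
  f2 <- fit_pcr(X, y, 2)
  expect_lt(rsq(f1$fitted, y), 0.1)
  expect_gt(rsq(f2$fitted, y), 0.999)
  gram <- crossprod(f2$scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-10)
})

test_that("MPLS residual standardization spreads coefficient mass", {
  set.seed(53)
  n <- 60; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% rep(1, p)) + rnorm(n, 0, 0.5)
  X_scaled <- X
  X_scaled[, 1] <- X_scaled[, 1] * 1000
  share <- function(fit) abs(fit$coef[1] * 1000) / sum(abs(fit$coef * c(1000, rep(1, p - 1))))
  # with a single factor the contrast is starkest: plain PLS latches onto
  # the high-variance column, MPLS's rescaling equalizes the columns
  pls_share <- share(fit_pls(X_scaled, y, 1))
  mpls_share <- share(fit_mpls(X_scaled, y, 1))
  expect_lt(mpls_share, pls_share)
  expect_lt(mpls_share, 0.3)
  expect_gt(pls_share, 0.9)
})

test_that("training SEC never increases with added components", {
  set.seed(59)
  for (method in c("pls", "mpls", "pcr")) {
    X <- matrix(rnorm(40 * 15), 40, 15)
    y <- drop(X %*% rnorm(15)) + rnorm(40)
    fit <- fit_latent(X, y, n_pcs = 8, method = method)
    Xc <- sweep(X, 2, fit$x_mean)
    sec <- vapply(seq_len(fit$n_pcs), function(k) {
      res <- y - (drop(Xc %*% fit$coef_path[, k]) + fit$y_mean)
      sqrt(sum(res^2) / (length(y) - 1))
    }, numeric(1))
    expect_true(all(diff(sec) <= 1e-10), label = method)
  }
})

test_that("predictions are invariant to sample order and serialization", {
  fx <- small_fixture(n = 45, seed = 61)
  plan <- split_by_trait(fx$reference, "oil_pct")
  cal <- subset_samples(fx$spectra, plan$calibration_ids)
  val <- subset_samples(fx$spectra, plan$validation_ids)
  model <- calibrate(cal, fx$reference, "oil_pct", method = "pls",
                     scatter = "msc", treatment = "2,4,4,1")
  pred <- predict(model, val)
  perm <- rev(seq_along(val$sample_ids))
  pred_perm <- predict(model, subset_samples(val, perm))
  expect_equal(pred[perm], pred_perm, tolerance = 1e-12)

  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  model2 <- load_model(path)
  expect_identical(predict(model2, val), pred)
})

test_that("block cross-validation matches a literal loop-based oracle and
           caps the component count", {
  fx <- small_fixture(n = 30, seed = 67)
  treated <- preprocess(fx$spectra, "msc", "2,4,4,1")
  X <- treated$absorbance
  y <- fx$reference$protein_pct
  cv <- cross_validate(X, y, method = "pls", n_pcs_max = 5, n_groups = 4)
  expect_equal(cv$secv, brute_block_cv(X, y, 5, 4), tolerance = 1e-10)
  expect_lte(cv$n_pcs, 5)

  # noiseless two-component response: SECV bottoms out at 2 components
  set.seed(71)
  t1 <- rnorm(36); t2 <- rnorm(36)
  P <- qr.Q(qr(matrix(rnorm(20 * 2), 20, 2)))
  X2 <- t1 %*% t(P[, 1]) + t2 %*% t(P[, 2])
  y2 <- t1 - 2 * t2
  cv2 <- cross_validate(X2, y2, method = "pls", n_pcs_max = 4, n_groups = 4)
  expect_equal(cv2$n_pcs, 2)
  expect_lt(cv2$secv[2], 1e-8)
})

test_that("outlier elimination flags spikes, spares clean data, and
           respects the removal cap", {
  set.seed(73)
  t_ <- rnorm(40)
  X <- outer(t_, runif(10))
  y <- 2 * t_ + 1
  clean <- remove_outliers(X, y, method = "pls", n_pcs = 1)
  expect_equal(nrow(clean$removed), 0)

  y_spiked <- y + rnorm(40, 0, 0.05)
  y_spiked[17] <- y_spiked[17] + 10 * sd(y_spiked)
  res <- remove_outliers(X, y_spiked, method = "pls", n_pcs = 1,
                         ids = sprintf("S%02d", 1:40))
  expect_true("S17" %in% res$removed$id)
  expect_true(all(res$removed$reason[res$removed$id == "S17"] %in%
                    c("t", "t+gh")))

  # eight corrupted samples in a 120-sample set: removals stay within the
  # 10 percent cap
  fx <- small_fixture(n = 120, seed = 79)
  treated <- preprocess(fx$spectra, "snv_dt", "2,8,8,1")
  Xf <- treated$absorbance
  yf <- fx$reference$amylose_pct
  bad <- c(3, 17, 29, 41, 53, 67, 88, 101)
  yf[bad] <- yf[bad] + c(6, -7, 8, -6, 7, -8, 6, 9)
  resf <- suppressWarnings(
    remove_outliers(Xf, yf, method = "pls", n_pcs = 5,
                    ids = fx$spectra$sample_ids))
  expect_lte(nrow(resf$removed), floor(0.10 * 120))
  expect_gte(sum(fx$spectra$sample_ids[bad] %in% resf$removed$id), 6)
})

test_that("degenerate regression inputs raise informative errors", {
  X <- matrix(rnorm(30), 10, 3)
  expect_error(fit_pls(X, rep(1, 10), 2), "zero variance")
  expect_error(fit_pls(X, rnorm(10), 12), "more samples")
})
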