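test_that("MSC correction formula behaves on forced cases", {
  set.seed(4)
  m <- runif(40, 0.2, 1.2)
  sp <- toy_spectra(rbind(m, 2 * m + 1), ids = c("same", "scaled"))
  res <- msc_fit_apply(sp, reference = m)
  expect_equal(unname(res$spectra$absorbance[1, ]), m, tolerance = 1e-12)
  expect_equal(unname(res$spectra$absorbance[2, ]), m, tolerance = 1e-12)
  expect_identical(res$correction$method, "msc")
  expect_equal(res$correction$reference, m)

  flat <- toy_spectra(rbind(m, rep(mean(m), 40)), ids = c("ok", "flat"))
  expect_error(msc_fit_apply(flat, reference = m), "flat")
})

test_that("MSC removes simulated scatter variance at baseline wavelengths", {
  fx <- small_fixture(n = 80, seed = 13)
  corrected <- msc_fit_apply(fx$spectra)$spectra
  # 800 nm carries baseline only (far from every configured band)
  i <- which(fx$spectra$wavelengths_nm == 800)
  v_raw <- var(fx$spectra$absorbance[, i])
  v_cor <- var(corrected$absorbance[, i])
  expect_lt(v_cor, 0.1 * v_raw)
})

test_that("SNV-DT annihilates affine and quadratic spectra, centers the rest", {
  wl <- seq(400, 600, by = 2)
  affine <- 0.3 + 0.002 * wl
  quad <- 1 + 0.01 * (wl - 500) + 3e-5 * (wl - 500)^2
  set.seed(5)
  bumpy <- 0.5 + 0.3 * exp(-(wl - 480)^2 / 200) + rnorm(length(wl), 0, 0.01)
  sp <- toy_spectra(rbind(affine, quad, bumpy), wl,
                    ids = c("affine", "quad", "bumpy"))
  out <- snv_detrend(sp)$absorbance
  expect_lt(max(abs(out[1, ])), 1e-10)
  expect_lt(max(abs(out[2, ])), 1e-10)
  # residual property: output orthogonal to {1, wl, wl^2}
  fit <- lm(out[3, ] ~ wl + I(wl^2))
  expect_lt(max(abs(coef(fit))), 1e-8)

  expect_error(snv_detrend(toy_spectra(matrix(1, 1, 10))), "constant")
})

test_that("treatment codes parse, serialize and reject malformed input", {
  t1 <- parse_treatment("4,8,8,1")
  expect_equal(unclass(t1)[c("d", "g", "s1", "s2")],
               list(d = 4L, g = 8L, s1 = 8L, s2 = 1L))
  expect_identical(format(parse_treatment("3,16,8,2")), "3,16,8,2")
  t0 <- parse_treatment("0,0,1,1")
  expect_equal(t0$d, 0L)
  expect_error(parse_treatment("1,2,3"), "four")
  expect_error(parse_treatment("1,-2,1,1"), "gap|even|positive")
  expect_error(parse_treatment("1,3,1,1"), "odd gap")
  expect_error(parse_treatment("2,0,1,1"), "positive")
})

test_that("gap derivatives reproduce closed forms on polynomial spectra", {
  idx <- 1:60
  c0 <- 0.37
  lin <- toy_spectra(matrix(c0 * idx, 1))
  out <- apply_treatment(lin, "1,4,1,1")
  expect_equal(unname(out$absorbance[1, ]),
               rep(4 * c0, ncol(out$absorbance)), tolerance = 1e-12)
  expect_equal(out$wavelengths_nm, 3:58)

  quad <- toy_spectra(matrix(0.1 * idx^2, 1))
  d2 <- apply_treatment(quad, "2,2,1,1")$absorbance
  expect_equal(unname(d2[1, ]), rep(0.1 * 8, ncol(d2)), tolerance = 1e-10)
  d3 <- apply_treatment(quad, "3,2,1,1")$absorbance
  expect_lt(max(abs(d3)), 1e-10)

  any_sp <- toy_spectra(matrix(rnorm(60), 1))
  expect_equal(apply_treatment(any_sp, "0,0,1,1")$absorbance,
               any_sp$absorbance)
})

test_that("fast treatment operator matches the literal brute-force oracle", {
  set.seed(6)
  # gap-16 treatments trim 2*d*8 points, so they get a longer test grid
  codes <- c("2,4,4,1" = 50, "3,16,8,2" = 120, "4,8,8,1" = 50,
             "4,6,6,1" = 50, "2,8,8,1" = 50, "0,0,5,1" = 50,
             "1,2,1,4" = 50, "4,16,8,2" = 160)
  for (code in names(codes)) {
    t <- parse_treatment(code)
    x <- rnorm(codes[[code]])
    fast <- apply_treatment(toy_spectra(matrix(x, 1)), t)$absorbance[1, ]
    slow <- brute_treatment(x, t$d, t$g, t$s1, t$s2)
    expect_equal(unname(fast), slow, tolerance = 1e-10, label = code)
  }
})

test_that("treatment operator is linear and row-local", {
  set.seed(8)
  x <- rnorm(50); y <- rnorm(50)
  a <- 2.5; b <- -1.3
  t <- "2,4,4,1"
  Tx <- apply_treatment(toy_spectra(matrix(x, 1)), t)$absorbance
  Ty <- apply_treatment(toy_spectra(matrix(y, 1)), t)$absorbance
  Tz <- apply_treatment(toy_spectra(matrix(a * x + b * y, 1)), t)$absorbance
  expect_equal(Tz, a * Tx + b * Ty, tolerance = 1e-10)

  mat <- matrix(rnorm(200), 4, 50)
  perm <- c(3, 1, 4, 2)
  T1 <- apply_treatment(toy_spectra(mat, ids = letters[1:4]), t)
  T2 <- apply_treatment(toy_spectra(mat[perm, ], ids = letters[perm]), t)
  expect_equal(T1$absorbance[perm, ], T2$absorbance, ignore_attr = TRUE)
})

test_that("treatments that empty the grid raise a sizing error", {
  short <- toy_spectra(matrix(rnorm(10), 1))
  expect_error(apply_treatment(short, "4,16,8,2"), "too short")
})

test_that("preprocess chains scatter correction and treatment with history", {
  fx <- small_fixture(n = 20, seed = 30)
  out <- preprocess(fx$spectra, "snv_dt", "3,16,8,2")
  expect_true(all(is.finite(out$absorbance)))
  expect_lt(length(out$wavelengths_nm), 1046)
  expect_identical(out$meta$history,
                   c("scatter:snv_dt", "treatment:3,16,8,2"))

  # (msc, identity treatment) is MSC alone
  via_pre <- preprocess(fx$spectra, "msc", "0,0,1,1")
  direct <- msc_fit_apply(fx$spectra)$spectra
  expect_equal(via_pre$absorbance, direct$absorbance)

  # (none, treatment) is the treatment alone
  via_pre2 <- preprocess(fx$spectra, "none", "4,8,8,1")
  direct2 <- apply_treatment(fx$spectra, "4,8,8,1")
  expect_equal(via_pre2$absorbance, direct2$absorbance)
})
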