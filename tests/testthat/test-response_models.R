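test_that("linear moisture fit recovers exact linear data and rejects degenerate designs", {
  w <- seq(5, 30, length.out = 12)
  df <- make_meas(2 + 0.5 * w, w = w)
  f <- fit_moisture_linear(df)
  expect_equal(f$m, 2, tolerance = 1e-10)
  expect_equal(f$n, 0.5, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-10)
  expect_error(fit_moisture_linear(make_meas(1:5, w = 10)),
               class = "fs_degenerate_error")
  expect_error(fit_moisture_linear(make_meas(1:2, w = c(1, 2))),
               class = "fs_argument_error")
})

test_that("moisture fit under the null shows no explanatory power", {
  set.seed(101)
  df <- make_meas(rlnorm(200, 0.5, 0.3), w = runif(200, 5, 35))
  f <- fit_moisture_linear(df)
  expect_lt(f$r2, 0.05)
  expect_gt(f$p_value, 0.05)
})

test_that("exponential fit recovers noise-free parameters exactly (both methods)", {
  temp <- seq(15, 32, length.out = 20)
  df <- make_meas(0.174 * exp(0.098 * temp), temp = temp)
  for (method in c("nls", "loglinear")) {
    f <- fit_temperature_exponential(df, method = method)
    expect_equal(f$a, 0.174, tolerance = 1e-6)
    expect_equal(f$b, 0.098, tolerance = 1e-6)
    expect_equal(f$r2, 1, tolerance = 1e-9)
    expect_equal(f$q10, exp(10 * f$b), tolerance = 1e-12)
  }
  expect_error(fit_temperature_exponential(make_meas(1:5, temp = 20)),
               class = "fs_degenerate_error")
  neg <- make_meas(c(0, 1, 2), temp = c(18, 22, 26))
  expect_error(fit_temperature_exponential(neg, method = "loglinear"),
               class = "fs_domain_error")
})

test_that("bivariate fit recovers noise-free parameters and nests the exponential", {
  set.seed(5)
  temp <- runif(30, 15, 32)
  w <- runif(30, 5, 35)
  df <- make_meas(0.307 * exp(0.066 * temp) * w^0.118, temp = temp, w = w)
  f <- fit_temperature_moisture(df)
  expect_equal(f$a, 0.307, tolerance = 1e-6)
  expect_equal(f$b, 0.066, tolerance = 1e-6)
  expect_equal(f$c, 0.118, tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)

  # nesting: data generated with c = 0 gives back the univariate fit
  df0 <- make_meas(0.2 * exp(0.09 * temp), temp = temp, w = w)
  fb <- fit_temperature_moisture(df0)
  fe <- fit_temperature_exponential(df0)
  expect_equal(fb$c, 0, tolerance = 1e-6)
  expect_equal(fb$a, fe$a, tolerance = 1e-6)
  expect_equal(fb$b, fe$b, tolerance = 1e-6)
  expect_error(fit_temperature_moisture(make_meas(1:5, temp = 20:24, w = 0)),
               class = "fs_domain_error")
})

test_that("all three fits recover random noise-free draws to <= 1e-6 relative error", {
  set.seed(77)
  for (i in 1:10) {
    a <- runif(1, 0.1, 0.5); b <- runif(1, 0.05, 0.12)
    cc <- runif(1, 0.02, 0.25)
    m <- runif(1, 1, 3); n <- runif(1, 0.02, 0.1)  # keeps rates positive
    temp <- runif(25, 14, 33); w <- runif(25, 4, 38)
    fl <- fit_moisture_linear(make_meas(m + n * w, w = w))
    expect_equal(fl$m, m, tolerance = 1e-6)
    expect_equal(fl$n, n, tolerance = 1e-6)
    fe <- fit_temperature_exponential(make_meas(a * exp(b * temp), temp = temp))
    expect_equal(fe$a, a, tolerance = 1e-6)
    expect_equal(fe$b, b, tolerance = 1e-6)
    fb <- fit_temperature_moisture(
      make_meas(a * exp(b * temp) * w^cc, temp = temp, w = w))
    expect_equal(fb$a, a, tolerance = 1e-6)
    expect_equal(fb$b, b, tolerance = 1e-6)
    expect_equal(fb$c, cc, tolerance = 1e-6)
  }
})

test_that("on a synthetic stand the model hierarchy behaves as expected", {
  b <- small_bundle()
  rec <- b$measurements[b$measurements$stand_id == "SF", ]
  fl <- fit_moisture_linear(rec)
  fe <- fit_temperature_exponential(rec)
  fb <- fit_temperature_moisture(rec)
  expect_gt(fl$n, 0)                      # weak positive moisture slope
  expect_lt(fl$r2, fe$r2)                 # temperature dominates
  expect_gte(fb$r2, fe$r2 - 1e-9)         # nested model can't fit worse
  expect_lt(fb$r2 - fe$r2, 0.1)           # ...and adds little
  expect_true(fe$r2 > 0.45 && fe$r2 < 0.95)
  expect_lt(abs(fe$b - b$truth$SF$b_true) / b$truth$SF$b_true, 0.15)
})

test_that("nls optimum beats a dense parameter grid on a noisy fixture", {
  set.seed(13)
  temp <- runif(10, 15, 32)
  df <- make_meas(0.25 * exp(0.09 * temp) * rlnorm(10, 0, 0.2), temp = temp)
  f <- fit_temperature_exponential(df)
  sse <- function(a, b) sum((df$rs - a * exp(b * temp))^2)
  sse_fit <- sse(f$a, f$b)
  grid <- expand.grid(a = seq(0.1, 0.5, length.out = 60),
                      b = seq(0.05, 0.14, length.out = 60))
  sse_grid <- min(mapply(sse, grid$a, grid$b))
  expect_lte(sse_fit, sse_grid + 1e-9)
})

test_that("q10 follows the exponential identity and is strictly monotone", {
  expect_equal(round(compute_q10(0.098), 2), 2.66)
  expect_equal(round(compute_q10(0.102), 2), 2.77)
  expect_equal(compute_q10(0), 1)
  bs <- sort(runif(25, -0.1, 0.2))
  expect_true(all(diff(compute_q10(bs)) > 0))
  expect_error(compute_q10(Inf), class = "fs_argument_error")
})

test_that("predict_rs evaluates each fitted form exactly", {
  fe <- structure(list(a = 1, b = 0), class = c("exponential_fit", "fs_fit"))
  expect_equal(predict_rs(fe, temp = c(-5, 20, 40)), rep(1, 3))
  fb <- structure(list(a = 0.307, b = 0.066, c = 0.118),
                  class = c("bivariate_fit", "fs_fit"))
  expect_equal(predict_rs(fb, temp = 25, moisture = 20),
               0.307 * exp(0.066 * 25) * 20^0.118)
  fl <- structure(list(m = 2.35, n = -0.007), class = c("linear_fit", "fs_fit"))
  expect_equal(round(predict_rs(fl, moisture = 10), 2), 2.28)
  expect_error(predict_rs(fl), class = "fs_argument_error")
  expect_error(predict_rs(fb, temp = 25, moisture = -1),
               class = "fs_domain_error")
})

test_that("nls and loglinear agree on clean data and stay close under noise", {
  set.seed(23)
  temp <- runif(60, 15, 32)
  clean <- make_meas(0.3 * exp(0.08 * temp), temp = temp)
  f1 <- fit_temperature_exponential(clean, "nls")
  f2 <- fit_temperature_exponential(clean, "loglinear")
  expect_equal(f1$b, f2$b, tolerance = 1e-6)
  noisy <- make_meas(0.3 * exp(0.08 * temp) * rlnorm(60, 0, 0.25), temp = temp)
  g1 <- fit_temperature_exponential(noisy, "nls")
  g2 <- fit_temperature_exponential(noisy, "loglinear")
  expect_lt(abs(g1$b - g2$b), g1$se_b)   # within one estimator sd
})
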