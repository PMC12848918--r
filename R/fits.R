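# Respiration response models.
#
# Three forms are fitted, mirroring the standard hierarchy for seasonal
# chamber data:
#   linear moisture       Rs = m + n * W
#   exponential temperature Rs = a * exp(b * T)      (Q10 = exp(10 b))
#   bivariate             Rs = a * exp(b * T) * W^c
# Nonlinear fits run on the original rate scale (R2 = 1 - SSE/SST there),
# initialised from the log-linear closed form; the purely log-linear fit is
# exposed as an alternative `method`.

fit_frame <- function(records) {
  records <- validate_measurements(records)
  data.frame(rs = records$rs, temp = records$soil_temp_10cm,
             w = records$soil_moisture)
}

check_nondegenerate <- function(x, what) {
  if (stats::sd(x) < 1e-12)
    abort_fs(sprintf("degenerate design: %s is constant", what),
             "fs_degenerate_error")
}

model_f_pvalue <- function(sse, sst, n, p) {
  if (sse <= 0) return(0)
  f <- ((sst - sse) / (p - 1)) / (sse / (n - p))
  stats::pf(f, p - 1, n - p, lower.tail = FALSE)
}

#' Linear moisture response fit
#'
#' Ordinary least squares of respiration rate on volumetric soil moisture,
#' `Rs = m + n * W`.
#'
#' @param records measurement table (>= 3 rows, non-constant moisture).
#' @return a `linear_fit` with m, n, r2, p_value, n_obs.
#' @export
fit_moisture_linear <- function(records) {
  d <- fit_frame(records)
  if (nrow(d) < 3) abort_fs("need >= 3 records", "fs_argument_error")
  check_nondegenerate(d$w, "soil_moisture")
  fit <- stats::lm(rs ~ w, data = d)
  # noise-free oracle fixtures are legitimate inputs: silence the
  # "essentially perfect fit" warning from summary.lm
  s <- suppressWarnings(summary(fit))
  structure(list(m = unname(stats::coef(fit)[1L]),
                 n = unname(stats::coef(fit)[2L]),
                 r2 = s$r.squared,
                 p_value = unname(stats::pf(s$fstatistic[1L], s$fstatistic[2L],
                                            s$fstatistic[3L], lower.tail = FALSE)),
                 n_obs = nrow(d)),
            class = c("linear_fit", "fs_fit"))
}

loglinear_start <- function(d, bivariate = FALSE) {
  pos <- d$rs > 0 & (!bivariate | d$w > 0)
  if (sum(!pos))
    message(sprintf("excluded %d record(s) with non-positive rs/moisture from the log-linear step",
                    sum(!pos)))
  dp <- d[pos, , drop = FALSE]
  if (nrow(dp) < 3) abort_fs("too few positive records", "fs_domain_error")
  if (bivariate) {
    if (abs(stats::cor(dp$temp, log(dp$w))) > 0.999)
      abort_fs("degenerate design: temperature and log(moisture) collinear",
               "fs_degenerate_error")
    co <- stats::coef(stats::lm(log(rs) ~ temp + log(w), data = dp))
    list(a = exp(unname(co[1L])), b = unname(co[2L]), c = unname(co[3L]))
  } else {
    co <- stats::coef(stats::lm(log(rs) ~ temp, data = dp))
    list(a = exp(unname(co[1L])), b = unname(co[2L]))
  }
}

finish_exp_fit <- function(d, pars, se_b, n_par, cls) {
  pred <- pars$a * exp(pars$b * d$temp)
  if (!is.null(pars$c)) pred <- pred * d$w^pars$c
  sse <- sum((d$rs - pred)^2)
  sst <- sum((d$rs - mean(d$rs))^2)
  out <- c(pars, list(
    r2 = 1 - sse / sst,
    p_value = model_f_pvalue(sse, sst, nrow(d), n_par),
    n_obs = nrow(d)))
  if (cls == "exponential_fit") {
    out$q10 <- compute_q10(pars$b)
    out$se_b <- se_b
    out$q10_se <- if (is.null(se_b)) NA_real_ else 10 * out$q10 * se_b
  }
  structure(out, class = c(cls, "fs_fit"))
}

#' Exponential temperature response fit
#'
#' Fits `Rs = a * exp(b * T)`. The default method is nonlinear least squares
#' on the original rate scale, initialised from the log-linear closed form
#' `ln Rs = ln a + b T`; `method = "loglinear"` returns the closed-form fit
#' itself (requires strictly positive rates). R2 is `1 - SSE/SST` on the
#' rate scale in both cases, and `q10 = exp(10 b)` is attached together with
#' a delta-method standard error (`q10_se`, from the nls `b` standard
#' error; `NA` for the log-linear path).
#'
#' @param records measurement table (>= 3 rows, non-constant temperature).
#' @param method `"nls"` (default) or `"loglinear"`.
#' @return an `exponential_fit` with a, b, r2, p_value, n_obs, q10.
#' @export
fit_temperature_exponential <- function(records, method = c("nls", "loglinear")) {
  method <- match.arg(method)
  d <- fit_frame(records)
  if (nrow(d) < 3) abort_fs("need >= 3 records", "fs_argument_error")
  check_nondegenerate(d$temp, "soil_temp_10cm")
  if (method == "loglinear" && any(d$rs <= 0))
    abort_fs("rs <= 0 is outside the log-linear domain", "fs_domain_error")
  start <- loglinear_start(d)
  if (method == "loglinear")
    return(finish_exp_fit(d, start, se_b = NULL, n_par = 2L,
                          cls = "exponential_fit"))
  fit <- run_nls(rs ~ a * exp(b * temp), d, start)
  co <- as.list(stats::coef(fit))
  finish_exp_fit(d, co, se_b = summary(fit)$coefficients["b", "Std. Error"],
                 n_par = 2L, cls = "exponential_fit")
}

#' Bivariate temperature-moisture response fit
#'
#' Fits `Rs = a * exp(b * T) * W^c` by nonlinear least squares on the rate
#' scale (default), initialised from the multiple log-linear regression of
#' `ln Rs` on `(T, ln W)`, or by that log-linear regression itself.
#'
#' @inheritParams fit_temperature_exponential
#' @return a `bivariate_fit` with a, b, c, r2, p_value, n_obs.
#' @export
fit_temperature_moisture <- function(records, method = c("nls", "loglinear")) {
  method <- match.arg(method)
  d <- fit_frame(records)
  if (nrow(d) < 4) abort_fs("need >= 4 records", "fs_argument_error")
  if (any(d$w <= 0))
    abort_fs("moisture <= 0 is outside the power-law domain", "fs_domain_error")
  check_nondegenerate(d$temp, "soil_temp_10cm")
  check_nondegenerate(d$w, "soil_moisture")
  if (method == "loglinear" && any(d$rs <= 0))
    abort_fs("rs <= 0 is outside the log-linear domain", "fs_domain_error")
  start <- loglinear_start(d, bivariate = TRUE)
  if (method == "loglinear")
    return(finish_exp_fit(d, start, se_b = NULL, n_par = 3L,
                          cls = "bivariate_fit"))
  fit <- run_nls(rs ~ a * exp(b * temp) * w^c, d, start)
  finish_exp_fit(d, as.list(stats::coef(fit)), se_b = NULL, n_par = 3L,
                 cls = "bivariate_fit")
}

# nls with settings that also converge on artificial zero-residual data
# (scaleOffset) and carry diagnostics on failure. Start values of exactly
# zero are nudged: nls's numeric-derivative step is relative, so a zero
# start yields a zero gradient column ("singular gradient").
run_nls <- function(formula, data, start) {
  start <- lapply(start, function(v) if (abs(v) < 1e-8) 1e-8 else v)
  tryCatch(
    stats::nls(formula, data = data, start = start,
               control = stats::nls.control(maxiter = 500, minFactor = 1e-10,
                                            scaleOffset = 1)),
    error = function(e)
      abort_fs(paste0("nls failed to converge: ", conditionMessage(e)),
               "fs_fit_error"))
}

#' Q10 temperature sensitivity
#'
#' Under the exponential model `Rs = a * exp(b * T)`, a 10 degC warming
#' multiplies the rate by `Q10 = exp(10 b)`.
#'
#' @param b exponential temperature coefficient (per degC); vectorised.
#' @return `exp(10 * b)`.
#' @examples
#' compute_q10(c(0.098, 0.071, 0.088, 0.102))
#' @export
compute_q10 <- function(b) {
  if (!is.numeric(b) || !all(is.finite(b)))
    abort_fs("`b` must be finite numeric", "fs_argument_error")
  exp(10 * b)
}

#' Evaluate a fitted response model
#'
#' @param fit a `linear_fit`, `exponential_fit` or `bivariate_fit`.
#' @param temp soil temperature (degC); ignored by `linear_fit`.
#' @param moisture volumetric soil moisture (%); required by `linear_fit`
#'   and `bivariate_fit` (positive for the latter).
#' @return predicted respiration rate(s), umol CO2 m-2 s-1.
#' @export
predict_rs <- function(fit, temp = NULL, moisture = NULL) {
  UseMethod("predict_rs")
}

#' @export
predict_rs.linear_fit <- function(fit, temp = NULL, moisture = NULL) {
  if (is.null(moisture))
    abort_fs("linear_fit prediction requires `moisture`", "fs_argument_error")
  fit$m + fit$n * moisture
}

#' @export
predict_rs.exponential_fit <- function(fit, temp = NULL, moisture = NULL) {
  if (is.null(temp))
    abort_fs("exponential_fit prediction requires `temp`", "fs_argument_error")
  fit$a * exp(fit$b * temp)
}

#' @export
predict_rs.bivariate_fit <- function(fit, temp = NULL, moisture = NULL) {
  if (is.null(temp) || is.null(moisture))
    abort_fs("bivariate_fit prediction requires `temp` and `moisture`",
             "fs_argument_error")
  if (any(moisture <= 0))
    abort_fs("moisture must be positive", "fs_domain_error")
  fit$a * exp(fit$b * temp) * moisture^fit$c
}

#' @export
print.fs_fit <- function(x, ...) {
  cls <- class(x)[1L]
  eq <- switch(cls,
    linear_fit = sprintf("Rs = %.4f + %.4f W", x$m, x$n),
    exponential_fit = sprintf("Rs = %.4f exp(%.4f T)   Q10 = %.2f",
                              x$a, x$b, x$q10),
    bivariate_fit = sprintf("Rs = %.4f exp(%.4f T) W^%.4f", x$a, x$b, x$c))
  cat(sprintf("<%s> %s\n  R2 = %.3f%s  (n = %d)\n", cls, eq, x$r2,
              significance_star(x$p_value), x$n_obs))
  invisible(x)
}
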