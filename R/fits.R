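#' Fit a gamma distribution by maximum likelihood
#'
#' Maximum-likelihood fit with method-of-moments starting values (shape
#' = mean^2 / var, rate = mean / var). Falls back to the moment estimate
#' if the likelihood optimization fails to converge.
#'
#' @param x positive finite values, length >= 2.
#' @return list with `shape` and `rate`.
#' @export
fit_gamma <- function(x) {
  x <- x[is.finite(x)]
  stop_if(length(x) < 2L, "need at least 2 finite values for a gamma fit")
  stop_if(any(x <= 0), "gamma fit requires strictly positive values")
  m <- mean(x); v <- stats::var(x)
  stop_if(v == 0, "degenerate gamma fit: input has zero variance")
  start <- list(shape = m^2 / v, rate = m / v)
  fit <- tryCatch(
    fitdistrplus::fitdist(x, "gamma", method = "mle", start = start,
                          lower = c(1e-8, 1e-8)),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$estimate)))
    return(start)
  list(shape = unname(fit$estimate["shape"]),
       rate = unname(fit$estimate["rate"]))
}

#' Fit a log-normal distribution by maximum likelihood
#'
#' The MLE is available in closed form: mean and standard deviation of
#' the log values.
#'
#' @param x positive finite values, length >= 2.
#' @return list with `meanlog` and `sdlog`.
#' @export
fit_lnorm <- function(x) {
  x <- x[is.finite(x)]
  stop_if(length(x) < 2L, "need at least 2 finite values for a log-normal fit")
  stop_if(any(x <= 0), "log-normal fit requires strictly positive values")
  lx <- log(x)
  n <- length(lx)
  list(meanlog = mean(lx), sdlog = sqrt(stats::var(lx) * (n - 1) / n))
}
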