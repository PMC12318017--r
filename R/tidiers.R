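#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the path-model coefficients
#' @param x a `tf_path_model`.
#' @param ... unused.
#' @return tibble: term, estimate, std.error, statistic, p.value.
#' @export
tidy.tf_path_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
         statistic = sm[, 3], p.value = sm[, 4])
}

#' One-row summary of the path model
#' @param x a `tf_path_model`.
#' @param ... unused.
#' @return tibble: r.squared, sigma, nobs.
#' @export
glance.tf_path_model <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = x$sigma, nobs = x$n)
}

#' Tidy the outcome-classifier coefficients (original metric scale)
#' @param x a `tf_classifier`.
#' @param ... unused.
#' @return tibble: term, estimate.
#' @export
tidy.tf_classifier <- function(x, ...) {
  b <- x$coefficients
  slopes <- b[-1] / x$scale
  intercept <- b[1] - sum(b[-1] * x$center / x$scale)
  tibble(term = c("(Intercept)", x$metrics),
         estimate = c(intercept, slopes))
}

#' One-row summary of the outcome classifier
#' @param x a `tf_classifier`.
#' @param ... unused.
#' @return tibble: log_lik, converged, separation, nobs.
#' @export
glance.tf_classifier <- function(x, ...) {
  tibble(log_lik = x$log_lik, converged = x$converged,
         separation = x$separation, nobs = x$n)
}
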