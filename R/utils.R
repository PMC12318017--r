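#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||% .data :=
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across left_join bind_rows bind_cols n rename row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom stats fft sd cor var approx quantile rnorm runif rpois lm coef
#'   median complete.cases setNames
NULL

# consistent error classes so callers can condition on failure kind
tf_abort <- function(msg, class = "tf_error", ...) {
  abort(msg, class = c(class, "tf_error"), ...)
}

tf_validation_error <- function(msg, field = NULL) {
  if (!is.null(field)) msg <- paste0(msg, " [field: ", field, "]")
  tf_abort(msg, class = "tf_validation_error", field = field)
}

tf_data_error <- function(msg, stream_id = NULL) {
  if (!is.null(stream_id)) msg <- paste0(msg, " [stream: ", stream_id, "]")
  tf_abort(msg, class = "tf_data_error", stream_id = stream_id)
}

rms <- function(x) sqrt(mean(x^2, na.rm = TRUE))

# Deterministic child seed derived from a root seed and string labels.
# Keeps derived seeds in [0, 2^31): a simple polynomial string hash, stable
# across platforms (no dependence on R's RNG state).
child_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(labels)) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h)
}

is_uniform_grid <- function(t, tol = 1e-6) {
  if (length(t) < 3) return(TRUE)
  dt <- diff(t)
  max(abs(dt - mean(dt))) < tol * max(mean(dt), 1e-12)
}

#' Gini coefficient of a non-negative vector
#'
#' Inequality of a load (or any non-negative quantity) across athletes:
#' 0 means perfectly equal shares, (n-1)/n means one athlete carries
#' everything.
#'
#' @param x numeric vector of non-negative values.
#' @return a single number in `[0, 1)`.
#' @export
#' @examples
#' gini(c(1, 1, 1, 1))      # 0
#' gini(c(0, 0, 0, 4))      # 0.75
gini <- function(x) {
  if (any(x < 0)) tf_validation_error("gini() requires non-negative values", "x")
  n <- length(x)
  if (n == 0 || sum(x) == 0) return(0)
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n * sum(xs))
}
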