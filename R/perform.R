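#' Fit the team-individual performance path model
#'
#' Observed-variable linear path model
#' `P_team = b1 * C_spatial + b2 * C_temporal + b3 * sum_i w_i P_ind_i + e`,
#' fitted by ordinary least squares on the three composite predictors. The
#' per-athlete contribution weights `w` are user inputs (default uniform).
#'
#' @param data data frame with columns `p_team`, `c_spatial`, `c_temporal`
#'   (one row per session).
#' @param p_ind numeric matrix of individual performance metrics, one row
#'   per session, one column per athlete.
#' @param w per-athlete contribution weights (default uniform, normalized
#'   to sum 1).
#' @param intercept include an intercept (default TRUE).
#' @return object of class `tf_path_model`: coefficients, standard errors,
#'   `r_squared`, `sigma`, the underlying `lm` fit.
#' @export
fit_path_model <- function(data, p_ind, w = NULL, intercept = TRUE) {
  data <- as_tibble(data)
  if (nrow(data) < 10) tf_validation_error("need at least 10 sessions", "data")
  p_ind <- as.matrix(p_ind)
  if (nrow(p_ind) != nrow(data)) {
    tf_validation_error("p_ind must have one row per session", "p_ind")
  }
  if (is.null(w)) w <- rep(1 / ncol(p_ind), ncol(p_ind))
  w <- w / sum(w)
  df <- tibble(p_team = data$p_team,
               c_spatial = data$c_spatial,
               c_temporal = data$c_temporal,
               p_ind_comp = as.numeric(p_ind %*% w))
  preds <- c("c_spatial", "c_temporal", "p_ind_comp")
  degenerate <- preds[vapply(df[preds], function(v) sd(v) < 1e-12, logical(1))]
  if (length(degenerate)) {
    tf_abort(paste0("unidentifiable path coefficients; constant predictor(s): ",
                    paste(degenerate, collapse = ", ")),
             class = "tf_identifiability_error")
  }
  Xm <- scale(as.matrix(df[preds]), scale = FALSE)
  kappa_ <- kappa(crossprod(Xm), exact = TRUE)
  if (kappa_ > 1e8) {
    tf_abort(sprintf("collinear design (condition number %.3g): %s",
                     kappa_, paste(preds, collapse = ", ")),
             class = "tf_identifiability_error")
  }
  fml <- if (intercept) p_team ~ c_spatial + c_temporal + p_ind_comp else
    p_team ~ c_spatial + c_temporal + p_ind_comp - 1
  fit <- lm(fml, data = df)
  sm <- summary(fit)
  structure(list(
    coefficients = coef(fit),
    se = sm$coefficients[, "Std. Error"],
    r_squared = sm$r.squared, sigma = sm$sigma,
    w = w, n = nrow(df), fit = fit),
    class = "tf_path_model")
}

#' @export
print.tf_path_model <- function(x, ...) {
  cat("Team-individual performance path model (OLS)\n")
  cat(sprintf("  n = %d sessions, R^2 = %.3f, sigma = %.3g\n",
              x$n, x$r_squared, x$sigma))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Fit the four-metric outcome classifier
#'
#' Logistic regression of session outcome (win vs loss) on the four key
#' collaborative metrics — temporal coordination rate, coordination
#' perturbation response, spatial synchronization and individual-collective
#' coupling — fitted by iteratively reweighted least squares. Under
#' complete separation the fit is ridge-stabilized with a warning.
#'
#' @param data tibble from [make_outcome_dataset()] (or any frame with an
#'   `outcome` column of "win"/"loss" and the metric columns).
#' @param metrics predictor column names.
#' @param ridge ridge stabilizer used on separation.
#' @param max_iter IRLS iteration cap.
#' @return object of class `tf_classifier`: `coefficients` (intercept
#'   first), `metrics`, `converged`, `separation`, `log_lik`, scaling info.
#' @export
fit_outcome_classifier <- function(data, metrics = c("tcr", "cpr", "ssi", "icc"),
                                   ridge = 1e-6, max_iter = 50) {
  data <- as_tibble(data)
  y <- as.integer(data$outcome == "win")
  if (length(unique(y)) < 2) {
    tf_validation_error("both outcome classes must be present", "outcome")
  }
  missing_m <- setdiff(metrics, names(data))
  if (length(missing_m)) {
    tf_validation_error(paste0("metric column(s) not in data: ",
                               paste(missing_m, collapse = ", ")), "metrics")
  }
  X0 <- as.matrix(data[metrics])
  ctr <- colMeans(X0); scl <- apply(X0, 2, sd)
  scl[scl < 1e-12] <- 1
  X <- cbind(1, sweep(sweep(X0, 2, ctr), 2, scl, "/"))
  res <- irls_logistic(X, y, ridge = 0, max_iter = max_iter)
  mu_hat <- 1 / (1 + exp(-as.numeric(X %*% res$beta)))
  separation <- !res$converged || max(abs(res$beta)) > 1e3 ||
    (all(mu_hat[y == 1] > 1 - 1e-6) && all(mu_hat[y == 0] < 1e-6))
  if (separation) {
    warn("complete or quasi-separation detected; ridge-stabilized fit used")
    res <- irls_logistic(X, y, ridge = max(ridge, 1e-4), max_iter = max_iter)
  }
  structure(list(coefficients = res$beta, metrics = metrics,
                 center = ctr, scale = scl,
                 converged = res$converged, separation = separation,
                 log_lik = res$log_lik, n = length(y)),
            class = "tf_classifier")
}

# plain Newton/IRLS for binomial-logit with optional ridge on all terms
irls_logistic <- function(X, y, ridge = 0, max_iter = 50, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X, w * X) + diag(ridge, p)
    beta_new <- tryCatch(solve(A, crossprod(X, w * z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta <- as.numeric(beta_new)
    eta <- as.numeric(X %*% beta)
    ll <- sum(y * eta - log1p(exp(eta))) - ridge / 2 * sum(beta^2)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(beta = beta, converged = converged, log_lik = ll_old,
       log_lik_trace = ll_trace)
}

#' Predict win probability
#' @param object a `tf_classifier`.
#' @param newdata data frame containing the metric columns.
#' @param ... unused.
#' @return numeric vector of win probabilities in (0, 1).
#' @export
predict.tf_classifier <- function(object, newdata, ...) {
  X0 <- as.matrix(as_tibble(newdata)[object$metrics])
  X <- cbind(1, sweep(sweep(X0, 2, object$center), 2, object$scale, "/"))
  eta <- as.numeric(X %*% object$coefficients)
  1 / (1 + exp(-eta))
}

#' Leave-one-session-out accuracy of the outcome classifier
#'
#' Session-level hold-out: each session is predicted by a classifier
#' fitted on all other sessions, avoiding window-level leakage.
#'
#' @inheritParams fit_outcome_classifier
#' @return accuracy in `[0, 1]`.
#' @export
loso_accuracy <- function(data, metrics = c("tcr", "cpr", "ssi", "icc")) {
  data <- as_tibble(data)
  n <- nrow(data)
  correct <- vapply(seq_len(n), function(i) {
    fit <- suppressWarnings(
      fit_outcome_classifier(data[-i, ], metrics = metrics))
    p <- predict(fit, data[i, ])
    (p >= 0.5) == (data$outcome[i] == "win")
  }, logical(1))
  mean(correct)
}

#' Change-point detection on an indicator series
#'
#' Binary segmentation for mean shifts: the split maximizing the reduction
#' in residual sum of squares is accepted when the gain exceeds
#' `penalty * sigma^2` (default penalty `3 * log(n)`, a BIC-style cost for
#' the two extra parameters of a segment boundary); accepted segments are
#' split recursively. `sigma^2` is estimated robustly from first
#' differences, so large level shifts do not inflate it.
#'
#' @param x numeric series (>= 20 samples).
#' @param penalty positive penalty multiplier; `NULL` for the default.
#' @param min_seg minimum segment length.
#' @return list of class `tf_changepoints`: `change_indices` (last index of
#'   each left segment, sorted), `penalty`, `sigma2`, `gains`.
#' @export
detect_change_points <- function(x, penalty = NULL, min_seg = 5) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 20) tf_validation_error("need at least 20 samples", "x")
  penalty <- penalty %||% (3 * log(n))
  sigma2 <- (median(abs(diff(x))) / (0.6744898 * sqrt(2)))^2
  sigma2 <- max(sigma2, 1e-24)
  found <- integer(0)
  gains <- numeric(0)
  recurse <- function(lo, hi) {
    len <- hi - lo + 1
    if (len < 2 * min_seg) return(invisible())
    seg <- x[lo:hi]
    cs <- cumsum(seg); tot <- cs[len]
    ks <- min_seg:(len - min_seg)
    gain <- (cs[ks] - ks / len * tot)^2 * len / (ks * (len - ks))
    best <- which.max(gain)
    if (gain[best] > penalty * sigma2) {
      k <- ks[best]
      found <<- c(found, lo + k - 1)
      gains <<- c(gains, gain[best])
      recurse(lo, lo + k - 1)
      recurse(lo + k, hi)
    }
    invisible()
  }
  recurse(1, n)
  structure(list(change_indices = sort(found), penalty = penalty,
                 sigma2 = sigma2, gains = gains[order(found)]),
            class = "tf_changepoints")
}

#' Rule-based early warning on indicator series
#'
#' Evaluates configurable predicates over indicator levels and short-lag
#' derivatives; a window where every rule holds raises one alert. The
#' default rule set mirrors the observation that rapid rises in spatial
#' synchronization together with elevated temporal coordination anticipate
#' successful interventions.
#'
#' @param indicators a `tf_indicators`.
#' @param rules list of rules, each
#'   `list(indicator =, type = "level"|"delta", threshold =, direction = ">"|"<")`.
#'   `delta` compares the change from the previous window. Empty list gives
#'   no alerts.
#' @return tibble of class `tf_alerts`: `t` (window centre) and the values
#'   of the rule indicators at the alert.
#' @export
early_warning <- function(indicators,
                          rules = list(
                            list(indicator = "ssi", type = "delta",
                                 threshold = 0.1, direction = ">"),
                            list(indicator = "tcr", type = "level",
                                 threshold = 0.5, direction = ">"))) {
  ind <- as_tibble(indicators)
  if (length(rules) == 0) {
    return(structure(tibble(t = numeric()),
                     class = c("tf_alerts", class(tibble()))))
  }
  ok <- rep(TRUE, nrow(ind))
  for (r in rules) {
    if (!r$indicator %in% names(ind)) {
      tf_validation_error(paste0("unknown indicator in rule: ", r$indicator),
                          "rules")
    }
    v <- ind[[r$indicator]]
    if (identical(r$type, "delta")) v <- c(NA, diff(v))
    hit <- if (identical(r$direction %||% ">", ">")) v > r$threshold else
      v < r$threshold
    ok <- ok & !is.na(hit) & hit
  }
  cols <- unique(vapply(rules, `[[`, character(1), "indicator"))
  structure(bind_cols(tibble(t = ind$t[ok]), ind[ok, cols, drop = FALSE]),
            class = c("tf_alerts", class(tibble())))
}
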