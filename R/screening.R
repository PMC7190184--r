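#' Screened-set size d = floor(multiplier * n / log(n))
#'
#' Natural logarithm (the Fan & Lv convention); the bracket is a floor. The
#' simulation pipeline uses multiplier 2; exposure-path screening in data
#' applications commonly uses 3.
#'
#' @param n sample size (>= 3).
#' @param multiplier positive scaling of the n/log(n) budget.
#' @return Integer screened-set size (capped at p by the callers).
#' @export
screen_size <- function(n, multiplier = 2) {
  if (n < 3) stop("n must be at least 3")
  if (multiplier <= 0) stop("multiplier must be positive")
  as.integer(floor(multiplier * n / log(n)))
}

screen_result <- function(utilities, d, mode) {
  p <- length(utilities)
  d <- min(d, p)
  # descending utility, ties broken by lower column index
  ord <- order(-utilities, seq_len(p))
  structure(list(retained = ord[seq_len(d)], d = d,
                 utilities = utilities, mode = mode),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("SIS (", x$mode, " path): retained ", length(x$retained), " of ",
      length(x$utilities), " mediators\n", sep = "")
  invisible(x)
}

#' Sure independence screening on the outcome path
#'
#' Ranks every mediator by the standardized coefficient
#' \eqn{|\hat\beta_k| / \mathrm{SE}(\hat\beta_k)} from the marginal Cox model
#' with design (X, Z, M_k) and retains the top `d`. Adjusting for exposure
#' and covariates in the marginal fit keeps the ranking from favoring
#' mediators that merely track the exposure. A mediator whose marginal fit
#' fails (for example a constant column) gets utility 0 with a warning,
#' never a crash.
#'
#' @param data a [survival_dataset()].
#' @param d number of mediators to retain (capped at p).
#' @return A `screen_result`: `retained` (indices ordered by descending
#'   utility), `d`, `utilities`, `mode`.
#' @export
sis_outcome <- function(data, d) {
  stopifnot(d >= 1)
  pr <- cox_prep(data$time)
  Xf <- design_matrix(data)[pr$ord, , drop = FALSE]
  res <- cox_sis_cpp(Xf, data$mediators[pr$ord, , drop = FALSE],
                     data$event[pr$ord], pr$first)
  if (res$n_failed > 0)
    warning(res$n_failed, " marginal fit(s) failed; utilities set to 0")
  out <- screen_result(drop(res$utility), d, "outcome_path")
  out$coef <- drop(res$coef)
  out$se <- drop(res$se)
  out
}

#' Sure independence screening on the exposure path
#'
#' Ranks every mediator by \eqn{|\hat\alpha_k| / \mathrm{SE}(\hat\alpha_k)}
#' from the least-squares mediator model M_k ~ 1 + X + Z and retains the top
#' `d`. Used when the exposure-to-mediator signal is the limiting factor
#' (the data-application mode).
#'
#' @inheritParams sis_outcome
#' @return A `screen_result` (mode `"exposure_path"`), with per-mediator
#'   `coef`, `se` and `p_alpha` attached.
#' @export
sis_exposure <- function(data, d) {
  stopifnot(d >= 1)
  if (sd(data$exposure) < 1e-12) stop("degenerate exposure")
  fits <- ols_mediator_all(data)
  util <- abs(fits$alpha) / fits$se_alpha
  util[!is.finite(util)] <- 0
  out <- screen_result(util, d, "exposure_path")
  out$coef <- fits$alpha
  out$se <- fits$se_alpha
  out$p_alpha <- fits$p_alpha
  out
}

# vectorized OLS of every mediator on (1, X, Z): exposure coefficient, SE,
# residual variance and two-sided t-test p-value
ols_mediator_all <- function(data, columns = NULL) {
  M <- if (is.null(columns)) data$mediators
       else data$mediators[, columns, drop = FALSE]
  D <- cbind(1, data$exposure, data$covariates)
  n <- data$n
  qd <- ncol(D)
  if (qr(D)$rank < qd) stop("rank-deficient mediator-model design")
  qrD <- qr(D)
  coefs <- qr.coef(qrD, M)
  res <- M - D %*% coefs
  dfree <- n - qd
  sigma2 <- colSums(res^2) / dfree
  xtxinv <- chol2inv(qr.R(qrD))
  se_alpha <- sqrt(sigma2 * xtxinv[2, 2])
  alpha <- coefs[2, ]
  tstat <- alpha / se_alpha
  list(alpha = unname(alpha), se_alpha = unname(se_alpha),
       intercept = unname(coefs[1, ]),
       vartheta = if (qd > 2) unname(coefs[-(1:2), , drop = FALSE])
                  else matrix(0, 0, ncol(M)),
       residual_variance = unname(sigma2),
       p_alpha = unname(2 * pt(-abs(tstat), dfree)), df = dfree)
}
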