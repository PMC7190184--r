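#' Cox log partial likelihood
#'
#' Evaluates \eqn{\sum_i \delta_i \{P_i'Q - \log \sum_{l \in R_i}
#' \exp(P_l'Q)\}} with risk sets \eqn{R_i = \{l : T_l \ge T_i\}} (Breslow
#' handling of ties) over the selected design columns.
#'
#' @param data a [survival_dataset()].
#' @param coefs coefficient vector matching the selected columns.
#' @param mediators mediator column indices to include.
#' @param include_exposure,include_covariates include the exposure / the
#'   baseline covariates in the design.
#' @return The log partial likelihood (scalar).
#' @export
log_partial_likelihood <- function(data, coefs, mediators = integer(0),
                                   include_exposure = TRUE,
                                   include_covariates = TRUE) {
  X <- design_matrix(data, mediators, include_exposure, include_covariates)
  if (length(coefs) != ncol(X))
    stop("coefs length must match the selected design columns")
  if (sum(data$event) == 0) stop("no events")
  eta <- if (ncol(X)) drop(X %*% coefs) else rep(0, data$n)
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  pr <- cox_prep(data$time)
  cox_loglik_cpp(eta[pr$ord], data$event[pr$ord], pr$first)
}

#' Fit an unpenalized Cox proportional hazards model
#'
#' Newton-Raphson maximization of the Breslow partial likelihood with step
#' halving; standard errors come from the inverse observed information at the
#' optimum. The exposure and covariates are included by default (they are
#' confounder adjustments, never selection targets).
#'
#' @inheritParams log_partial_likelihood
#' @param tol convergence tolerance on the relative change in log partial
#'   likelihood.
#' @param max_iter iteration cap.
#' @return A `cox_fit` object: `coefficients`, `standard_errors`, `cov`,
#'   `log_partial_likelihood`, `score`, `converged`, `n_iterations`,
#'   `n`, `n_events`, `column_names`, plus the column bookkeeping needed by
#'   the inference layer.
#' @export
fit_cox <- function(data, mediators = integer(0), include_exposure = TRUE,
                    include_covariates = TRUE, tol = 1e-9, max_iter = 100) {
  X <- design_matrix(data, mediators, include_exposure, include_covariates)
  d <- ncol(X)
  if (d == 0) stop("empty design")
  nev <- sum(data$event)
  if (nev == 0) stop("no events")
  if (d >= nev)
    warning("more design columns than events; estimates unreliable")
  sds <- apply(X, 2, sd)
  if (any(sds < 1e-12)) stop("singular information (constant column)")
  if (qr(X)$rank < d) stop("singular information")
  pr <- cox_prep(data$time)
  ft <- cox_newton_cpp(X[pr$ord, , drop = FALSE], data$event[pr$ord],
                       pr$first, rep(0, d), max_iter, tol)
  if (ft$singular) stop("singular information")
  cov <- tryCatch(solve(ft$information),
                  error = function(e) stop("singular information"))
  converged <- isTRUE(ft$converged)
  if (max(abs(ft$coefficients)) > 30) {
    warning("monotone likelihood suspected; fit did not stabilize")
    converged <- FALSE
  }
  se <- sqrt(pmax(diag(cov), 0))
  coefs <- drop(ft$coefficients)
  names(coefs) <- names(se) <- colnames(X)
  structure(
    list(coefficients = coefs, standard_errors = se, cov = cov,
         log_partial_likelihood = ft$loglik, score = drop(ft$score),
         converged = converged, n_iterations = ft$iterations,
         n = data$n, n_events = nev, column_names = colnames(X),
         mediators = mediators, include_exposure = include_exposure,
         include_covariates = include_covariates),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox model fit (", x$n, "subjects,", x$n_events, "events )\n")
  z <- x$coefficients / x$standard_errors
  tab <- data.frame(coef = x$coefficients, se = x$standard_errors, z = z,
                    p = 2 * pnorm(-abs(z)))
  print(tab, digits = 4)
  cat("log partial likelihood:", format(x$log_partial_likelihood),
      "| converged:", x$converged, "\n")
  invisible(x)
}

#' Breslow baseline cumulative hazard
#'
#' Step-function estimate \eqn{\hat\Lambda_0(t) = \sum_{t_j \le t} d_j /
#' \sum_{l \in R_j} \exp(\hat\eta_l)} with jumps only at event times.
#'
#' @param fit a converged [fit_cox()] result.
#' @param data the dataset the model was fitted on.
#' @return A right-continuous nondecreasing [stats::stepfun()].
#' @export
baseline_cumulative_hazard <- function(fit, data) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  X <- design_matrix(data, fit$mediators, fit$include_exposure,
                     fit$include_covariates)
  eta <- drop(X %*% fit$coefficients)
  theta <- exp(eta)
  ut <- sort(unique(data$time[data$event == 1]))
  if (!length(ut)) return(stats::stepfun(0, c(0, 0)))
  jumps <- vapply(ut, function(t0) {
    sum(data$event == 1 & data$time == t0) / sum(theta[data$time >= t0])
  }, numeric(1))
  stats::stepfun(ut, c(0, cumsum(jumps)))
}
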