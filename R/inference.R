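#' Fit the linear mediator model for one mediator
#'
#' Ordinary least squares of \eqn{M_k} on (1, X, Z):
#' \eqn{M_k = c_k + \alpha_k X + \vartheta^T Z + e_k}. The residual variance
#' is RSS / (n - q - 2) and the exposure-coefficient SE comes from the usual
#' normal-theory estimate.
#'
#' @param data a [survival_dataset()].
#' @param k mediator column index.
#' @return A `mediator_fit`: `alpha_hat`, `se_alpha`, `intercept_hat`,
#'   `vartheta_hat`, `residual_variance`, `p_alpha`, `df`, `mediator`.
#' @export
fit_mediator_model <- function(data, k) {
  if (sd(data$exposure) < 1e-12) stop("degenerate exposure")
  f <- ols_mediator_all(data, columns = k)
  structure(list(alpha_hat = f$alpha[1], se_alpha = f$se_alpha[1],
                 intercept_hat = f$intercept[1],
                 vartheta_hat = drop(f$vartheta[, 1]),
                 residual_variance = f$residual_variance[1],
                 p_alpha = f$p_alpha[1], df = f$df, mediator = k),
            class = "mediator_fit")
}

#' Sobel test of an indirect-effect product
#'
#' Delta-method Wald test of \eqn{H_0: \alpha_k \beta_k = 0} with
#' \eqn{\hat\sigma_{\alpha\beta} = \sqrt{\hat\alpha^2 se_\beta^2 +
#' \hat\beta^2 se_\alpha^2}}, \eqn{z = |\hat\alpha\hat\beta| /
#' \hat\sigma_{\alpha\beta}}, and \eqn{p = 2\{1 - \Phi(z)\}}. Degenerate
#' case: when both the product and its SE are zero, p := 1.
#'
#' @param alpha_hat,se_alpha exposure-to-mediator estimate and SE.
#' @param beta_hat,se_beta mediator-to-outcome estimate and SE.
#' @return List with `sobel_se`, `z`, `p_raw`.
#' @export
sobel_test <- function(alpha_hat, se_alpha, beta_hat, se_beta) {
  if (any(se_alpha < 0) || any(se_beta < 0)) stop("negative standard error")
  sobel_se <- sqrt(alpha_hat^2 * se_beta^2 + beta_hat^2 * se_alpha^2)
  z <- ifelse(sobel_se > 0, abs(alpha_hat * beta_hat) / sobel_se,
              ifelse(alpha_hat * beta_hat == 0, 0, Inf))
  p_raw <- 2 * (1 - pnorm(z))
  list(sobel_se = sobel_se, z = z, p_raw = p_raw)
}

#' Joint significance (causal steps / MaxP) test
#'
#' Declares mediation only when both path coefficients are individually
#' significant; the p-value is the maximum of the two path p-values. The
#' test provides no effect estimate.
#'
#' @param p_alpha,p_beta path-specific p-values in \[0, 1\].
#' @return The raw joint p-value.
#' @export
joint_test <- function(p_alpha, p_beta) {
  stopifnot(all(p_alpha >= 0 & p_alpha <= 1),
            all(p_beta >= 0 & p_beta <= 1))
  pmax(p_alpha, p_beta)
}

#' Bonferroni adjustment
#'
#' \eqn{\min(p \cdot m, 1)} with m the number of tests (here the size of the
#' selected set S2).
#'
#' @param p_raw raw p-value(s).
#' @param m number of comparisons (>= 1).
#' @return Adjusted p-value(s).
#' @export
bonferroni_adjust <- function(p_raw, m) {
  stopifnot(m >= 1)
  pmin(p_raw * m, 1)
}

#' Decompose the exposure effect into direct and indirect components
#'
#' On the log hazard-ratio scale the direct effect of moving the exposure
#' from `x_from` to `x_to` is \eqn{(x^* - x)\hat\gamma}; each selected
#' mediator contributes an indirect effect
#' \eqn{(x^* - x)\hat\alpha_k\hat\beta_k}; the total effect is their sum.
#' Hazard-ratio-scale values are exponentials. CIs: normal on the log-HR
#' scale (refit SE for the direct effect, Sobel SE per mediator, summed
#' variances for the total, treating components as independent), then
#' exponentiated.
#'
#' @param refit the unpenalized Cox refit on (X, Z, S2) from
#'   [refit_unpenalized()].
#' @param mediator_fits list of [fit_mediator_model()] objects for the S2
#'   mediators, in the same order as they appear in `refit`.
#' @param x_from,x_to exposure contrast (default 0 to 1).
#' @param conf_level confidence level (default 0.95).
#' @return An `effect_decomposition`: log-HR-scale `direct_log_hr`,
#'   `indirect_log_hr` (named per mediator), `total_indirect_log_hr`,
#'   `total_log_hr`, a `table` with HR-scale estimates and CIs, and
#'   `sigma2_W_beta` \eqn{= \sum_k \hat\beta_k^2 \hat\sigma^2_{M_k}}.
#' @export
decompose_effects <- function(refit, mediator_fits, x_from = 0, x_to = 1,
                              conf_level = 0.95) {
  if (!isTRUE(refit$converged)) stop("refit did not converge")
  ctr <- x_to - x_from
  zq <- qnorm(1 - (1 - conf_level) / 2)
  gamma_hat <- unname(refit$coefficients["exposure"])
  gamma_se <- unname(refit$standard_errors["exposure"])
  meds <- refit$mediators
  stopifnot(length(mediator_fits) == length(meds))
  med_names <- if (length(meds)) utils::tail(refit$column_names,
                                             length(meds)) else character()
  beta_hat <- if (length(meds)) unname(refit$coefficients[med_names])
              else numeric()
  beta_se <- if (length(meds)) unname(refit$standard_errors[med_names])
             else numeric()
  alpha_hat <- vapply(mediator_fits, `[[`, numeric(1), "alpha_hat")
  alpha_se <- vapply(mediator_fits, `[[`, numeric(1), "se_alpha")
  sig2m <- vapply(mediator_fits, `[[`, numeric(1), "residual_variance")
  sob <- if (length(meds)) sobel_test(alpha_hat, alpha_se, beta_hat, beta_se)
         else list(sobel_se = numeric())

  direct <- ctr * gamma_hat
  indirect <- ctr * alpha_hat * beta_hat
  names(indirect) <- med_names
  total_ind <- sum(indirect)
  total <- direct + total_ind

  ci <- function(est, se) c(low = est - zq * se, high = est + zq * se)
  d_ci <- ci(direct, abs(ctr) * gamma_se)
  i_se <- abs(ctr) * sob$sobel_se
  t_se <- abs(ctr) * sqrt(gamma_se^2 + sum(sob$sobel_se^2))
  t_ci <- ci(total, t_se)

  rows <- data.frame(
    effect = c("direct", if (length(meds)) paste0("indirect:", med_names),
               "total_indirect", "total"),
    log_hr = c(direct, indirect, total_ind, total),
    hr = exp(c(direct, indirect, total_ind, total)),
    ci_low = exp(c(d_ci["low"], if (length(meds)) indirect - zq * i_se,
                   sum(indirect) - zq * abs(ctr) * sqrt(sum(sob$sobel_se^2)),
                   t_ci["low"])),
    ci_high = exp(c(d_ci["high"], if (length(meds)) indirect + zq * i_se,
                    sum(indirect) + zq * abs(ctr) * sqrt(sum(sob$sobel_se^2)),
                    t_ci["high"])),
    row.names = NULL)

  structure(list(x_from = x_from, x_to = x_to,
                 direct_log_hr = direct, indirect_log_hr = indirect,
                 total_indirect_log_hr = total_ind, total_log_hr = total,
                 table = rows, sigma2_W_beta = sum(beta_hat^2 * sig2m),
                 conf_level = conf_level),
            class = "effect_decomposition")
}

#' @export
print.effect_decomposition <- function(x, ...) {
  cat("Effect decomposition (exposure ", x$x_from, " -> ", x$x_to,
      "), hazard-ratio scale:\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' Approximate counterfactual log hazard
#'
#' Evaluates \eqn{\log\lambda(T(x, M_1(x^*), \ldots, M_p(x^*)); t \mid Z)
#' \approx \log\lambda_0(t) + \theta^T Z + \tfrac12\sigma^2_{W\beta} +
#' \sum_k \beta_k (c_k + \vartheta_k^T Z) + \gamma x +
#' (\sum_k \alpha_k \beta_k) x^*} with
#' \eqn{\sigma^2_{W\beta} = \sum_k \beta_k^2 \sigma^2_{M_k}}. Differences of
#' two evaluations reproduce the direct and indirect contrasts exactly: the
#' baseline, covariate and \eqn{\sigma^2_{W\beta}} terms cancel.
#'
#' @param params list with `gamma`, `theta` (length q), `beta`, `alpha`,
#'   `c` (mediator intercepts), `vartheta` (q x K matrix or length-q vector
#'   shared across mediators), `sigma2_M` (residual variances), and
#'   optionally `log_baseline` (default 0).
#' @param x exposure value the outcome is set to.
#' @param x_star exposure value the mediators are set to.
#' @param z covariate vector (length q).
#' @return Scalar approximate log hazard.
#' @export
counterfactual_log_hazard <- function(params, x, x_star, z = numeric()) {
  K <- length(params$beta)
  stopifnot(length(params$alpha) == K, length(params$c) == K,
            length(params$sigma2_M) == K)
  vt <- params$vartheta
  if (is.null(vt)) vt <- matrix(0, length(z), K)
  if (is.vector(vt)) vt <- matrix(vt, length(z), K)
  lb <- params$log_baseline %||% 0
  zterm <- if (length(z)) sum(params$theta * z) else 0
  medz <- if (K) sum(params$beta *
                     (params$c + if (length(z)) drop(crossprod(vt, z)) else 0))
          else 0
  lb + zterm + 0.5 * sum(params$beta^2 * params$sigma2_M) + medz +
    params$gamma * x + sum(params$alpha * params$beta) * x_star
}
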