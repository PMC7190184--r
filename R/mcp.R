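#' Minimax concave penalty and its derivative
#'
#' \eqn{P_\lambda(\beta) = \lambda|\beta| - \beta^2/(2a)} for
#' \eqn{|\beta| \le a\lambda} and \eqn{a\lambda^2/2} beyond; the derivative
#' in \eqn{|\beta|} is \eqn{(a\lambda - |\beta|)_+ / a}, signed by
#' \eqn{\mathrm{sign}(\beta)}. At the origin the slope equals \eqn{\lambda}
#' (lasso-like); beyond \eqn{a\lambda} the penalty is flat, so large
#' coefficients are left unshrunk.
#'
#' @param beta coefficient value(s).
#' @param lambda nonnegative regularization parameter.
#' @param a shape parameter, must exceed 1 (default 3).
#' @return List with vectors `penalty` and `derivative`.
#' @export
mcp_penalty <- function(beta, lambda, a = 3) {
  if (a <= 1) stop("a must exceed 1")
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  ab <- abs(beta)
  inner <- ab <= a * lambda
  penalty <- ifelse(inner, lambda * ab - beta^2 / (2 * a), a * lambda^2 / 2)
  derivative <- sign(beta) * pmax(a * lambda - ab, 0) / a
  derivative[beta == 0] <- lambda  # slope magnitude at the origin
  list(penalty = penalty, derivative = derivative)
}

#' One-dimensional penalized coordinate update
#'
#' Exact minimizer of the coordinate problem \eqn{q(b) = \tfrac{v}{2} b^2 -
#' u b + P_\lambda(|b|)} used inside the coordinate-descent solver, solved
#' by candidate enumeration over the pieces of the penalty (which stays
#' correct when \eqn{v \le 1/a} and the MCP middle piece is concave).
#'
#' @param u linear coefficient (weighted inner product of the column with
#'   the working residual, plus `v` times the current value).
#' @param v quadratic curvature (> 0).
#' @param lambda penalty level.
#' @param a MCP shape parameter.
#' @param kind `"mcp"` or `"lasso"`.
#' @return The minimizing coordinate value (vectorized over `u`).
#' @export
mcp_threshold <- function(u, v, lambda, a = 3, kind = c("mcp", "lasso")) {
  kind <- match.arg(kind)
  stopifnot(all(v > 0), all(lambda >= 0))
  k <- if (kind == "lasso") 1L else 0L
  vapply(seq_along(u),
         function(i) mcp_threshold_cpp(u[i], v[min(i, length(v))],
                                       lambda[min(i, length(lambda))], a, k),
         numeric(1))
}

#' Penalty and solver configuration for penalized Cox selection
#'
#' @param kind `"mcp"` (default) or `"lasso"`.
#' @param a MCP shape parameter (> 1, default 3).
#' @param lambda explicit decreasing grid, or `NULL` for an automatic
#'   log-spaced grid from \eqn{\lambda_{max}} (the smallest value zeroing all
#'   penalized coefficients) down to `lambda_min_ratio * lambda_max`.
#' @param nlambda grid length for the automatic grid (default 100).
#' @param lambda_min_ratio lower end of the automatic grid as a fraction of
#'   \eqn{\lambda_{max}}; default 0.05, or 0.01 when the penalized block is
#'   smaller than the sample size.
#' @param lambda_selection `"bic"` (default, deterministic) or `"cv"`.
#' @param n_folds folds for cross-validation (default 10).
#' @param tol coordinate-descent convergence tolerance on the maximum
#'   absolute coefficient change (default 1e-7).
#' @param max_iter cap on IRLS/coordinate-descent cycles per lambda.
#' @param standardize standardize penalized columns internally (default
#'   TRUE); coefficients are always returned on the original scale.
#' @param seed seed for the CV fold assignment.
#' @return A `penalty_config` list.
#' @export
penalty_config <- function(kind = c("mcp", "lasso"), a = 3, lambda = NULL,
                           nlambda = 100, lambda_min_ratio = NULL,
                           lambda_selection = c("bic", "cv"), n_folds = 10,
                           tol = 1e-7, max_iter = 2000, standardize = TRUE,
                           seed = 1L) {
  kind <- match.arg(kind)
  lambda_selection <- match.arg(lambda_selection)
  if (kind == "mcp" && a <= 1) stop("a must exceed 1")
  if (!is.null(lambda)) {
    lambda <- as.numeric(lambda)
    if (length(lambda) > 1 && any(diff(lambda) > 0))
      stop("lambda grid must be decreasing")
  }
  structure(list(kind = kind, a = a, lambda = lambda, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio,
                 lambda_selection = lambda_selection, n_folds = n_folds,
                 tol = tol, max_iter = max_iter, standardize = standardize,
                 seed = seed),
            class = "penalty_config")
}

# low-level path solver on an explicit design split; mediator columns are
# penalized, Xu columns never are
pen_path_solve <- function(time, event, Xu, Xp, config) {
  n <- length(time)
  pr <- cox_prep(time)
  dl <- event[pr$ord]
  Xu_s <- Xu[pr$ord, , drop = FALSE]
  Xp_s <- Xp[pr$ord, , drop = FALSE]
  ctr <- colMeans(Xp_s)
  scl <- rep(1, ncol(Xp_s))
  if (config$standardize && ncol(Xp_s)) {
    scl <- apply(Xp_s, 2, sd) * sqrt((n - 1) / n)
    scl[scl < 1e-12] <- 1
  }
  Xp_s <- sweep(sweep(Xp_s, 2, ctr, "-"), 2, scl, "/")
  if (ncol(Xu_s)) Xu_s <- sweep(Xu_s, 2, colMeans(Xu_s), "-")

  # warm start for the unpenalized block and the gradient needed for the
  # lambda_max of the automatic grid
  bu0 <- rep(0, ncol(Xu_s))
  if (ncol(Xu_s)) {
    f0 <- cox_newton_cpp(Xu_s, dl, pr$first, bu0, 100, 1e-9)
    if (!f0$singular) bu0 <- drop(f0$coefficients)
  }
  eta0 <- if (ncol(Xu_s)) drop(Xu_s %*% bu0) else rep(0, n)
  gr <- cox_gradient_cpp(eta0, dl, pr$first)
  lambda <- config$lambda
  if (is.null(lambda)) {
    lmax <- if (ncol(Xp_s)) max(abs(drop(crossprod(Xp_s, gr$g)))) / n else 1
    lmax <- max(lmax, 1e-6)
    ratio <- config$lambda_min_ratio %||%
      (if (ncol(Xp_s) < n) 0.01 else 0.05)
    lambda <- exp(seq(log(lmax), log(lmax * ratio),
                      length.out = config$nlambda))
  }
  kind <- if (config$kind == "lasso") 1L else 0L
  fit <- cox_pen_path_cpp(Xu_s, Xp_s, dl, pr$first, lambda,
                          config$a, kind, config$tol, config$max_iter,
                          bu0, rep(0, ncol(Xp_s)))
  beta_pen <- fit$beta_pen / scl  # back to the original mediator scale
  list(lambda = lambda, beta_unpen = fit$beta_unpen, beta_pen = beta_pen,
       beta_pen_std = fit$beta_pen, scales = scl,
       loglik = drop(fit$loglik), objective = drop(fit$objective),
       iterations = drop(fit$iterations),
       converged = drop(fit$converged) == 1, n_events = sum(event))
}

#' MCP- or lasso-penalized Cox regression over the screened set
#'
#' Solves \eqn{\max_\beta \{ n^{-1} l_n(\beta) - \sum_{k} P_\lambda(\beta_k)\}}
#' along a decreasing \eqn{\lambda} grid with warm starts. Each \eqn{\lambda}
#' is handled by iteratively reweighted least squares: a quadratic
#' approximation of the partial likelihood at the current coefficients,
#' coordinate descent with the exact MCP (or soft) thresholding operator on
#' the mediator columns, plain coordinate-Newton updates on the unpenalized
#' exposure and covariates, and step halving so the penalized objective never
#' decreases across outer iterations. Exposure and covariates are never
#' penalized.
#'
#' @param data a [survival_dataset()].
#' @param S1 mediator indices entering the penalized model (for example
#'   `screen_result$retained`); a `screen_result` is also accepted.
#' @param config a [penalty_config()].
#' @return A `hd_cox_path`: `lambda`, `beta_pen` (mediators x lambda, on the
#'   original scale), `beta_unpen`, `df` (nonzero penalized count),
#'   `loglik`, `objective`, `converged`, `S1`, plus bookkeeping.
#' @export
fit_penalized_cox <- function(data, S1, config = penalty_config()) {
  if (inherits(S1, "screen_result")) S1 <- S1$retained
  S1 <- sort(unique(as.integer(S1)))  # fixed ascending coordinate order
  if (length(S1) >= data$n)
    warning("penalized block is not smaller than n; results may be unstable")
  Xu <- design_matrix(data)
  Xp <- data$mediators[, S1, drop = FALSE]
  sol <- pen_path_solve(data$time, data$event, Xu, Xp, config)
  rownames(sol$beta_pen) <- data$mediator_ids[S1]
  rownames(sol$beta_unpen) <- colnames(Xu)
  structure(c(sol,
              list(S1 = S1, df = colSums(sol$beta_pen != 0),
                   n_unpen = ncol(Xu), n = data$n, config = config)),
            class = "hd_cox_path")
}

#' @export
print.hd_cox_path <- function(x, ...) {
  cat("Penalized Cox path (", x$config$kind, "): ", length(x$lambda),
      " lambda values, ", length(x$S1), " penalized mediators, ",
      x$n_unpen, " unpenalized columns\n", sep = "")
  cat("active-set sizes:", paste(range(x$df), collapse = " .. "), "\n")
  invisible(x)
}

#' Choose lambda along a penalized Cox path
#'
#' BIC mode (default) minimizes \eqn{-2 l_n(\hat\beta_\lambda) +
#' \log(n_{events}) \cdot df_\lambda} where \eqn{df_\lambda} counts nonzero
#' penalized coefficients plus the unpenalized columns. CV mode maximizes the
#' Verweij-Van Houwelingen cross-validated partial likelihood with folds
#' stratified by event status.
#'
#' @param path a [fit_penalized_cox()] result.
#' @param data the dataset the path was fitted on.
#' @param config the [penalty_config()] (supplies the CV settings).
#' @return List with `lambda`, `index`, `criterion` (per-lambda values) and
#'   `method`.
#' @export
select_lambda <- function(path, data, config = path$config) {
  stopifnot(length(path$lambda) >= 1)
  if (config$lambda_selection == "bic") {
    df <- path$df + path$n_unpen
    crit <- -2 * path$loglik + log(path$n_events) * df
    idx <- which.min(crit)
    return(list(lambda = path$lambda[idx], index = idx, criterion = crit,
                method = "bic"))
  }
  # cross-validated partial likelihood, folds stratified by event status
  set.seed(config$seed)
  fold <- integer(data$n)
  for (ev in c(0, 1)) {
    idx <- which(data$event == ev)
    fold[idx] <- sample(rep_len(seq_len(config$n_folds), length(idx)))
  }
  Xu <- design_matrix(data)
  Xp <- data$mediators[, path$S1, drop = FALSE]
  cfg <- config
  cfg$lambda <- path$lambda
  cvl <- rep(0, length(path$lambda))
  pr_all <- cox_prep(data$time)
  for (f in seq_len(config$n_folds)) {
    tr <- fold != f
    sol <- pen_path_solve(data$time[tr], data$event[tr],
                          Xu[tr, , drop = FALSE], Xp[tr, , drop = FALSE], cfg)
    pr_tr <- cox_prep(data$time[tr])
    for (li in seq_along(path$lambda)) {
      eta_all <- drop(Xu %*% sol$beta_unpen[, li]) +
        drop(Xp %*% sol$beta_pen[, li])
      ll_all <- cox_loglik_cpp(eta_all[pr_all$ord], data$event[pr_all$ord],
                               pr_all$first)
      ll_tr <- cox_loglik_cpp(eta_all[tr][pr_tr$ord],
                              data$event[tr][pr_tr$ord], pr_tr$first)
      cvl[li] <- cvl[li] + (ll_all - ll_tr)
    }
  }
  idx <- which.max(cvl)
  list(lambda = path$lambda[idx], index = idx, criterion = cvl,
       method = "cv")
}

#' Unpenalized refit on the selected mediators
#'
#' Fits the Cox model on (X, Z, S2) without penalty; the refit coefficients
#' and standard errors feed the Sobel test and the effect decomposition
#' (penalized estimates are shrunk and carry no defined SE).
#'
#' @param data a [survival_dataset()].
#' @param S2 mediator indices with nonzero penalized coefficients.
#' @return A [fit_cox()] object.
#' @export
refit_unpenalized <- function(data, S2) {
  S2 <- as.integer(S2)
  if (length(S2) + data$q + 1 >= sum(data$event))
    warning("selected model is large relative to the number of events")
  fit_cox(data, mediators = S2)
}

#' Penalized Cox objective value
#'
#' Evaluates \eqn{n^{-1} l_n(\beta) - \sum_k P_\lambda(\beta_k)} for given
#' coefficients (penalty applied to the mediator block only), the quantity
#' the path solver maximizes per lambda. Coefficients are interpreted on the
#' same (original) scale the solver reports when `standardize = FALSE`; with
#' standardization the penalty applies to the standardized magnitudes via
#' `scales`.
#'
#' @param data a [survival_dataset()].
#' @param S1 mediator indices of the penalized block.
#' @param beta_unpen coefficients for (exposure, covariates).
#' @param beta_pen coefficients for the `S1` mediators (original scale).
#' @param lambda,a,kind penalty parameters.
#' @param scales per-column scales used internally (default 1).
#' @return Scalar objective value.
#' @export
penalized_cox_objective <- function(data, S1, beta_unpen, beta_pen, lambda,
                                    a = 3, kind = c("mcp", "lasso"),
                                    scales = rep(1, length(beta_pen))) {
  kind <- match.arg(kind)
  Xu <- design_matrix(data)
  Xp <- data$mediators[, S1, drop = FALSE]
  eta <- drop(Xu %*% beta_unpen) + drop(Xp %*% beta_pen)
  pr <- cox_prep(data$time)
  ll <- cox_loglik_cpp(eta[pr$ord], data$event[pr$ord], pr$first)
  b <- beta_pen * scales
  pen <- if (kind == "lasso") sum(lambda * abs(b))
         else sum(mcp_penalty(b, lambda, a)$penalty)
  ll / data$n - pen
}
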