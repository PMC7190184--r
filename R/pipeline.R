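#' High-dimensional survival mediation analysis (screen, select, test,
#' decompose)
#'
#' Runs the full workflow on a dataset: sure independence screening down to
#' `d = floor(multiplier * n / log n)` candidates, MCP- (or lasso-)
#' penalized Cox selection of S2 over the screened set, an unpenalized Cox
#' refit on (X, Z, S2), per-mediator linear mediator models, Sobel and joint
#' significance tests with Bonferroni adjustment over |S2|, and the
#' direct/indirect effect decomposition on the log hazard-ratio scale.
#'
#' @param data a [survival_dataset()].
#' @param screen_mode `"outcome"` (rank by the marginal Cox association,
#'   the simulation-study mode) or `"exposure"` (rank by the
#'   exposure-to-mediator association, useful when that path is the limiting
#'   signal).
#' @param screen_multiplier multiplier in the screened-set size (default 2).
#' @param penalty a [penalty_config()].
#' @param alpha_level significance level applied to the Bonferroni-adjusted
#'   p-values (default 0.05).
#' @param contrast exposure contrast `c(x_from, x_to)` for the decomposition.
#' @param verbose emit one progress line per stage to stderr.
#' @return An `hdms_mediation` object: `screen`, `path`, `lambda`,
#'   `S2` (mediator indices), `refit`, `mediator_fits`, `results` (one row
#'   per S2 mediator with estimates, Sobel/joint raw and adjusted p-values,
#'   HR-scale indirect effect and CI), `significant_sobel`,
#'   `significant_joint` (indices at `alpha_level`), `decomposition`,
#'   `alpha_level`.
#' @export
hdms_mediate <- function(data, screen_mode = c("outcome", "exposure"),
                         screen_multiplier = 2, penalty = penalty_config(),
                         alpha_level = 0.05, contrast = c(0, 1),
                         verbose = FALSE) {
  screen_mode <- match.arg(screen_mode)
  say <- function(...) if (verbose) message("[hdmedsurv] ", ...)
  d <- min(screen_size(data$n, screen_multiplier), data$p)
  scr <- if (screen_mode == "outcome") sis_outcome(data, d)
         else sis_exposure(data, d)
  say("screen: retained |S1| = ", length(scr$retained), " of p = ", data$p)

  path <- fit_penalized_cox(data, scr$retained, penalty)
  sel <- select_lambda(path, data, penalty)
  S2 <- path$S1[path$beta_pen[, sel$index] != 0]
  say("select: lambda = ", signif(sel$lambda, 4), ", |S2| = ", length(S2))

  refit <- refit_unpenalized(data, S2)
  mediator_fits <- lapply(S2, function(k) fit_mediator_model(data, k))
  results <- mediation_results_table(data, refit, mediator_fits, S2,
                                     alpha_level)
  sig_sobel <- S2[results$p_sobel_adj < alpha_level]
  sig_joint <- S2[results$p_joint_adj < alpha_level]
  say("test: significant (Sobel) = ", length(sig_sobel),
      ", (joint) = ", length(sig_joint))
  decomp <- decompose_effects(refit, mediator_fits,
                              x_from = contrast[1], x_to = contrast[2])
  structure(list(screen = scr, path = path, lambda = sel$lambda,
                 lambda_index = sel$index, S2 = S2, refit = refit,
                 mediator_fits = mediator_fits, results = results,
                 significant_sobel = sig_sobel,
                 significant_joint = sig_joint,
                 decomposition = decomp, alpha_level = alpha_level,
                 contrast = contrast),
            class = "hdms_mediation")
}

# per-mediator results table shared by the pipeline and the baselines
mediation_results_table <- function(data, refit, mediator_fits, S2,
                                    alpha_level, m = length(S2),
                                    zcrit = qnorm(0.975)) {
  if (!length(S2)) {
    return(data.frame(mediator = integer(), mediator_id = character(),
                      alpha_hat = numeric(), se_alpha = numeric(),
                      beta_hat = numeric(), se_beta = numeric(),
                      indirect_log_hr = numeric(), sobel_se = numeric(),
                      p_sobel_raw = numeric(), p_sobel_adj = numeric(),
                      p_joint_raw = numeric(), p_joint_adj = numeric(),
                      hr_indirect = numeric(), hr_ci_low = numeric(),
                      hr_ci_high = numeric(), significant = logical()))
  }
  med_names <- utils::tail(refit$column_names, length(S2))
  beta_hat <- unname(refit$coefficients[med_names])
  beta_se <- unname(refit$standard_errors[med_names])
  p_beta <- 2 * pnorm(-abs(beta_hat / beta_se))
  alpha_hat <- vapply(mediator_fits, `[[`, numeric(1), "alpha_hat")
  alpha_se <- vapply(mediator_fits, `[[`, numeric(1), "se_alpha")
  p_alpha <- vapply(mediator_fits, `[[`, numeric(1), "p_alpha")
  sob <- sobel_test(alpha_hat, alpha_se, beta_hat, beta_se)
  p_joint <- joint_test(p_alpha, p_beta)
  est <- alpha_hat * beta_hat
  data.frame(
    mediator = S2, mediator_id = data$mediator_ids[S2],
    alpha_hat = alpha_hat, se_alpha = alpha_se,
    beta_hat = beta_hat, se_beta = beta_se,
    indirect_log_hr = est, sobel_se = sob$sobel_se,
    p_sobel_raw = sob$p_raw,
    p_sobel_adj = bonferroni_adjust(sob$p_raw, m),
    p_joint_raw = p_joint,
    p_joint_adj = bonferroni_adjust(p_joint, m),
    hr_indirect = exp(est),
    hr_ci_low = exp(est - zcrit * sob$sobel_se),
    hr_ci_high = exp(est + zcrit * sob$sobel_se),
    significant = bonferroni_adjust(sob$p_raw, m) < alpha_level,
    row.names = NULL)
}

#' @export
print.hdms_mediation <- function(x, ...) {
  cat("High-dimensional survival mediation analysis\n")
  cat("  screened |S1| =", length(x$screen$retained),
      "| selected |S2| =", length(x$S2),
      "| significant (Sobel) =", length(x$significant_sobel),
      "| (joint) =", length(x$significant_joint), "\n")
  if (nrow(x$results)) print(x$results, digits = 4)
  else cat("  no mediators selected\n")
  print(x$decomposition)
  invisible(x)
}

#' Naive per-mediator comparator
#'
#' No screening or selection: for every mediator the marginal Cox model
#' (X, Z, M_k) supplies beta and the linear mediator model supplies alpha;
#' Sobel and joint tests are Bonferroni-adjusted over all p mediators.
#'
#' @inheritParams hdms_mediate
#' @return List with `results` (all p mediators), `significant_sobel`,
#'   `significant_joint`.
#' @export
run_baseline_naive <- function(data, alpha_level = 0.05) {
  pr <- cox_prep(data$time)
  Xf <- design_matrix(data)[pr$ord, , drop = FALSE]
  mc <- cox_sis_cpp(Xf, data$mediators[pr$ord, , drop = FALSE],
                    data$event[pr$ord], pr$first)
  ols <- ols_mediator_all(data)
  beta_hat <- drop(mc$coef)
  beta_se <- drop(mc$se)
  ok <- is.finite(beta_hat) & is.finite(beta_se) & beta_se > 0
  p_beta <- rep(1, data$p)
  p_beta[ok] <- 2 * pnorm(-abs(beta_hat[ok] / beta_se[ok]))
  bh <- ifelse(ok, beta_hat, 0)
  bs <- ifelse(ok, beta_se, 0)
  sob <- sobel_test(ols$alpha, ols$se_alpha, bh, bs)
  p_sobel_adj <- bonferroni_adjust(sob$p_raw, data$p)
  p_joint_adj <- bonferroni_adjust(joint_test(ols$p_alpha, p_beta), data$p)
  results <- data.frame(
    mediator = seq_len(data$p), mediator_id = data$mediator_ids,
    alpha_hat = ols$alpha, se_alpha = ols$se_alpha,
    beta_hat = bh, se_beta = bs,
    indirect_log_hr = ols$alpha * bh, sobel_se = sob$sobel_se,
    p_sobel_raw = sob$p_raw, p_sobel_adj = p_sobel_adj,
    p_joint_raw = joint_test(ols$p_alpha, p_beta),
    p_joint_adj = p_joint_adj, row.names = NULL)
  list(results = results,
       significant_sobel = which(p_sobel_adj < alpha_level),
       significant_joint = which(p_joint_adj < alpha_level))
}

#' One-step comparator: penalized selection without screening
#'
#' MCP- (or lasso-) penalized Cox on all p mediators, then the same refit,
#' tests and Bonferroni adjustment over |S2| as the full pipeline. With
#' p <= d this coincides with the full pipeline (screening is a no-op).
#'
#' @inheritParams hdms_mediate
#' @return An `hdms_mediation`-like list (no screening stage).
#' @export
run_baseline_onestep <- function(data, penalty = penalty_config(),
                                 alpha_level = 0.05) {
  path <- fit_penalized_cox(data, seq_len(data$p), penalty)
  sel <- select_lambda(path, data, penalty)
  S2 <- path$S1[path$beta_pen[, sel$index] != 0]
  refit <- refit_unpenalized(data, S2)
  mediator_fits <- lapply(S2, function(k) fit_mediator_model(data, k))
  results <- mediation_results_table(data, refit, mediator_fits, S2,
                                     alpha_level)
  list(path = path, lambda = sel$lambda, S2 = S2, refit = refit,
       results = results,
       significant_sobel = S2[results$p_sobel_adj < alpha_level],
       significant_joint = S2[results$p_joint_adj < alpha_level])
}

#' Run the pipeline from a configuration (file input or simulation)
#'
#' Thin orchestration wrapper used by the command-line interface: builds the
#' dataset (from delimited files or from a [simulation_config()]), runs
#' [hdms_mediate()], and optionally writes `results.tsv`,
#' `decomposition.json` and `run_metadata.json` into `out_dir`. Reruns with
#' the same configuration and seed are byte-identical.
#'
#' @param config a list with either `pheno`, `mediators` (+ column-name
#'   entries `time_col`, `event_col`, `exposure_col`, `covariate_cols`) or
#'   `simulation` (a [simulation_config()]); optional `screen_mode`,
#'   `screen_multiplier`, `penalty`, `alpha_level`, `contrast`, `seed`.
#' @param out_dir output directory or `NULL` for no files.
#' @param verbose forwarded to [hdms_mediate()].
#' @return The `hdms_mediation` object (invisibly when files are written).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  has_files <- !is.null(config$pheno)
  has_sim <- !is.null(config$simulation)
  if (has_files == has_sim)
    stop("config must contain exactly one of file inputs or a simulation block")
  if (has_files) {
    data <- read_survival_data(config$pheno, config$mediators,
                               time_col = config$time_col %||% "time",
                               event_col = config$event_col %||% "event",
                               exposure_col = config$exposure_col %||% "exposure",
                               covariate_cols = config$covariate_cols %||%
                                 character())
  } else {
    data <- simulate_dataset(config$simulation, seed = config$seed)
  }
  res <- hdms_mediate(
    data,
    screen_mode = config$screen_mode %||% "outcome",
    screen_multiplier = config$screen_multiplier %||% 2,
    penalty = config$penalty %||% penalty_config(),
    alpha_level = config$alpha_level %||% 0.05,
    contrast = config$contrast %||% c(0, 1),
    verbose = verbose)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(res$results, file.path(out_dir, "results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(contrast = res$contrast,
           sigma2_W_beta = res$decomposition$sigma2_W_beta,
           effects = res$decomposition$table),
      file.path(out_dir, "decomposition.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      list(package = "hdmedsurv",
           version = as.character(utils::packageVersion("hdmedsurv")),
           seed = config$seed,
           screen_mode = config$screen_mode %||% "outcome",
           screen_multiplier = config$screen_multiplier %||% 2,
           penalty_kind = (config$penalty %||% penalty_config())$kind,
           alpha_level = config$alpha_level %||% 0.05,
           n = data$n, p = data$p,
           S1_size = length(res$screen$retained),
           S2_size = length(res$S2),
           significant_sobel = length(res$significant_sobel),
           significant_joint = length(res$significant_joint)),
      file.path(out_dir, "run_metadata.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}
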