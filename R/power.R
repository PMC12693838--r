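#' Configuration for a Monte Carlo power run
#'
#' @param n_persons participants per simulated panel.
#' @param n_obs_per_person observations per participant.
#' @param true_between_r,true_within_r generating correlations, in (-1, 1).
#' @param icc_x,icc_y intraclass correlations of the two variables.
#' @param alpha two-sided significance level.
#' @param n_reps Monte Carlo replicates (>= 100).
#' @param test_level `"between"` or `"within"`: which correlation's Wald test
#'   is evaluated.
#' @param seed integer seed for the whole run.
#' @return list of class `power_config`.
#' @export
power_config <- function(n_persons = 100, n_obs_per_person = 9,
                         true_between_r = 0, true_within_r = 0,
                         icc_x = 0.5, icc_y = 0.5, alpha = 0.05,
                         n_reps = 1000, test_level = c("between", "within"),
                         seed = NULL) {
  test_level <- match.arg(test_level)
  cfg <- list(n_persons = as.integer(n_persons),
              n_obs_per_person = as.integer(n_obs_per_person),
              true_between_r = true_between_r, true_within_r = true_within_r,
              icc_x = icc_x, icc_y = icc_y, alpha = alpha,
              n_reps = as.integer(n_reps), test_level = test_level,
              seed = seed)
  class(cfg) <- "power_config"
  validate_power_config(cfg)
  cfg
}

validate_power_config <- function(cfg) {
  stopifnot(inherits(cfg, "power_config"))
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("power_config: alpha must lie in (0, 1)")
  if (cfg$n_reps < 100L) stop("power_config: n_reps must be >= 100")
  if (abs(cfg$true_between_r) >= 1 || abs(cfg$true_within_r) >= 1)
    stop("power_config: correlations must lie in (-1, 1)")
  invisible(cfg)
}

#' Monte Carlo power of a two-level correlation test
#'
#' For each replicate a panel is generated with [simulate_panel()] under the
#' configured two-level correlation structure, the target-level correlation
#' is estimated with [multilevel_corr()] (latent ML estimator), and rejection
#' at the configured alpha is recorded. Degenerate replicates (estimation
#' failure) are counted; more than 5% is an error. With both true
#' correlations at zero the returned proportion estimates the type-I error
#' of the test rather than its power.
#'
#' @param cfg a [power_config()].
#' @return list of class `power_result`: `power` (rejection proportion),
#'   `mc_se` (binomial Monte Carlo standard error
#'   \eqn{\sqrt{\hat p (1-\hat p)/n_{reps}}}), `n_degenerate`, and the
#'   config echo.
#' @export
#' @examples
#' estimate_power(power_config(n_persons = 50, true_between_r = 0.9,
#'                             n_reps = 100, seed = 1))
estimate_power <- function(cfg) {
  validate_power_config(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pcfg <- panel_config(
    cfg$n_persons, cfg$n_obs_per_person, variables = c("x", "y"),
    between_corr = matrix(c(1, cfg$true_between_r, cfg$true_between_r, 1), 2),
    within_corr = matrix(c(1, cfg$true_within_r, cfg$true_within_r, 1), 2),
    icc = c(cfg$icc_x, cfg$icc_y))
  reject <- logical(cfg$n_reps)
  degenerate <- 0L
  for (r in seq_len(cfg$n_reps)) {
    sim <- simulate_panel(pcfg)
    est <- tryCatch(multilevel_corr(sim$panel, "x", "y"),
                    error = function(e) NULL)
    pv <- if (is.null(est)) NA_real_ else est[[cfg$test_level]]$p
    if (is.null(pv) || is.na(pv)) {
      degenerate <- degenerate + 1L
      reject[r] <- NA
    } else reject[r] <- pv < cfg$alpha
  }
  if (degenerate > 0.05 * cfg$n_reps)
    stop("estimate_power: more than 5% of replicates were degenerate (",
         degenerate, "/", cfg$n_reps, ")")
  p_hat <- mean(reject, na.rm = TRUE)
  res <- list(power = p_hat,
              mc_se = sqrt(p_hat * (1 - p_hat) / sum(!is.na(reject))),
              n_degenerate = degenerate, config = cfg)
  class(res) <- "power_result"
  res
}

#' @export
print.power_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Power (%s-level r, n = %d x %d, true rB = %.2f, rW = %.2f, alpha = %.3f):\n",
              cfg$test_level, cfg$n_persons, cfg$n_obs_per_person,
              cfg$true_between_r, cfg$true_within_r, cfg$alpha))
  cat(sprintf("  %.3f (MC se %.4f, %d reps, %d degenerate)\n",
              x$power, x$mc_se, cfg$n_reps, x$n_degenerate))
  invisible(x)
}

#' Power across a sweep of configurations
#'
#' @param configs list of [power_config()] objects.
#' @return data.frame with one row per config: the design columns plus
#'   `power` and `mc_se`.
#' @export
power_curve <- function(configs) {
  stopifnot(length(configs) >= 1)
  rows <- lapply(configs, function(cfg) {
    res <- estimate_power(cfg)
    data.frame(n_persons = cfg$n_persons,
               n_obs_per_person = cfg$n_obs_per_person,
               true_between_r = cfg$true_between_r,
               true_within_r = cfg$true_within_r,
               icc_x = cfg$icc_x, icc_y = cfg$icc_y, alpha = cfg$alpha,
               n_reps = cfg$n_reps, test_level = cfg$test_level,
               power = res$power, mc_se = res$mc_se,
               n_degenerate = res$n_degenerate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
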