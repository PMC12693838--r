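#' Variance components and intraclass correlation
#'
#' One-way random-effects decomposition of a repeatedly measured variable
#' into between-person and within-person (day-level) variance, estimated by
#' restricted maximum likelihood with [lme4::lmer()]:
#' \deqn{ICC = Var(BP) / (Var(BP) + Var(WP)).}
#' An ICC near 1 means the measure barely fluctuates within a person (little
#' room for within-person associations); near 0, variance is almost entirely
#' day-to-day fluctuation. REML bounds the between component at zero, so no
#' negative estimate can occur.
#'
#' @param data data.frame with columns `person_id` and `variable`.
#' @param variable name of the measured column.
#' @return an object of class `var_decomp`: list with `var_bp`, `var_wp`,
#'   `icc`, `n_persons`, `n_obs`, `variable`.
#' @export
#' @examples
#' sim <- simulate_panel(panel_config(100, 8, variables = "x", icc = 0.68,
#'   between_corr = matrix(1), within_corr = matrix(1), seed = 3))
#' variance_components(sim$panel, "x")
variance_components <- function(data, variable) {
  d <- data[!is.na(data[[variable]]), c("person_id", variable)]
  names(d) <- c("person_id", "value")
  tab <- table(d$person_id)
  if (length(tab) < 2) stop("variance decomposition needs at least 2 persons")
  if (max(tab) < 2)
    stop("within-person variance inestimable: every person has a single observation")
  fit <- lme4::lmer(value ~ 1 + (1 | person_id), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_bp <- vc$vcov[vc$grp == "person_id"]
  var_wp <- vc$vcov[vc$grp == "Residual"]
  res <- list(variable = variable, var_bp = var_bp, var_wp = var_wp,
              icc = if (var_bp + var_wp > 0) var_bp / (var_bp + var_wp)
                    else NA_real_,
              n_persons = length(tab), n_obs = nrow(d))
  class(res) <- "var_decomp"
  res
}

#' @export
print.var_decomp <- function(x, ...) {
  cat(sprintf("Variance components for '%s': Var(BP) = %.4f, Var(WP) = %.4f, ICC = %.3f\n",
              x$variable, x$var_bp, x$var_wp, x$icc))
  cat(sprintf("  n = %d persons, %d observations\n", x$n_persons, x$n_obs))
  invisible(x)
}
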