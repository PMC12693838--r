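#' Configuration for the two-level panel generator
#'
#' Describes a person x day panel generated from the decomposition
#' \deqn{y_{ij} = \mu + b_i + w_{ij},}
#' where person effects \eqn{b_i} have covariance
#' \eqn{D_B^{1/2} R_B D_B^{1/2}} with \eqn{D_B = diag(icc)} and day effects
#' \eqn{w_{ij}} have covariance \eqn{D_W^{1/2} R_W D_W^{1/2}} with
#' \eqn{D_W = diag(1 - icc)}. Each variable therefore has unit total variance
#' and intraclass correlation `icc` before any covariate effects are added.
#' Age and gender enter the between level only: standardized age and centered
#' gender are added to the person effects with the configured weights.
#' Binary variables are person-level: the latent person value is thresholded
#' at the normal quantile matching the requested probability of a 1.
#'
#' @param n_persons number of persons.
#' @param n_obs_per_person observations (days or weeks) per person.
#' @param variables character vector of variable names.
#' @param between_corr,within_corr correlation matrices over `variables`
#'   (symmetric, positive semi-definite, unit diagonal).
#' @param icc per-variable intraclass correlations, in (0, 1); recycled.
#' @param binary_specs named list mapping a variable name to its probability
#'   of a 1; listed variables are emitted as person-constant 0/1 codes.
#' @param covariate_effects named list with optional numeric vectors `age`
#'   and `gender` of per-variable between-level weights (default all zero).
#' @param age_range uniform sampling range for age, years.
#' @param seed optional integer seed.
#' @return a list of class `panel_config`.
#' @export
panel_config <- function(n_persons, n_obs_per_person,
                         variables = c("x", "y"),
                         between_corr = diag(length(variables)),
                         within_corr = diag(length(variables)),
                         icc = 0.5, binary_specs = list(),
                         covariate_effects = list(), age_range = c(18, 65),
                         seed = NULL) {
  p <- length(variables)
  icc <- rep_len(icc, p)
  cfg <- list(n_persons = as.integer(n_persons),
              n_obs_per_person = as.integer(n_obs_per_person),
              variables = variables,
              between_corr = as.matrix(between_corr),
              within_corr = as.matrix(within_corr),
              icc = icc, binary_specs = binary_specs,
              covariate_effects = covariate_effects,
              age_range = age_range, seed = seed)
  class(cfg) <- "panel_config"
  validate_panel_config(cfg)
  cfg
}

validate_panel_config <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  p <- length(cfg$variables)
  if (cfg$n_persons < 1L) stop("panel_config: n_persons must be >= 1")
  if (cfg$n_obs_per_person < 1L) stop("panel_config: n_obs_per_person must be >= 1")
  if (any(cfg$icc <= 0 | cfg$icc >= 1)) stop("panel_config: icc must lie in (0, 1)")
  for (nm in c("between_corr", "within_corr")) {
    m <- cfg[[nm]]
    if (!all(dim(m) == c(p, p))) stop("panel_config: ", nm, " has wrong dimension")
    if (max(abs(m - t(m))) > 1e-8) stop("panel_config: ", nm, " is not symmetric")
    if (max(abs(diag(m) - 1)) > 1e-8) stop("panel_config: ", nm, " must have unit diagonal")
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("panel_config: ", nm, " is not positive semi-definite ",
           "(smallest eigenvalue = ", format(min(ev), digits = 4), ")")
  }
  bad <- setdiff(names(cfg$binary_specs), cfg$variables)
  if (length(bad)) stop("panel_config: binary_specs name unknown variables: ",
                        paste(bad, collapse = ", "))
  invisible(cfg)
}

covar_weights <- function(cfg, which) {
  w <- cfg$covariate_effects[[which]]
  if (is.null(w)) numeric(length(cfg$variables)) else rep_len(w, length(cfg$variables))
}

#' Simulate a two-level panel with known correlation structure
#'
#' @param cfg a [panel_config()].
#' @return a list of class `panel_sim` with elements `panel` (a wide
#'   data.frame: `person_id`, `day_index`, `age`, `gender`, one column per
#'   variable) and `truth` (the generating parameters plus the realized
#'   per-person latent means). When `n_obs_per_person == 1` the panel carries
#'   attribute `no_within_info = TRUE`: such a panel identifies no
#'   within-person quantity.
#' @export
#' @examples
#' sim <- simulate_panel(panel_config(50, 5, seed = 1))
#' head(sim$panel)
simulate_panel <- function(cfg) {
  validate_panel_config(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  p <- length(cfg$variables)
  np <- cfg$n_persons; no <- cfg$n_obs_per_person

  sd_b <- sqrt(cfg$icc); sd_w <- sqrt(1 - cfg$icc)
  sigma_b <- diag(sd_b, p) %*% cfg$between_corr %*% diag(sd_b, p)
  sigma_w <- diag(sd_w, p) %*% cfg$within_corr %*% diag(sd_w, p)

  age <- stats::runif(np, cfg$age_range[1], cfg$age_range[2])
  gender <- stats::rbinom(np, 1, 0.5)
  z_age <- (age - mean(cfg$age_range)) / (diff(cfg$age_range) / sqrt(12))
  g_cen <- gender - 0.5

  b <- MASS::mvrnorm(np, rep(0, p), sigma_b)
  b <- matrix(b, nrow = np)
  beta_age <- covar_weights(cfg, "age")
  beta_gender <- covar_weights(cfg, "gender")
  person_mean <- b + outer(z_age, beta_age) + outer(g_cen, beta_gender)

  w <- MASS::mvrnorm(np * no, rep(0, p), sigma_w)
  w <- matrix(w, nrow = np * no)
  idx <- rep(seq_len(np), each = no)
  values <- person_mean[idx, , drop = FALSE] + w
  colnames(values) <- cfg$variables

  ## binary variables: threshold the latent person-level value
  for (nm in names(cfg$binary_specs)) {
    pr <- cfg$binary_specs[[nm]]
    j <- match(nm, cfg$variables)
    lat_sd <- sqrt(cfg$icc[j] + beta_age[j]^2 + beta_gender[j]^2 / 4)
    thr <- stats::qnorm(1 - pr, 0, lat_sd)
    values[, j] <- as.numeric(person_mean[idx, j] > thr)
  }

  panel <- data.frame(person_id = sprintf("p%04d", idx),
                      day_index = rep(seq_len(no), np),
                      age = age[idx], gender = gender[idx])
  panel <- cbind(panel, as.data.frame(values))
  if (no == 1L) attr(panel, "no_within_info") <- TRUE

  truth <- list(config = cfg, person_means = person_mean,
                sigma_between = sigma_b, sigma_within = sigma_w,
                age = age, gender = gender)
  structure(list(panel = panel, truth = truth), class = "panel_sim")
}
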