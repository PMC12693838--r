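#' Average repeated within-day administrations
#'
#' Health items administered several times per day are reduced to their daily
#' average before entering correlational analyses, so that one observation
#' per person-day remains.
#'
#' @param long data.frame with columns `person_id`, `day_index`, `variable`,
#'   `value` (possibly several rows per person-day-variable).
#' @param variable variable name to average; default all.
#' @return data.frame with one row per person-day-variable: `person_id`,
#'   `day_index`, `variable`, `value` (the mean), `n_items` (contributing
#'   administrations).
#' @export
daily_average <- function(long, variable = NULL) {
  if (!is.null(variable)) long <- long[long$variable %in% variable, ]
  long <- long[!is.na(long$value), ]
  key <- interaction(long$person_id, long$day_index, long$variable, drop = TRUE)
  agg <- data.frame(
    person_id = tapply(long$person_id, key, `[`, 1),
    day_index = as.numeric(tapply(long$day_index, key, `[`, 1)),
    variable = tapply(long$variable, key, `[`, 1),
    value = as.numeric(tapply(long$value, key, mean)),
    n_items = as.integer(tapply(long$value, key, length)),
    stringsAsFactors = FALSE)
  rownames(agg) <- NULL
  agg[order(agg$person_id, agg$day_index, agg$variable), ]
}

#' Pair a health measure with HRV under a lag rule
#'
#' Joins the health measure reported on day *t* with the HRV record the lag
#' rule points at: the following night (`health_day_to_next_night`), the next
#' morning (`prior_day_to_morning`), or the same index (`same_day`). Both lag
#' rules implement the "measures from day *t*, HRV from the night/morning
#' after" convention; unmatched days are dropped and counted.
#'
#' @param panel wide data.frame with columns `person_id`, `day_index` and the
#'   two variables.
#' @param health,hrv column names of the health measure and the HRV metric.
#' @param lag one of `"same_day"`, `"health_day_to_next_night"`,
#'   `"prior_day_to_morning"`.
#' @return data.frame `person_id`, `day_index` (the health day), the health
#'   column and the lagged HRV column; attribute `n_dropped` counts unmatched
#'   health days.
#' @export
align_lag <- function(panel, health, hrv,
                      lag = c("same_day", "health_day_to_next_night",
                              "prior_day_to_morning")) {
  lag <- match.arg(lag)
  shift <- if (lag == "same_day") 0L else 1L
  h <- panel[!is.na(panel[[health]]), c("person_id", "day_index", health)]
  v <- panel[!is.na(panel[[hrv]]), c("person_id", "day_index", hrv)]
  v$day_index <- v$day_index - shift  # HRV of day t+shift keyed to health day t
  out <- merge(h, v, by = c("person_id", "day_index"))
  attr(out, "n_dropped") <- nrow(h) - nrow(out)
  out
}

#' Residualize person-level values on covariates
#'
#' Between-person correlations are adjusted for age and gender by partialling
#' the covariates out of the person-level component of each variable: with
#' person-constant covariates, ordinary least-squares residualization of the
#' observations removes only between-level variance and leaves the
#' within-person deviations untouched. Constant covariates are dropped with a
#' warning; persons with missing covariates are removed listwise.
#'
#' @param data data.frame of observations.
#' @param vars columns to residualize.
#' @param covariates covariate column names (person-constant).
#' @return `data` with `vars` replaced by residuals; attribute
#'   `adjusted_for` lists the covariates actually used.
#' @export
adjust_between <- function(data, vars, covariates) {
  keep <- covariates[vapply(covariates, function(cv) {
    v <- data[[cv]]
    ok <- length(unique(v[!is.na(v)])) > 1
    if (!ok) warning("covariate '", cv, "' is constant; dropped from adjustment",
                     call. = FALSE)
    ok
  }, TRUE)]
  cc <- stats::complete.cases(data[keep])
  if (!all(cc)) data <- data[cc, ]
  if (length(keep)) {
    X <- stats::model.matrix(
      stats::reformulate(keep), data = data)
    for (v in vars) {
      fit <- stats::lm.fit(X, data[[v]])
      data[[v]] <- fit$residuals
    }
  }
  attr(data, "adjusted_for") <- keep
  data
}

## ---- bivariate two-level ML machinery ------------------------------------

## per-cluster sufficient statistics for complete (x, y) pairs
cluster_stats <- function(x, y, id) {
  sp <- split(seq_along(x), id)
  ni <- lengths(sp)
  mx <- vapply(sp, function(k) mean(x[k]), 0)
  my <- vapply(sp, function(k) mean(y[k]), 0)
  sxx <- syy <- sxy <- numeric(length(sp))
  for (j in seq_along(sp)) {
    k <- sp[[j]]
    dx <- x[k] - mx[j]; dy <- y[k] - my[j]
    sxx[j] <- sum(dx * dx); syy[j] <- sum(dy * dy); sxy[j] <- sum(dx * dy)
  }
  list(ni = ni, mx = mx, my = my,
       Swx = sum(sxx), Swy = sum(syy), Swxy = sum(sxy),
       N = sum(ni), ncl = length(sp))
}

## negative profile log-likelihood over th = (log sbx, log sby, atanh rB,
## log swx, log swy, atanh rW); the two GLS means are profiled out
biv_nll <- function(th, st) {
  sbx <- exp(th[1]); sby <- exp(th[2]); rb <- tanh(th[3])
  swx <- exp(th[4]); swy <- exp(th[5]); rw <- tanh(th[6])
  SB11 <- sbx^2; SB22 <- sby^2; SB12 <- rb * sbx * sby
  SW11 <- swx^2; SW22 <- swy^2; SW12 <- rw * swx * swy
  detW <- SW11 * SW22 - SW12^2
  if (!is.finite(detW) || detW <= 0) return(1e10)
  iW11 <- SW22 / detW; iW22 <- SW11 / detW; iW12 <- -SW12 / detW
  llw <- -(st$N - st$ncl) / 2 * log(detW) -
    0.5 * (iW11 * st$Swx + iW22 * st$Swy + 2 * iW12 * st$Swxy)
  ## cluster means: Var = SW/n_i + SB
  V11 <- SW11 / st$ni + SB11; V22 <- SW22 / st$ni + SB22
  V12 <- SW12 / st$ni + SB12
  detV <- V11 * V22 - V12^2
  if (any(!is.finite(detV)) || any(detV <= 0)) return(1e10)
  iV11 <- V22 / detV; iV22 <- V11 / detV; iV12 <- -V12 / detV
  A11 <- sum(iV11); A22 <- sum(iV22); A12 <- sum(iV12)
  b1 <- sum(iV11 * st$mx + iV12 * st$my)
  b2 <- sum(iV12 * st$mx + iV22 * st$my)
  dA <- A11 * A22 - A12^2
  mu1 <- (A22 * b1 - A12 * b2) / dA
  mu2 <- (A11 * b2 - A12 * b1) / dA
  d1 <- st$mx - mu1; d2 <- st$my - mu2
  llb <- -0.5 * sum(log(detV)) -
    0.5 * sum(iV11 * d1 * d1 + 2 * iV12 * d1 * d2 + iV22 * d2 * d2)
  -(llw + llb)
}

biv_start <- function(st) {
  vw_x <- st$Swx / max(st$N - st$ncl, 1)
  vw_y <- st$Swy / max(st$N - st$ncl, 1)
  vb_x <- max(stats::var(st$mx) - vw_x / mean(st$ni), 0.05 * stats::var(st$mx),
              1e-6)
  vb_y <- max(stats::var(st$my) - vw_y / mean(st$ni), 0.05 * stats::var(st$my),
              1e-6)
  clamp <- function(r) atanh(max(min(r, 0.95), -0.95))
  rb0 <- suppressWarnings(stats::cor(st$mx, st$my))
  rw0 <- st$Swxy / sqrt(st$Swx * st$Swy)
  if (!is.finite(rb0)) rb0 <- 0
  if (!is.finite(rw0)) rw0 <- 0
  c(log(sqrt(vb_x)), log(sqrt(vb_y)), clamp(rb0),
    log(sqrt(max(vw_x, 1e-6))), log(sqrt(max(vw_y, 1e-6))), clamp(rw0))
}

#' Within- and between-person correlation by two-level maximum likelihood
#'
#' Decomposes the joint distribution of two repeatedly measured variables
#' into a person level and a day level,
#' \deqn{(x_{ij}, y_{ij})' = \mu + b_i + w_{ij}, \quad
#'       b_i \sim N(0, \Sigma_B), \; w_{ij} \sim N(0, \Sigma_W),}
#' and reports the between-person correlation (off-diagonal of
#' \eqn{\Sigma_B}, the correlation of latent person means) and the
#' within-person correlation (off-diagonal of \eqn{\Sigma_W}). The default
#' estimator maximises the exact Gaussian likelihood via per-cluster
#' sufficient statistics with the fixed means profiled out; correlations are
#' parameterised on the Fisher-z scale, so standard errors come from the
#' observed information and Wald tests are performed on the z scale. The
#' `moments` estimator uses person-centered values (within) and observed
#' person means (between); with few observations per person the between
#' estimate is attenuated toward the observed-mean correlation, which is why
#' the latent ML route is the default.
#'
#' When `covariates` are supplied the observations are residualized on the
#' person-constant covariates first (see [adjust_between()]), making the
#' between-person correlation a partial correlation at that level; the
#' within-person estimate is unaffected.
#'
#' @param data data.frame with columns `person_id`, the two variables, and
#'   any covariates.
#' @param x,y column names of the paired variables.
#' @param covariates optional person-constant covariate columns (e.g. age,
#'   gender) partialled out of the between level.
#' @param estimator `"ml"` (default, latent two-level ML) or `"moments"`.
#' @return an object of class `ml_corr`: a list with `within` and `between`
#'   components (each `r`, `se`, `z`, `p`, possibly flags), variance matrices
#'   `sigma_between` / `sigma_within` (ml only), `n_persons`, `n_obs`,
#'   `estimator`, `adjusted_for`.
#' @export
#' @examples
#' sim <- simulate_panel(panel_config(80, 6, icc = 0.5,
#'   between_corr = matrix(c(1, .4, .4, 1), 2),
#'   within_corr = matrix(c(1, -.1, -.1, 1), 2), seed = 7))
#' multilevel_corr(sim$panel, "x", "y")
multilevel_corr <- function(data, x, y, covariates = NULL,
                            estimator = c("ml", "moments")) {
  estimator <- match.arg(estimator)
  cols <- c("person_id", x, y, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("columns not found in data: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[c(x, y)]), cols]
  adjusted_for <- character(0)
  if (length(covariates)) {
    d <- adjust_between(d, c(x, y), covariates)
    adjusted_for <- attr(d, "adjusted_for")
  }
  id <- factor(d$person_id)
  xv <- d[[x]]; yv <- d[[y]]
  st <- cluster_stats(xv, yv, id)

  res <- list(pair = c(x = x, y = y), estimator = paste0(estimator,
              if (estimator == "ml") "_latent" else "_observed"),
              n_persons = st$ncl, n_obs = st$N, adjusted_for = adjusted_for,
              type = "pearson")
  class(res) <- "ml_corr"

  no_within <- st$N - st$ncl < 2 || st$Swx <= 0 || st$Swy <= 0
  no_between <- st$ncl < 3

  if (estimator == "moments" || no_within) {
    res$within <- if (no_within) {
      list(r = NA_real_, se = NA_real_, p = NA_real_,
           flag = "no within-person information")
    } else moments_within(st, xv, yv, id)
    res$between <- if (no_between) {
      list(r = NA_real_, se = NA_real_, p = NA_real_,
           flag = "fewer than 3 persons")
    } else moments_between(st)
    if (estimator == "ml" && !no_between) {
      ## degenerate within level: fall back to moments with a note
      res$estimator <- "moments_observed"
      res$note <- "ml estimator requires within-person variance; used moments"
    }
    return(res)
  }

  op <- stats::optim(biv_start(st), biv_nll, st = st, method = "BFGS",
                     hessian = TRUE, control = list(maxit = 300))
  V <- tryCatch(solve(op$hessian), error = function(e) matrix(NA_real_, 6, 6))
  zse <- sqrt(pmax(diag(V), 0))
  mk <- function(k) {
    z <- op$par[k]; se_z <- zse[k]
    r <- tanh(z)
    se_r <- se_z * (1 - r^2)  # delta method back to the r scale
    ## Wald on the r scale: the z-scale statistic degenerates as |r| -> 1
    ## (the atanh standard error diverges faster than the estimate grows)
    stat <- if (se_r > 0) abs(r / se_r) else if (abs(r) > 0) Inf else 0
    list(r = r, se = se_r, z = z, se_z = se_z,
         p = 2 * stats::pnorm(-stat))
  }
  res$within <- mk(6)
  res$between <- if (no_between)
    list(r = NA_real_, se = NA_real_, p = NA_real_,
         flag = "fewer than 3 persons") else mk(3)
  sb <- exp(op$par[1:2]); sw <- exp(op$par[4:5])
  res$sigma_between <- matrix(c(sb[1]^2, tanh(op$par[3]) * prod(sb),
                                tanh(op$par[3]) * prod(sb), sb[2]^2), 2)
  res$sigma_within <- matrix(c(sw[1]^2, tanh(op$par[6]) * prod(sw),
                               tanh(op$par[6]) * prod(sw), sw[2]^2), 2)
  res$convergence <- op$convergence
  res
}

moments_within <- function(st, xv, yv, id) {
  cx <- xv - st$mx[id]; cy <- yv - st$my[id]
  r <- stats::cor(cx, cy)
  df <- st$N - st$ncl - 1
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, se = sqrt((1 - r^2) / df),
       p = 2 * stats::pt(-abs(tstat), df),
       note = "person-centered; attenuation-free at the within level")
}

moments_between <- function(st) {
  r <- stats::cor(st$mx, st$my)
  df <- st$ncl - 2
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, se = sqrt((1 - r^2) / df),
       p = 2 * stats::pt(-abs(tstat), df),
       note = "observed person means; attenuated when days per person are few")
}

#' @export
print.ml_corr <- function(x, ...) {
  cat(sprintf("Two-level correlation: %s ~ %s  [%s]\n",
              x$pair["x"], x$pair["y"], x$estimator))
  fmt <- function(lv, nm) {
    if (is.na(lv$r)) {
      cat(sprintf("  %-8s --  (%s)\n", nm, lv$flag))
    } else {
      cat(sprintf("  %-8s r = %6.3f (se %.3f), p = %.4g  [%s]\n",
                  nm, lv$r, lv$se, lv$p, label_effect(lv$r)))
    }
  }
  fmt(x$within, "within")
  fmt(x$between, "between")
  cat(sprintf("  n = %d persons, %d observations", x$n_persons, x$n_obs))
  if (length(x$adjusted_for))
    cat("; between level adjusted for ", paste(x$adjusted_for, collapse = ", "),
        sep = "")
  cat("\n")
  invisible(x)
}

#' Conventional effect-size label for a correlation
#'
#' |r| of 0.10, 0.30 and 0.50 mark small, medium and large effects
#' (inclusive thresholds).
#'
#' @param r correlation(s) in [-1, 1].
#' @return character vector with values `below_small`, `small`, `medium`,
#'   `large`.
#' @export
label_effect <- function(r) {
  stopifnot(all(abs(r[!is.na(r)]) <= 1))
  a <- abs(r)
  out <- ifelse(a >= 0.50, "large",
         ifelse(a >= 0.30, "medium",
         ifelse(a >= 0.10, "small", "below_small")))
  out[is.na(r)] <- NA_character_
  out
}

#' Tabulate correlation estimates
#'
#' Flattens a list of `ml_corr` / biserial estimates into a tidy report with
#' one row per estimated level, mirroring the shape of a within/between
#' correlation table. p-values are reported raw (no multiple-comparison
#' adjustment).
#'
#' @param estimates list of `ml_corr` objects.
#' @return data.frame with columns `x`, `y`, `level`, `type`, `r`, `se`, `p`,
#'   `effect`, `n_persons`, `n_obs`, `adjusted_for`.
#' @export
correlation_report <- function(estimates) {
  cols <- c("x", "y", "level", "type", "r", "se", "p", "effect",
            "n_persons", "n_obs", "adjusted_for")
  if (length(estimates) == 0L) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  rows <- lapply(estimates, function(e) {
    lv <- Filter(Negate(is.null), list(within = e$within, between = e$between))
    do.call(rbind, lapply(names(lv), function(nm) {
      data.frame(x = unname(e$pair["x"]), y = unname(e$pair["y"]), level = nm,
                 type = e$type, r = lv[[nm]]$r, se = lv[[nm]]$se,
                 p = lv[[nm]]$p,
                 effect = if (is.na(lv[[nm]]$r)) NA_character_
                          else label_effect(lv[[nm]]$r),
                 n_persons = e$n_persons, n_obs = e$n_obs,
                 adjusted_for = paste(e$adjusted_for, collapse = "+"),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
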