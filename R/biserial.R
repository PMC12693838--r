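#' Biserial correlation with an artificially dichotomized variable
#'
#' Estimates the latent-normal correlation between a continuous variable and
#' a binary variable assumed to arise by thresholding an underlying normal
#' variable:
#' \deqn{r_b = \frac{M_1 - M_0}{s_y} \cdot \frac{p(1-p)}{\phi(\Phi^{-1}(p))},}
#' with \eqn{M_1, M_0} the class means of the continuous variable, \eqn{s_y}
#' its total standard deviation, and \eqn{p} the proportion of 1s. Binary
#' health variables (diagnoses, status codes) are person-level here, so the
#' estimate is a between-person quantity computed on person-level values.
#' Small-sample estimates can exceed 1 in magnitude; these are clipped to
#' +/-1 and flagged.
#'
#' @param cont numeric vector (e.g. person-mean HRV).
#' @param bin 0/1 vector, both classes present.
#' @return an object of class `ml_corr` with a `between` component only
#'   (`r`, `se`, `p`, `clipped`); `type` is `"biserial"`. The standard error
#'   is Soper's large-sample approximation and the p-value a Wald test.
#' @export
#' @examples
#' set.seed(1)
#' z <- MASS::mvrnorm(500, c(0, 0), matrix(c(1, .4, .4, 1), 2))
#' biserial_corr(z[, 1], as.numeric(z[, 2] > 0))
biserial_corr <- function(cont, bin) {
  ok <- stats::complete.cases(cont, bin)
  cont <- cont[ok]; bin <- bin[ok]
  if (!all(bin %in% c(0, 1))) stop("bin must be coded 0/1")
  n <- length(cont)
  p <- mean(bin)
  if (p <= 0 || p >= 1) stop("degenerate dichotomy: binary variable has a single class")
  m1 <- mean(cont[bin == 1]); m0 <- mean(cont[bin == 0])
  sy <- stats::sd(cont)
  yord <- stats::dnorm(stats::qnorm(p))
  rb <- (m1 - m0) / sy * p * (1 - p) / yord
  clipped <- abs(rb) > 1
  rb_c <- max(min(rb, 1), -1)
  se <- (sqrt(p * (1 - p)) / yord - rb_c^2) / sqrt(n)
  res <- list(pair = c(x = "cont", y = "bin"),
              estimator = "biserial", type = "biserial",
              n_persons = n, n_obs = n, adjusted_for = character(0),
              within = NULL,
              between = list(r = rb_c, se = se,
                             p = 2 * stats::pnorm(-abs(rb_c / se)),
                             clipped = clipped,
                             raw_r = rb))
  class(res) <- "ml_corr"
  res
}
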