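# Simulated behavioral responses: von Mises error around the true direction
# with a uniform lapse component.

# Best-Fisher (1979) von Mises sampler, mean 0, concentration kappa (radians).
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    val <- sign(u3[ok] - 0.5) * acos(f[ok])
    k <- length(val)
    if (k > 0) {
      out[(got + 1L):(got + k)] <- val
      got <- got + k
    }
  }
  out
}

# Mean absolute angular error (degrees) of a von Mises responder with a
# uniform lapse component; used to place kappa in a target accuracy regime.
expected_abs_error <- function(kappa, lapse = 0) {
  f <- function(t) abs(t) * exp(kappa * cos(t)) / (2 * pi * besselI(kappa, 0))
  vm <- stats::integrate(f, -pi, pi)$value * 180 / pi
  (1 - lapse) * vm + lapse * 90
}

#' Calibrate response concentration to a target mean error
#'
#' Finds the von Mises concentration for which the expected mean absolute
#' angular error (including the lapse component) equals `target_deg`. With
#' the default lapse of 0, a target of 33.68 degrees (the accuracy regime of
#' trained participants) gives kappa of about 2.6.
#'
#' @param target_deg Target mean absolute angular error in degrees.
#' @param lapse Uniform lapse probability in `[0, 1]`.
#' @return The concentration `kappa`.
#' @export
calibrate_kappa <- function(target_deg = 33.68, lapse = 0) {
  lo <- expected_abs_error(0, lapse)
  if (target_deg >= lo) return(0)
  stats::uniroot(function(k) expected_abs_error(k, lapse) - target_deg,
                 c(1e-6, 500))$root
}

#' Simulate behavioral direction responses
#'
#' Draws a response direction for every trial: von Mises around the true
#' direction with probability `1 - lapse`, uniform on the circle otherwise
#' (lapses). Returns the absolute wrapped angular error per trial; with
#' `lapse = 1` the median absolute error converges to the 90-degree chance
#' level. A 4-point confidence rating is generated (higher for smaller
#' errors) but carried only as bookkeeping.
#'
#' @param trials A trial tibble with `trial_id` and `direction_deg`.
#' @param kappa Von Mises concentration (>= 0); see [calibrate_kappa()].
#' @param lapse Uniform lapse probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A tibble: `trial_id`, `true_deg`, `response_deg`, `error_deg`,
#'   `confidence`.
#' @export
simulate_behavior <- function(trials, kappa, lapse = 0, seed = NULL) {
  stopifnot_scalar_number(kappa, "kappa", 0)
  if (lapse < 0 || lapse > 1) abort("`lapse` must lie in [0, 1].")
  n <- nrow(trials)
  with_seed(seed, {
    dev <- rvonmises(n, kappa) * 180 / pi
    lapsed <- runif(n) < lapse
    dev[lapsed] <- runif(sum(lapsed), -180, 180)
    resp <- wrap_deg(trials$direction_deg + dev)
    err <- angular_error(trials$direction_deg, resp)
    conf <- pmin(4L, pmax(1L, 4L - floor(err / 45) + sample(-1:0, n, replace = TRUE)))
    tibble(trial_id = trials$trial_id, true_deg = trials$direction_deg,
           response_deg = resp, error_deg = err, confidence = as.integer(conf))
  })
}
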