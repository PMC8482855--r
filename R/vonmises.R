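#' Draw von Mises random angles
#'
#' Best–Fisher rejection sampler for the von Mises distribution, returning
#' angles in degrees on `[0, 360)`.
#'
#' @param n Number of draws.
#' @param mu Mean direction, degrees.
#' @param kappa Concentration, `> 0`.
#' @return Numeric vector of `n` angles in `[0, 360)`.
#' @keywords internal
rvonmises <- function(n, mu, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1 || !is.finite(kappa) || kappa <= 0) {
    stop("`kappa` must be a single positive number.", call. = FALSE)
  }
  stopifnot(n >= 0)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[keep] - 0.5) * acos(pmin(pmax(f[keep], -1), 1))
    k <- length(theta)
    if (k > 0) {
      out[(got + 1):(got + k)] <- theta
      got <- got + k
    }
  }
  wrap_angle(mu + out * 180 / pi)
}

#' Sample visual hints around a hidden target
#'
#' Hints are i.i.d. von Mises draws centred on the target location; their
#' circular mean converges to the target as `n` grows.
#'
#' @param target_angle Hidden target location, degrees.
#' @param kappa von Mises concentration, `> 0`.
#' @param n Number of hints, `>= 1`.
#' @param seed Optional integer seed; if supplied the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return Numeric vector of `n` hint angles in `[0, 360)`.
#' @examples
#' h <- sample_hints(90, kappa = 30, n = 5, seed = 1)
#' @export
sample_hints <- function(target_angle, kappa, n, seed = NULL) {
  stopifnot(length(target_angle) == 1, is.finite(target_angle), n >= 1)
  if (is.null(seed)) {
    rvonmises(n, target_angle, kappa)
  } else {
    withr::with_seed(seed, rvonmises(n, target_angle, kappa))
  }
}
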