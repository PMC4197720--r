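# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators behave as pure functions of their config.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Configuration errors carry the offending field name so callers (and the
# pipeline's fail-fast validation) can report it.
config_error <- function(field, message) {
  stop(structure(
    class = c("pouchtrack_config_error", "error", "condition"),
    list(message = sprintf("invalid configuration field '%s': %s", field, message),
         call = sys.call(-1), field = field)
  ))
}

input_error <- function(message) {
  stop(structure(
    class = c("pouchtrack_input_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    config_error(field, "must be a single finite number")
  }
  if (x < lower || x > upper) {
    config_error(field, sprintf("must be in [%s, %s]", lower, upper))
  }
  invisible(x)
}

# Sample from the von Mises distribution, vectorised over `mu` and `kappa`
# (Best & Fisher rejection sampler).  kappa ~ 0 falls back to the uniform
# circle.  Returns angles in (-pi, pi].
rvonmises <- function(n, mu, kappa) {
  mu <- rep_len(mu, n)
  kappa <- rep_len(kappa, n)
  theta <- numeric(n)
  unif <- kappa < 1e-10
  if (any(unif)) theta[unif] <- stats::runif(sum(unif), -pi, pi)
  idx <- which(!unif)
  if (length(idx)) {
    k <- kappa[idx]
    tau <- 1 + sqrt(1 + 4 * k^2)
    rho <- (tau - sqrt(2 * tau)) / (2 * k)
    r <- (1 + rho^2) / (2 * rho)
    out <- rep(NA_real_, length(idx))
    todo <- seq_along(idx)
    while (length(todo)) {
      m <- length(todo)
      z <- cos(pi * stats::runif(m))
      f <- (1 + r[todo] * z) / (r[todo] + z)
      cc <- k[todo] * (r[todo] - f)
      u2 <- stats::runif(m)
      accept <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      u3 <- stats::runif(m)
      ang <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
      out[todo[accept]] <- ang[accept]
      todo <- todo[!accept]
    }
    theta[idx] <- wrap_angle_rad(mu[idx] + out)
  }
  theta
}

# Wrap radians into (-pi, pi].
wrap_angle_rad <- function(x) {
  w <- x - 2 * pi * floor(x / (2 * pi) + 0.5)
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

sem <- function(x) stats::sd(x) / sqrt(length(x))
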