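#' miR-9 input profiles
#'
#' An `mir9_profile` represents a strictly positive miR-9 concentration
#' m(t) over a contiguous time window, built from piecewise constant or
#' linear segments, an arbitrary tabulated curve, or any of these with a
#' multiplicative log-scale fluctuation overlaid. Profiles are the input
#' to [simulate_basic()] and [simulate_extended()].
#'
#' Evaluation outside the window clamps to the boundary values, so a
#' profile can always drive a longer simulation (the input is held at
#' its final level). Piecewise-constant steps change value *at* the step
#' time: `profile_eval(p, t_step)` returns the post-step value.
#'
#' @name mir9_profile
NULL

new_profile <- function(segments, noise = NULL, table = NULL) {
  structure(
    list(segments = segments, noise = noise, table = table),
    class = "mir9_profile"
  )
}

stop_if_not_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single finite value > 0 (got %s)",
                 name, deparse(x)), call. = FALSE)
  }
}

#' Constant miR-9 profile
#'
#' @param m0 miR-9 level (arbitrary concentration units, > 0).
#' @param t0,t1 window start and end (hours, `t0 < t1`).
#' @return An [mir9_profile] evaluating to `m0` everywhere.
#' @examples
#' p <- make_constant(2.5, 24, 48)
#' profile_eval(p, c(24, 36, 48))
#' @export
make_constant <- function(m0, t0 = 0, t1 = 100) {
  stop_if_not_positive_scalar(m0, "m0")
  if (t0 >= t1) stop("'t0' must be < 't1'", call. = FALSE)
  new_profile(data.frame(t0 = t0, t1 = t1, kind = "constant",
                         v0 = m0, v1 = m0))
}

#' Linear miR-9 ramp
#'
#' Interpolates linearly from `m0` at `t0` to `m1` at `t1`; held at the
#' endpoint values outside the window.
#'
#' @param m0,m1 start and end miR-9 levels (> 0).
#' @param t0,t1 window start and end (hours, `t0 < t1`).
#' @return An [mir9_profile].
#' @examples
#' profile_eval(make_linear(1, 3, 0, 10), 5) # 2
#' @export
make_linear <- function(m0, m1, t0, t1) {
  stop_if_not_positive_scalar(m0, "m0")
  stop_if_not_positive_scalar(m1, "m1")
  if (t0 >= t1) stop("'t0' must be < 't1'", call. = FALSE)
  new_profile(data.frame(t0 = t0, t1 = t1, kind = "linear",
                         v0 = m0, v1 = m1))
}

#' Stepwise miR-9 profile from fold changes
#'
#' Starts at `m0` and multiplies the level by `fold` at each step time,
#' so the level after the k-th step is `m0 * prod(folds[1:k])`. The
#' value changes at the step time itself.
#'
#' @param m0 initial miR-9 level (> 0).
#' @param steps data frame (or list coercible to one) with columns `t`
#'   (strictly increasing step times, hours) and `fold` (> 0). May have
#'   zero rows for a constant profile.
#' @param t0 window start; must be <= the first step time.
#' @param t1 window end; defaults to 10 hours past the last step.
#' @return An [mir9_profile].
#' @examples
#' p <- make_steps(1, data.frame(t = c(5, 10), fold = c(2, 5)))
#' profile_eval(p, c(4, 7, 12)) # 1 2 10
#' @export
make_steps <- function(m0, steps, t0 = 0, t1 = NULL) {
  stop_if_not_positive_scalar(m0, "m0")
  steps <- as.data.frame(steps)
  if (nrow(steps) > 0 &&
      (!all(c("t", "fold") %in% names(steps))))
    stop("'steps' needs columns 't' and 'fold'", call. = FALSE)
  if (nrow(steps) == 0) {
    if (is.null(t1)) t1 <- t0 + 10
    return(make_constant(m0, t0, t1))
  }
  if (any(steps$fold <= 0)) stop("all 'fold' values must be > 0", call. = FALSE)
  if (any(diff(steps$t) <= 0))
    stop("step times must be strictly increasing", call. = FALSE)
  if (t0 > steps$t[1]) stop("'t0' must be <= the first step time", call. = FALSE)
  if (is.null(t1)) t1 <- steps$t[nrow(steps)] + 10
  if (t1 <= steps$t[nrow(steps)])
    stop("'t1' must be > the last step time", call. = FALSE)
  lv <- m0 * cumprod(steps$fold)
  bounds <- c(t0, steps$t, t1)
  vals <- c(m0, lv)
  new_profile(data.frame(t0 = bounds[-length(bounds)], t1 = bounds[-1],
                         kind = "constant", v0 = vals, v1 = vals))
}

#' Tabulated miR-9 profile
#'
#' Wraps an arbitrary sampled curve (for example the population mean of
#' a simulated cell population) as a profile; evaluation interpolates
#' linearly between samples and clamps at the ends.
#'
#' @param t strictly increasing sample times (hours).
#' @param m miR-9 levels at `t` (all > 0).
#' @return An [mir9_profile].
#' @export
make_tabulated <- function(t, m) {
  if (length(t) != length(m) || length(t) < 2)
    stop("'t' and 'm' must be equal-length vectors (length >= 2)", call. = FALSE)
  if (any(diff(t) <= 0)) stop("'t' must be strictly increasing", call. = FALSE)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("all 'm' values must be finite and > 0", call. = FALSE)
  new_profile(segments = NULL, table = list(t = as.numeric(t), m = as.numeric(m)))
}

#' Overlay multiplicative log-scale fluctuations on a profile
#'
#' Produces m(t) = base(t) * exp(eta(t)) where eta is a stationary
#' zero-mean Ornstein-Uhlenbeck process with stationary standard
#' deviation `amplitude` and correlation time `correlation_time`. The
#' noise path is sampled once at construction on an internal grid (40
#' points per correlation time) with the exact AR(1) discretisation and
#' interpolated linearly in between, so evaluation is a pure function of
#' `(t, seed)`. Multiplicative log-scale noise keeps m(t) strictly
#' positive for any amplitude.
#'
#' @param base an [mir9_profile] (must not already carry noise).
#' @param amplitude stationary standard deviation of log m (>= 0;
#'   0 returns `base` unchanged).
#' @param correlation_time noise correlation time (hours, > 0).
#' @param seed integer seed; identical seeds give identical paths.
#' @return An [mir9_profile].
#' @export
make_fluctuating <- function(base, amplitude, correlation_time, seed) {
  if (!inherits(base, "mir9_profile")) stop("'base' must be an mir9_profile", call. = FALSE)
  if (!is.null(base$noise)) stop("'base' already has noise", call. = FALSE)
  if (!is.numeric(amplitude) || length(amplitude) != 1 || amplitude < 0)
    stop("'amplitude' must be a single value >= 0", call. = FALSE)
  if (amplitude == 0) return(base)
  if (!is.numeric(correlation_time) || correlation_time <= 0)
    stop("'correlation_time' must be > 0", call. = FALSE)
  w <- profile_window(base)
  dt <- correlation_time / 40
  tg <- seq(w[1], w[2], by = dt)
  if (tg[length(tg)] < w[2]) tg <- c(tg, w[2])
  eta <- local_seed(seed, {
    n <- length(tg)
    a <- exp(-diff(tg) / correlation_time)
    b <- amplitude * sqrt(1 - a^2)
    z <- stats::rnorm(n)
    e <- numeric(n)
    e[1] <- amplitude * z[1]
    for (i in 2:n) e[i] <- a[i - 1] * e[i - 1] + b[i - 1] * z[i]
    e
  })
  out <- base
  out$noise <- list(amplitude = amplitude, correlation_time = correlation_time,
                    seed = seed, t = tg, eta = eta)
  out
}

#' Time window covered by a profile
#'
#' @param profile an [mir9_profile].
#' @return Numeric `c(t0, t1)` in hours.
#' @export
profile_window <- function(profile) {
  if (!inherits(profile, "mir9_profile")) stop("not an mir9_profile", call. = FALSE)
  if (!is.null(profile$table)) {
    range(profile$table$t)
  } else {
    c(profile$segments$t0[1], profile$segments$t1[nrow(profile$segments)])
  }
}

#' Evaluate a profile
#'
#' @param profile an [mir9_profile].
#' @param t vector of times (hours). Times outside the window clamp to
#'   the boundary values.
#' @return miR-9 levels, all > 0.
#' @export
profile_eval <- function(profile, t) {
  if (!inherits(profile, "mir9_profile")) stop("not an mir9_profile", call. = FALSE)
  if (!is.null(profile$table)) {
    m <- stats::approx(profile$table$t, profile$table$m, xout = t, rule = 2)$y
  } else {
    seg <- profile$segments
    w <- profile_window(profile)
    tc <- pmin(pmax(t, w[1]), w[2])
    # segment index: last segment whose start is <= t (post-step value at
    # the step time); the final segment is closed on the right
    idx <- findInterval(tc, seg$t0, rightmost.closed = FALSE)
    idx[idx < 1L] <- 1L
    frac <- (tc - seg$t0[idx]) / (seg$t1[idx] - seg$t0[idx])
    m <- ifelse(seg$kind[idx] == "constant", seg$v0[idx],
                seg$v0[idx] + frac * (seg$v1[idx] - seg$v0[idx]))
  }
  if (!is.null(profile$noise)) {
    n <- profile$noise
    eta <- stats::approx(n$t, n$eta, xout = t, rule = 2)$y
    m <- m * exp(eta)
  }
  m
}

# Fast scalar evaluator used by the ODE right-hand sides: same values
# as profile_eval (the OU log-noise is by construction linear between
# its grid nodes, so approxfun reproduces it exactly), but without
# per-call S3 dispatch or argument checking.
profile_fun <- function(profile) {
  if (!is.null(profile$table)) {
    f <- stats::approxfun(profile$table$t, profile$table$m, rule = 2)
  } else {
    seg <- profile$segments
    t0v <- seg$t0; t1v <- seg$t1; v0 <- seg$v0; v1 <- seg$v1
    lin <- seg$kind == "linear"
    w0 <- t0v[1]; w1 <- t1v[length(t1v)]
    f <- function(t) {
      tc <- min(max(t, w0), w1)
      i <- findInterval(tc, t0v)
      if (i < 1L) i <- 1L
      if (lin[i]) v0[i] + (tc - t0v[i]) / (t1v[i] - t0v[i]) * (v1[i] - v0[i])
      else v0[i]
    }
  }
  if (!is.null(profile$noise)) {
    ef <- stats::approxfun(profile$noise$t, profile$noise$eta, rule = 2)
    base_f <- f
    f <- function(t) base_f(t) * exp(ef(t))
  }
  f
}

#' Times at which a profile is discontinuous
#'
#' Used by the simulators to restart integration at step times instead
#' of smearing an instantaneous change across solver steps.
#'
#' @param profile an [mir9_profile].
#' @return Numeric vector of interior breakpoint times (possibly empty).
#' @export
profile_breakpoints <- function(profile) {
  if (!inherits(profile, "mir9_profile")) stop("not an mir9_profile", call. = FALSE)
  if (!is.null(profile$table)) return(numeric(0))
  seg <- profile$segments
  if (nrow(seg) < 2) return(numeric(0))
  b <- seg$t0[-1]
  left <- ifelse(seg$kind[-nrow(seg)] == "constant",
                 seg$v0[-nrow(seg)], seg$v1[-nrow(seg)])
  b[abs(left - seg$v0[-1]) > 0]
}

#' @export
print.mir9_profile <- function(x, ...) {
  w <- profile_window(x)
  if (!is.null(x$table)) {
    cat(sprintf("<mir9_profile> tabulated, %d samples on [%g, %g] h\n",
                length(x$table$t), w[1], w[2]))
  } else {
    cat(sprintf("<mir9_profile> %d segment(s) on [%g, %g] h\n",
                nrow(x$segments), w[1], w[2]))
  }
  if (!is.null(x$noise)) {
    cat(sprintf("  log-OU noise: amplitude %g, correlation time %g h, seed %d\n",
                x$noise$amplitude, x$noise$correlation_time, x$noise$seed))
  }
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a deterministic per-component seed
#'
#' Maps a run seed and a component name to a substream seed below 2^31,
#' so every stochastic code path can derive its own stream from the one
#' global seed and adding a component never perturbs existing streams.
#'
#' @param seed integer run seed.
#' @param component character component name.
#' @return An integer seed in \[0, 2^31).
#' @export
component_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}
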