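# Shared fixtures: the reference parameter set and small generators used
# across test files. Everything is built in code; no stored fixtures.

ref_basic <- function() basic_params()
ref_extended <- function() extended_params()

# Random positive parameter draw for the basic model
random_basic <- function() {
  basic_params(alpha_h = stats::runif(1, 0.2, 3),
               mu_h = stats::runif(1, 0.2, 3),
               alpha_X = stats::runif(1, 0.2, 3),
               mu_X = stats::runif(1, 0.2, 3))
}

# Jitter the reference extended set by +/- `spread` (relative), keeping
# the Hill coefficients fixed; used to generate feasible random draws.
jitter_extended <- function(spread = 0.15) {
  j <- function(x) x * stats::runif(1, 1 - spread, 1 + spread)
  extended_params(
    basic = basic_params(alpha_h = j(1), mu_h = j(1),
                         alpha_X = j(0.2), mu_X = j(0.2)),
    alpha_Y = j(0.1), beta_Y = j(2), mu_Y = j(1),
    hill_y_on_h = hill_spec(5, j(0.3)),
    hill_h_on_y = hill_spec(5, j(0.5)),
    hill_y_self = hill_spec(4, j(0.3)))
}

# Draw feasible parameter sets (C1 + C2) around the reference point
draw_feasible <- function(n, spread = 0.15) {
  out <- list()
  tries <- 0
  while (length(out) < n && tries < 50 * n) {
    tries <- tries + 1
    p <- jitter_extended(spread)
    f <- check_parameter_feasibility(p, check_threshold = FALSE)
    if (f$C1 && f$C2) out[[length(out) + 1]] <- p
  }
  out
}

# Random piecewise profile: a few positive steps and/or a ramp on [0, 30]
random_profile <- function() {
  n_steps <- sample(0:3, 1)
  m0 <- stats::runif(1, 0.5, 2)
  if (n_steps == 0) {
    make_linear(m0, m0 * stats::runif(1, 0.5, 3), 0, 30)
  } else {
    ts <- sort(stats::runif(n_steps, 2, 28))
    make_steps(m0, data.frame(t = ts,
                              fold = stats::runif(n_steps, 0.5, 3)),
               t0 = 0, t1 = 30)
  }
}

# Dense-grid sign-change oracle for fixed points of a scalar residual:
# returns midpoints of the bracketing intervals on an n-point grid.
grid_root_oracle <- function(resid, lo, hi, n = 1e5) {
  g <- seq(lo, hi, length.out = n)
  r <- resid(g)
  i <- which(r[-1] * r[-length(r)] <= 0 & r[-length(r)] != 0)
  list(roots = (g[i] + g[i + 1]) / 2, resolution = g[2] - g[1])
}
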