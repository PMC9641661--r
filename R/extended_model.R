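#' The extended model: adaptation plus a bistable mutual-repression switch
#'
#' The adaptation loop alone can never hold Her6 down: any sustained
#' input change is eventually cancelled. The extended circuit adds a
#' downstream target Y that self-activates and is in mutual repression
#' with Her6:
#'
#'   dh/dt = alpha_h G(m) G(X) Gm(Y; y_on_h) - mu_h h
#'   dX/dt = alpha_X G(m)                    - mu_X X
#'   dY/dt = (alpha_Y + beta_Y Gp(Y; y_self)) Gm(h; h_on_y) - mu_Y Y
#'
#' where Gp and Gm are activating and repressing Hill functions and
#' G(x) = 1/x as in the basic model. While Her6 sits at its adapted
#' level h*, Y is repressed and the loop behaves like the basic model.
#' A sufficiently sharp increase of miR-9 drives a deep transient dip of
#' Her6; if the dip releases Y long enough for self-activation to carry
#' it past its unstable branch, Y locks high and represses Her6 into a
#' new, lower steady state. Gradual inputs of the same total fold never
#' dip deeply enough, so the circuit decodes step-like miR-9 increases
#' and ignores slow ones.
#'
#' @name extended_model
NULL

#' Hill interaction specification
#'
#' @param n Hill coefficient (>= 1).
#' @param p0 half-maximal threshold (> 0, units of the regulating
#'   species).
#' @return A `hill_spec` list.
#' @export
hill_spec <- function(n, p0) {
  if (!is.numeric(n) || n < 1) stop("Hill coefficient 'n' must be >= 1", call. = FALSE)
  stop_if_not_positive_scalar(p0, "p0")
  structure(list(n = n, p0 = p0), class = "hill_spec")
}

#' Activating Hill function p^n / (p0^n + p^n)
#'
#' Tends to 0 as p goes to 0 and to 1 for p >> p0; equals 1/2 at
#' p = p0.
#'
#' @param p level (>= 0), vectorised.
#' @param spec a [hill_spec()].
#' @return Factor in \[0, 1).
#' @export
hill_activating <- function(p, spec) {
  if (any(p < 0)) stop("'p' must be >= 0", call. = FALSE)
  r <- (p / spec$p0)^spec$n
  r / (1 + r)
}

#' Repressing Hill function p0^n / (p0^n + p^n)
#'
#' Equals 1 at p = 0 and goes to 0 for p >> p0; the exact complement of
#' [hill_activating()].
#'
#' @inheritParams hill_activating
#' @return Factor in (0, 1\].
#' @export
hill_repressing <- function(p, spec) {
  if (any(p < 0)) stop("'p' must be >= 0", call. = FALSE)
  1 / (1 + (p / spec$p0)^spec$n)
}

# d/dp of hill_activating; d/dp of hill_repressing is its negative
hill_activating_deriv <- function(p, spec) {
  n <- spec$n; p0 <- spec$p0
  ifelse(p == 0, if (n == 1) 1 / p0 else 0,
         n * (p / p0)^n / (p * (1 + (p / p0)^n)^2))
}

#' Parameters of the extended model
#'
#' The defaults are the package's reference parameter set: a feasible
#' configuration (see [check_parameter_feasibility()]) in which Y is
#' fully repressed at the adapted Her6 level h* = 1, the coupled system
#' is bistable, and an instantaneous miR-9 fold change of about 5.9
#' separates adaptation from switching.
#'
#' @param basic a [basic_params()].
#' @param alpha_Y basal production rate of Y (a.u./hour).
#' @param beta_Y additional production rate of Y under full
#'   self-activation (a.u./hour).
#' @param mu_Y degradation rate of Y (1/hour).
#' @param hill_y_on_h repression of Her6 by Y; its threshold is the p1
#'   parameter that sets the level of the low Her6 state.
#' @param hill_h_on_y repression of Y by Her6.
#' @param hill_y_self self-activation of Y; bistability of the Y branch
#'   needs a coefficient > 1.
#' @param gate_basal_only if `TRUE`, Her6 repression gates only the
#'   basal production of Y (`alpha_Y`), leaving self-activation
#'   ungated; the default gates the total production.
#' @return An `extended_params` list.
#' @export
extended_params <- function(basic = basic_params(),
                            alpha_Y = 0.1, beta_Y = 2, mu_Y = 1,
                            hill_y_on_h = hill_spec(5, 0.3),
                            hill_h_on_y = hill_spec(5, 0.5),
                            hill_y_self = hill_spec(4, 0.3),
                            gate_basal_only = FALSE) {
  stopifnot(inherits(basic, "basic_params"),
            inherits(hill_y_on_h, "hill_spec"),
            inherits(hill_h_on_y, "hill_spec"),
            inherits(hill_y_self, "hill_spec"))
  for (nm in c("alpha_Y", "mu_Y"))
    stop_if_not_positive_scalar(get(nm), nm)
  if (!is.numeric(beta_Y) || length(beta_Y) != 1 || beta_Y < 0)
    stop("'beta_Y' must be a single value >= 0", call. = FALSE)
  structure(list(basic = basic, alpha_Y = alpha_Y, beta_Y = beta_Y,
                 mu_Y = mu_Y, hill_y_on_h = hill_y_on_h,
                 hill_h_on_y = hill_h_on_y, hill_y_self = hill_y_self,
                 gate_basal_only = isTRUE(gate_basal_only)),
            class = "extended_params")
}

# Y production term at levels (h, Y)
y_production <- function(params, h, Y) {
  self <- params$beta_Y * hill_activating(Y, params$hill_y_self)
  rep_h <- hill_repressing(h, params$hill_h_on_y)
  if (params$gate_basal_only) params$alpha_Y * rep_h + self
  else (params$alpha_Y + self) * rep_h
}

#' Right-hand side of the extended model
#'
#' @param state numeric `c(h, X, Y)`; `h`, `X` > 0 and `Y` >= 0.
#' @param t time (hours).
#' @param params an [extended_params()].
#' @param profile an [mir9_profile] supplying m(t).
#' @return Numeric `c(dh, dX, dY)`.
#' @export
rhs_extended <- function(state, t, params, profile) {
  h <- state[[1]]; X <- state[[2]]; Y <- state[[3]]
  if (h <= 0 || X <= 0 || Y < 0)
    stop("extended model requires h > 0, X > 0, Y >= 0", call. = FALSE)
  b <- params$basic
  m <- profile_eval(profile, t)
  c(b$alpha_h * repression_G(m) * repression_G(X) *
      hill_repressing(Y, params$hill_y_on_h) - b$mu_h * h,
    b$alpha_X * repression_G(m) - b$mu_X * X,
    y_production(params, h, Y) - params$mu_Y * Y)
}

#' Fixed points of the Y branch with Her6 clamped
#'
#' Roots of (alpha_Y + beta_Y Gp(Y)) Gm(h) - mu_Y Y = 0 for fixed h,
#' found by sign-change bracketing on a dense grid followed by
#' `uniroot` refinement. A root is stable when the residual's slope
#' there is negative.
#'
#' @param params an [extended_params()].
#' @param h_clamped clamped Her6 level (>= 0).
#' @param y_max upper end of the scan (defaults to 1.5x the maximal
#'   production / degradation balance, and widens once if a root sits
#'   at the boundary).
#' @param n_grid number of scan points.
#' @return Data frame with columns `Y` and `stable`.
#' @export
y_subsystem_fixed_points <- function(params, h_clamped,
                                     y_max = NULL, n_grid = 4000L) {
  stopifnot(inherits(params, "extended_params"))
  if (h_clamped < 0) stop("'h_clamped' must be >= 0", call. = FALSE)
  if (is.null(y_max))
    y_max <- 1.5 * (params$alpha_Y + params$beta_Y) / params$mu_Y
  resid <- function(Y) y_production(params, h_clamped, Y) - params$mu_Y * Y
  for (attempt in 1:2) {
    grid <- seq(0, y_max, length.out = n_grid)
    r <- resid(grid)
    roots <- numeric(0)
    sc <- which(r[-1] * r[-length(r)] <= 0 & r[-length(r)] != 0)
    for (i in sc)
      roots <- c(roots, stats::uniroot(resid, c(grid[i], grid[i + 1]),
                                       tol = 1e-12)$root)
    exact <- which(r == 0)
    roots <- sort(unique(c(roots, grid[exact])))
    if (length(roots) && max(roots) > 0.99 * y_max) {
      y_max <- y_max * 4 # widen once: a root sits at the boundary
      next
    }
    break
  }
  if (!length(roots))
    stop("no Y fixed point found on [0, ", y_max, "]", call. = FALSE)
  eps <- y_max * 1e-7
  stable <- vapply(roots, function(y)
    (resid(y + eps) - resid(max(y - eps, 0))) < 0, logical(1))
  data.frame(Y = roots, stable = stable)
}

# Analytic Jacobian of the extended model at state (h, X, Y), input m
jacobian_extended <- function(params, state, m) {
  b <- params$basic
  h <- state[1]; X <- state[2]; Y <- state[3]
  ry <- hill_repressing(Y, params$hill_y_on_h)
  dry <- -hill_activating_deriv(Y, params$hill_y_on_h)
  rh <- hill_repressing(h, params$hill_h_on_y)
  drh <- -hill_activating_deriv(h, params$hill_h_on_y)
  s <- hill_activating(Y, params$hill_y_self)
  ds <- hill_activating_deriv(Y, params$hill_y_self)
  J <- matrix(0, 3, 3, dimnames = list(c("h", "X", "Y"), c("h", "X", "Y")))
  J["h", "h"] <- -b$mu_h
  J["h", "X"] <- -b$alpha_h / (m * X^2) * ry
  J["h", "Y"] <- b$alpha_h / (m * X) * dry
  J["X", "X"] <- -b$mu_X
  if (params$gate_basal_only) {
    J["Y", "h"] <- params$alpha_Y * drh
    J["Y", "Y"] <- params$beta_Y * ds - params$mu_Y
  } else {
    J["Y", "h"] <- (params$alpha_Y + params$beta_Y * s) * drh
    J["Y", "Y"] <- params$beta_Y * ds * rh - params$mu_Y
  }
  J
}

#' Fixed points of the full extended system at constant miR-9
#'
#' At steady state X* = alpha_X / (mu_X m) and h = h* Gm(Y; y_on_h)
#' (the m-dependence cancels exactly as in the basic model), so the
#' problem reduces to a scalar root search in Y. Stability comes from
#' the eigenvalues of the analytic 3x3 Jacobian.
#'
#' @param params an [extended_params()].
#' @param m constant miR-9 level (> 0).
#' @param n_grid scan resolution for the Y root search.
#' @return Data frame with columns `h`, `X`, `Y`, `stable`,
#'   `leading_eigenvalue_real`, ordered by increasing Y.
#' @export
full_fixed_points <- function(params, m, n_grid = 4000L) {
  stopifnot(inherits(params, "extended_params"))
  if (m <= 0) stop("'m' must be > 0", call. = FALSE)
  b <- params$basic
  hs <- steady_state_h(b)
  h_of_Y <- function(Y) hs * hill_repressing(Y, params$hill_y_on_h)
  resid <- function(Y) y_production(params, h_of_Y(Y), Y) - params$mu_Y * Y
  y_max <- 1.5 * (params$alpha_Y + params$beta_Y) / params$mu_Y
  grid <- seq(0, y_max, length.out = n_grid)
  r <- resid(grid)
  sc <- which(r[-1] * r[-length(r)] <= 0 & r[-length(r)] != 0)
  roots <- vapply(sc, function(i)
    stats::uniroot(resid, c(grid[i], grid[i + 1]), tol = 1e-12)$root,
    numeric(1))
  roots <- sort(unique(c(roots, grid[r == 0])))
  if (!length(roots))
    stop("no fixed point found; parameters appear invalid", call. = FALSE)
  X <- steady_state_X(b, m)
  out <- do.call(rbind, lapply(roots, function(Y) {
    st <- c(h = h_of_Y(Y), X = X, Y = Y)
    ev <- eigen(jacobian_extended(params, st, m), only.values = TRUE)$values
    lead <- max(Re(ev))
    data.frame(h = st[["h"]], X = st[["X"]], Y = Y,
               stable = lead < 0, leading_eigenvalue_real = lead)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate the extended model
#'
#' @inheritParams simulate_basic
#' @param params an [extended_params()].
#' @param init `"steady"` (the stable fixed point with the highest Her6
#'   level at m(t0), i.e. the adapted state) or numeric `c(h, X, Y)`.
#' @return An `mir9_trajectory` data frame with columns `time`, `m`,
#'   `h`, `X`, `Y`.
#' @export
simulate_extended <- function(params, profile, t_grid,
                              init = "steady", settings = solver_settings()) {
  stopifnot(inherits(params, "extended_params"))
  if (any(diff(t_grid) <= 0) || length(t_grid) < 2)
    stop("'t_grid' must be strictly increasing (length >= 2)", call. = FALSE)
  if (identical(init, "steady")) {
    m0 <- profile_eval(profile, t_grid[1])
    fp <- full_fixed_points(params, m0)
    fp <- fp[fp$stable, , drop = FALSE]
    if (!nrow(fp)) stop("no stable fixed point at m(t0)", call. = FALSE)
    fp <- fp[which.max(fp$h), ]
    init <- c(h = fp$h, X = fp$X, Y = fp$Y)
  } else {
    init <- c(h = unname(init[1]), X = unname(init[2]), Y = unname(init[3]))
    if (init[1] <= 0 || init[2] <= 0 || init[3] < 0)
      stop("initial state must have h > 0, X > 0, Y >= 0", call. = FALSE)
  }
  b <- params$basic
  mfun <- profile_fun(profile)
  # Hill terms are inlined with precomputed constants (this closure is
  # called tens of thousands of times per run) and clamped at 0 for the
  # solver's internal trial steps, which may poke infinitesimally below
  # zero near the low state
  aH <- b$alpha_h; mH <- b$mu_h; aX <- b$alpha_X; mX <- b$mu_X
  n1 <- params$hill_y_on_h$n; q1 <- params$hill_y_on_h$p0
  nh <- params$hill_h_on_y$n; qh <- params$hill_h_on_y$p0
  ns <- params$hill_y_self$n; qs <- params$hill_y_self$p0
  aY <- params$alpha_Y; bY <- params$beta_Y; mY <- params$mu_Y
  gate_basal <- params$gate_basal_only
  func <- function(t, y, p) {
    m <- mfun(t)
    hh <- max(y[1], 0)
    yy <- max(y[3], 0)
    rep_y <- 1 / (1 + (yy / q1)^n1)
    rep_h <- 1 / (1 + (hh / qh)^nh)
    rs <- (yy / qs)^ns
    self <- bY * rs / (1 + rs)
    prod_Y <- if (gate_basal) aY * rep_h + self else (aY + self) * rep_h
    list(c(aH / (m * y[2]) * rep_y - mH * y[1],
           aX / m - mX * y[2],
           prod_Y - mY * yy))
  }
  sol <- integrate_piecewise(func, init, t_grid, params, profile, settings)
  finish_trajectory(sol, profile, "extended", params)
}

#' Classify a trajectory as adapted or switched
#'
#' Operationalises the two behaviours of the extended circuit:
#' `"switched"` if the final Her6 level is below half of h* and Y ended
#' above the unstable branch at the final input; `"adapted"` if Her6 is
#' back within 5% of h* and Y below the unstable branch; `"undecided"`
#' otherwise, or (with a warning) when the trajectory has not settled
#' (|dh/dt| at the end above `settle_tol` * h* per hour).
#'
#' @param traj an `mir9_trajectory` from [simulate_extended()].
#' @param params an [extended_params()].
#' @param settle_tol settledness bound on |dh/dt| / h* (1/hour).
#' @return List with `classification`, `final_h_relative`,
#'   `max_transient_deviation`, `final_Y`.
#' @export
classify_outcome <- function(traj, params, settle_tol = 1e-6) {
  stopifnot(inherits(traj, "mir9_trajectory"),
            inherits(params, "extended_params"))
  hs <- steady_state_h(params$basic)
  n <- nrow(traj)
  end <- c(traj$h[n], traj$X[n], traj$Y[n])
  m_end <- traj$m[n]
  prof <- attr(traj, "profile")
  dh <- rhs_extended(pmax(end, c(1e-300, 1e-300, 0)), traj$time[n], params,
                     make_constant(m_end, traj$time[n], traj$time[n] + 1))[1]
  settled <- abs(dh) < settle_tol * hs
  fp <- full_fixed_points(params, m_end)
  y_unstable <- if (any(!fp$stable)) min(fp$Y[!fp$stable]) else NA_real_
  final_rel <- end[1] / hs
  res <- list(final_h_relative = final_rel,
              max_transient_deviation = max(abs(traj$h - hs) / hs),
              final_Y = end[3])
  if (!settled) {
    warning("trajectory has not settled; classification is undecided")
    res$classification <- "undecided"
  } else if (final_rel < 0.5 &&
             (is.na(y_unstable) || end[3] > y_unstable)) {
    res$classification <- "switched"
  } else if (abs(final_rel - 1) < 0.05 &&
             (is.na(y_unstable) || end[3] < y_unstable)) {
    res$classification <- "adapted"
  } else {
    res$classification <- "undecided"
  }
  res[c("classification", "final_h_relative", "max_transient_deviation",
        "final_Y")]
}

# Simulate a single instantaneous step m0 -> fold * m0 and classify.
step_response <- function(params, fold, m0 = 1, t_step = 10, t_end = 150,
                          settings = solver_settings()) {
  prof <- make_steps(m0, data.frame(t = t_step, fold = fold),
                     t0 = 0, t1 = t_end)
  traj <- simulate_extended(params, prof, seq(0, t_end, by = 0.1),
                            settings = settings)
  classify_outcome(traj, params)
}

#' Critical miR-9 fold change for switching
#'
#' Bisects the instantaneous step fold between `fold_range[1]`
#' (which must adapt) and `fold_range[2]` (which must switch) to a
#' relative tolerance of `tol`, returning the smallest switching fold.
#' Because the adaptation branch has exact fold-change symmetry, the
#' threshold does not depend on the pre-step level `m0`.
#'
#' @param params an [extended_params()].
#' @param m0 pre-step miR-9 level.
#' @param fold_range `c(lo, hi)` bracketing the threshold.
#' @param t_step,t_end step time and simulation end (hours).
#' @param tol relative bisection tolerance.
#' @param settings a [solver_settings()].
#' @return The critical fold (dimensionless).
#' @export
find_switching_threshold <- function(params, m0 = 1, fold_range = c(1.1, 20),
                                     t_step = 10, t_end = 150, tol = 1e-3,
                                     settings = solver_settings()) {
  stopifnot(inherits(params, "extended_params"))
  lo <- fold_range[1]; hi <- fold_range[2]
  cl_lo <- step_response(params, lo, m0, t_step, t_end, settings)$classification
  cl_hi <- step_response(params, hi, m0, t_step, t_end, settings)$classification
  if (cl_lo != "adapted" || cl_hi != "switched")
    stop("fold_range does not straddle the threshold (got ", cl_lo, " at ",
         lo, ", ", cl_hi, " at ", hi, ")", call. = FALSE)
  while ((hi - lo) / lo > tol) {
    mid <- sqrt(lo * hi)
    cl <- step_response(params, mid, m0, t_step, t_end, settings)$classification
    if (cl == "switched") hi <- mid else lo <- mid
  }
  hi
}

#' Feasibility of an extended parameter set
#'
#' The switch only works in a particular parameter regime. Three
#' conditions are checked:
#' \describe{
#'   \item{C1 (bistable switch)}{the full system at the reference input
#'     has at least two stable fixed points, one with Her6 near h* and
#'     one with Her6 below h*/2, and the Y branch alone is bistable for
#'     Her6 clamped at some level between 0 and h* -- the switch
#'     memory lives in Y self-activation (which requires a Hill
#'     coefficient > 1 and beta_Y > 0), not merely in mutual
#'     repression.}
#'   \item{C2 (Y silenced at h*)}{with Her6 clamped at h*, the Y branch
#'     has a unique fixed point, below the self-activation threshold:
#'     Y has no effect while Her6 is adapted.}
#'   \item{C3 (finite switching threshold)}{some instantaneous fold
#'     change in (1, 100] switches the system (only checked when
#'     `check_threshold` is `TRUE`; it costs several simulations).}
#' }
#'
#' @param params an [extended_params()].
#' @param m reference miR-9 level for C1.
#' @param check_threshold also verify C3 by simulation.
#' @return List with logical `C1`, `C2`, `C3` (`NA` when not checked),
#'   `feasible` (conjunction of the checked conditions) and the fixed
#'   points found.
#' @export
check_parameter_feasibility <- function(params, m = 1, check_threshold = TRUE) {
  stopifnot(inherits(params, "extended_params"))
  hs <- steady_state_h(params$basic)
  fp <- full_fixed_points(params, m)
  stable <- fp[fp$stable, , drop = FALSE]
  y_branch_bistable <- any(vapply(seq(0, hs, length.out = 21), function(h) {
    yf <- tryCatch(y_subsystem_fixed_points(params, h, n_grid = 1000L),
                   error = function(e) NULL)
    !is.null(yf) && sum(yf$stable) >= 2
  }, logical(1)))
  C1 <- nrow(stable) >= 2 &&
    any(abs(stable$h / hs - 1) < 0.05) && any(stable$h / hs < 0.5) &&
    y_branch_bistable
  yfp <- y_subsystem_fixed_points(params, hs)
  C2 <- nrow(yfp) == 1 && yfp$Y[1] < params$hill_y_self$p0
  C3 <- NA
  if (check_threshold && C1 && C2) {
    C3 <- FALSE
    lo <- 1.01
    for (hi in c(2, 5, 10, 30, 100)) {
      cl <- step_response(params, hi)$classification
      if (cl == "switched") { C3 <- TRUE; break }
    }
  }
  checked <- c(C1, C2, if (!is.na(C3)) C3)
  list(C1 = C1, C2 = C2, C3 = C3, feasible = all(checked),
       fixed_points = fp)
}
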