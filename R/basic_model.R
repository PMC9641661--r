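#' The perfect-adaptation incoherent feed-forward loop
#'
#' miR-9 (m) represses Her6 (h) directly and also represses an
#' intermediate repressor X of Her6, forming an incoherent feed-forward
#' loop:
#'
#'   dh/dt = alpha_h * G(m) * G(X) - mu_h * h
#'   dX/dt = alpha_X * G(m)        - mu_X * X
#'
#' with the repression function G(x) = 1/x. At steady state X* =
#' alpha_X / (mu_X * m), so the two m-dependencies cancel and
#' h* = alpha_h * mu_X / (mu_h * alpha_X) is independent of miR-9:
#' Her6 adapts perfectly to any sustained change of the input. With
#' G(x) = 1/x the adaptation is in fact an exact fold-change symmetry:
#' rescaling m(t) by a constant (with X rescaled inversely) leaves the
#' h trajectory unchanged, so only relative changes of miR-9 matter.
#'
#' @name basic_model
NULL

#' Parameters of the basic adaptation model
#'
#' @param alpha_h,alpha_X production rates of Her6 and X (a.u./hour).
#' @param mu_h,mu_X degradation rates of Her6 and X (1/hour).
#' @return A `basic_params` list. All four values must be > 0.
#' @export
basic_params <- function(alpha_h = 1, mu_h = 1, alpha_X = 0.2, mu_X = 0.2) {
  for (nm in c("alpha_h", "mu_h", "alpha_X", "mu_X"))
    stop_if_not_positive_scalar(get(nm), nm)
  structure(list(alpha_h = alpha_h, mu_h = mu_h,
                 alpha_X = alpha_X, mu_X = mu_X),
            class = "basic_params")
}

#' Repression function G(x) = 1/x
#'
#' The nonlinear negative interaction used for every repression in the
#' basic model. Its pole at 0 is a genuine model boundary: states and
#' inputs must stay strictly positive, and evaluation at x <= 0 is an
#' error rather than a regularised value.
#'
#' @param x positive level.
#' @return 1/x.
#' @export
repression_G <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("G(x) = 1/x requires x > 0", call. = FALSE)
  1 / x
}

#' Steady-state Her6 level
#'
#' h* = alpha_h * mu_X / (mu_h * alpha_X); independent of miR-9.
#'
#' @param params a [basic_params()].
#' @return Her6 steady state (a.u.).
#' @export
steady_state_h <- function(params) {
  stopifnot(inherits(params, "basic_params"))
  params$alpha_h * params$mu_X / (params$mu_h * params$alpha_X)
}

#' Steady-state X level at a given miR-9 input
#'
#' X* = alpha_X / (mu_X * m).
#'
#' @param params a [basic_params()].
#' @param m miR-9 level (> 0).
#' @return X steady state (a.u.).
#' @export
steady_state_X <- function(params, m) {
  stopifnot(inherits(params, "basic_params"))
  if (any(m <= 0)) stop("'m' must be > 0", call. = FALSE)
  params$alpha_X / (params$mu_X * m)
}

#' Right-hand side of the basic model
#'
#' @param state numeric `c(h, X)`, both > 0.
#' @param t time (hours).
#' @param params a [basic_params()].
#' @param profile an [mir9_profile] supplying m(t).
#' @return Numeric `c(dh, dX)`.
#' @export
rhs_basic <- function(state, t, params, profile) {
  h <- state[[1]]; X <- state[[2]]
  if (h <= 0 || X <= 0) stop("basic model state must be strictly positive", call. = FALSE)
  m <- profile_eval(profile, t)
  c(params$alpha_h * repression_G(m) * repression_G(X) - params$mu_h * h,
    params$alpha_X * repression_G(m) - params$mu_X * X)
}

#' Integration settings
#'
#' Defaults are tight because G(x) = 1/x is stiff near small X; `lsoda`
#' switches to a stiff method automatically.
#'
#' @param rtol,atol relative and absolute tolerances (> 0).
#' @param max_step largest internal step (hours).
#' @return A `solver_settings` list.
#' @export
solver_settings <- function(rtol = 1e-8, atol = 1e-10, max_step = Inf) {
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0", call. = FALSE)
  structure(list(rtol = rtol, atol = atol, max_step = max_step),
            class = "solver_settings")
}

# Integrate a deSolve func over t_grid, restarting at every profile
# discontinuity so instantaneous input changes are not smeared. The
# state is continuous across a restart; only the input jumps.
integrate_piecewise <- function(func, y0, t_grid, parms, profile, settings) {
  brk <- profile_breakpoints(profile)
  brk <- brk[brk > t_grid[1] & brk < t_grid[length(t_grid)]]
  bounds <- unique(c(t_grid[1], sort(brk), t_grid[length(t_grid)]))
  pieces <- vector("list", length(bounds) - 1)
  y <- y0
  for (k in seq_len(length(bounds) - 1)) {
    tt <- unique(c(bounds[k],
                   t_grid[t_grid > bounds[k] & t_grid < bounds[k + 1]],
                   bounds[k + 1]))
    sol <- deSolve::ode(y = y, times = tt, func = func, parms = parms,
                        rtol = settings$rtol, atol = settings$atol,
                        hmax = settings$max_step, method = "lsoda")
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integration failed (istate = ", attr(sol, "istate")[1], ")",
           call. = FALSE)
    y <- sol[nrow(sol), -1]
    pieces[[k]] <- sol
  }
  out <- do.call(rbind, lapply(seq_along(pieces), function(k) {
    s <- pieces[[k]]
    keep <- s[, 1] %in% t_grid
    if (k > 1) keep[1] <- FALSE # boundary row belongs to the left piece
    s[keep, , drop = FALSE]
  }))
  out
}

finish_trajectory <- function(sol, profile, model, params) {
  df <- as.data.frame(sol)
  names(df)[1] <- "time"
  df$m <- profile_eval(profile, df$time)
  df <- df[, c("time", "m", setdiff(names(df), c("time", "m")))]
  state_cols <- setdiff(names(df), c("time", "m"))
  for (cc in state_cols) {
    bad <- !is.finite(df[[cc]]) | df[[cc]] < -1e-9
    if (any(bad))
      stop("state '", cc, "' underflowed to <= 0 during integration at t = ",
           df$time[which(bad)[1]], call. = FALSE)
    df[[cc]] <- pmax(df[[cc]], 0)
  }
  structure(df, class = c("mir9_trajectory", "data.frame"),
            model = model, params = params, profile = profile)
}

#' Simulate the basic adaptation model
#'
#' @param params a [basic_params()].
#' @param profile an [mir9_profile]; evaluation clamps outside its
#'   window, so `t_grid` may extend past it.
#' @param t_grid strictly increasing output times (hours).
#' @param init `"steady"` (the steady state at m(t0)) or numeric
#'   `c(h, X)` with both entries > 0.
#' @param settings a [solver_settings()].
#' @return An `mir9_trajectory` data frame with columns `time`, `m`,
#'   `h`, `X`.
#' @export
simulate_basic <- function(params, profile, t_grid,
                           init = "steady", settings = solver_settings()) {
  stopifnot(inherits(params, "basic_params"))
  if (any(diff(t_grid) <= 0) || length(t_grid) < 2)
    stop("'t_grid' must be strictly increasing (length >= 2)", call. = FALSE)
  if (identical(init, "steady")) {
    m0 <- profile_eval(profile, t_grid[1])
    init <- c(h = steady_state_h(params), X = steady_state_X(params, m0))
  } else {
    init <- c(h = unname(init[1]), X = unname(init[2]))
    if (any(init <= 0)) stop("initial state must be strictly positive", call. = FALSE)
  }
  mfun <- profile_fun(profile)
  func <- function(t, y, p) {
    m <- mfun(t)
    list(c(p$alpha_h / (m * y[2]) - p$mu_h * y[1],
           p$alpha_X / m - p$mu_X * y[2]))
  }
  sol <- integrate_piecewise(func, init, t_grid, params, profile, settings)
  finish_trajectory(sol, profile, "basic", params)
}

#' Adaptation metrics of a trajectory
#'
#' Deviations of Her6 from its adapted level h*, and the recovery time:
#' the time elapsed between the last change of the input and the first
#' moment after it from which |h - h*| / h* stays below `band`.
#'
#' @param traj an `mir9_trajectory`.
#' @param params a [basic_params()] (or the `basic` component of
#'   extended parameters) defining h*.
#' @param band relative band defining recovery (default 0.01).
#' @return List with `max_relative_deviation`,
#'   `final_relative_deviation` and `recovery_time` (hours; `Inf` if
#'   the trajectory never settles into the band).
#' @export
adaptation_metrics <- function(traj, params, band = 0.01) {
  stopifnot(inherits(traj, "mir9_trajectory"))
  if (inherits(params, "extended_params")) params <- params$basic
  hs <- steady_state_h(params)
  rel <- abs(traj$h - hs) / hs
  prof <- attr(traj, "profile")
  brk <- if (!is.null(prof)) profile_breakpoints(prof) else numeric(0)
  brk <- brk[brk >= traj$time[1] & brk <= traj$time[length(traj$time)]]
  t_last <- if (length(brk)) max(brk) else traj$time[1]
  after <- which(traj$time >= t_last)
  inband <- rel[after] < band
  # first index after the last input change from which the deviation
  # stays inside the band
  stay <- rev(cumprod(rev(inband))) > 0
  rec <- if (any(stay)) traj$time[after[which(stay)[1]]] - t_last else Inf
  list(max_relative_deviation = max(rel),
       final_relative_deviation = rel[length(rel)],
       recovery_time = rec)
}
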