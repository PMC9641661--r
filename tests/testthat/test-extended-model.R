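test_that("Hill functions have the textbook limits and complement identity", {
  s <- hill_spec(4, 2)
  expect_equal(hill_activating(2, s), 0.5)
  expect_equal(hill_repressing(2, s), 0.5)
  expect_equal(hill_activating(0, s), 0)
  expect_equal(hill_repressing(0, s), 1)
  expect_lt(abs(hill_activating(200, s) - 1), 1e-8)
  set.seed(4)
  for (i in 1:30) {
    sp <- hill_spec(runif(1, 1, 6), runif(1, 0.1, 5))
    p <- runif(1, 0, 10)
    expect_lt(abs(hill_activating(p, sp) + hill_repressing(p, sp) - 1), 1e-15)
  }
  expect_error(hill_spec(0.5, 1), "Hill coefficient")
  expect_error(hill_activating(-1, s), ">= 0")
})

test_that("with Y at zero the extended dynamics reduce exactly to the basic model", {
  ep <- ref_extended()
  prof <- make_constant(1, 0, 10)
  st <- c(0.7, 1.4, 0)
  d3 <- rhs_extended(st, 0, ep, prof)
  d2 <- rhs_basic(st[1:2], 0, ep$basic, prof)
  expect_equal(d3[1:2], d2)
  # full trajectory agreement when the Y branch is silenced
  ep0 <- extended_params(beta_Y = 0, alpha_Y = 1e-12)
  tg <- seq(0, 60, by = 0.2)
  prof2 <- make_steps(1, data.frame(t = 10, fold = 3), t0 = 0, t1 = 60)
  tr3 <- simulate_extended(ep0, prof2, tg, init = c(1, 1, 0))
  tr2 <- simulate_basic(ep0$basic, prof2, tg, init = c(1, 1))
  expect_lt(max(abs(tr3$h - tr2$h)), 1e-6)
  expect_lt(max(abs(tr3$X - tr2$X)), 1e-6)
})

test_that("the Y branch has the expected root structure", {
  ep <- ref_extended()
  # linear case: beta_Y = 0 gives the single closed-form root
  ep0 <- extended_params(beta_Y = 0)
  fp <- y_subsystem_fixed_points(ep0, 1)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$Y, ep0$alpha_Y *
                 hill_repressing(1, ep0$hill_h_on_y) / ep0$mu_Y,
               tolerance = 1e-9)
  expect_true(fp$stable)
  # reference set: bistable at intermediate Her6, monostable low at h*,
  # monostable high once Her6 is fully cleared
  hs <- steady_state_h(ep$basic)
  mid <- y_subsystem_fixed_points(ep, 0.5 * hs)
  expect_equal(nrow(mid), 3)
  expect_equal(mid$stable, c(TRUE, FALSE, TRUE))
  low <- y_subsystem_fixed_points(ep, hs)
  expect_equal(nrow(low), 1)
  expect_true(low$stable && low$Y < ep$hill_y_self$p0)
  high <- y_subsystem_fixed_points(ep, 0)
  expect_equal(nrow(high), 1)
  expect_gt(high$Y, ep$hill_y_self$p0)
})

test_that("Y-branch roots match a dense-grid sign-change oracle", {
  set.seed(31)
  draws <- draw_feasible(5)
  expect_gte(length(draws), 5)
  for (p in draws) {
    for (h in c(0, 0.5, 1)) {
      fp <- y_subsystem_fixed_points(p, h)
      ymax <- 1.5 * (p$alpha_Y + p$beta_Y) / p$mu_Y
      oracle <- grid_root_oracle(function(Y)
        (p$alpha_Y + p$beta_Y * hill_activating(Y, p$hill_y_self)) *
          hill_repressing(h, p$hill_h_on_y) - p$mu_Y * Y, 0, ymax)
      expect_equal(nrow(fp), length(oracle$roots))
      expect_true(all(abs(sort(fp$Y) - sort(oracle$roots)) <=
                        oracle$resolution))
    }
  }
})

test_that("full fixed points satisfy the dynamics and include the bistable pair", {
  ep <- ref_extended()
  fp <- full_fixed_points(ep, 1)
  hs <- steady_state_h(ep$basic)
  for (i in seq_len(nrow(fp))) {
    res <- rhs_extended(c(fp$h[i], fp$X[i], fp$Y[i]), 0, ep,
                        make_constant(1, 0, 1))
    expect_lt(sqrt(sum(res^2)), 1e-9)
  }
  stable <- fp[fp$stable, ]
  expect_equal(nrow(stable), 2)
  expect_lt(abs(max(stable$h) / hs - 1), 0.01)  # adapted state at h*
  expect_lt(min(stable$h) / hs, 0.01)           # deep low state
  expect_gt(max(stable$Y), min(stable$Y) * 100)
  # stability labels come from eigenvalues with the documented sign rule
  expect_equal(fp$stable, fp$leading_eigenvalue_real < 0)
  # basic-model limit: no Y feedback leaves the single adapted state
  fp0 <- full_fixed_points(extended_params(beta_Y = 0, alpha_Y = 1e-10), 1)
  expect_equal(nrow(fp0), 1)
  expect_equal(fp0$h, hs, tolerance = 1e-6)
})

test_that("the analytic Jacobian agrees with finite differences", {
  ep <- ref_extended()
  st <- c(h = 0.8, X = 1.3, Y = 0.25)
  m <- 1.7
  J <- mir9step:::jacobian_extended(ep, st, m)
  prof <- make_constant(m, 0, 1)
  eps <- 1e-7
  for (j in 1:3) {
    stp <- st; stp[j] <- stp[j] + eps
    stm <- st; stm[j] <- stm[j] - eps
    fd <- (rhs_extended(stp, 0, ep, prof) - rhs_extended(stm, 0, ep, prof)) /
      (2 * eps)
    expect_equal(unname(J[, j]), fd, tolerance = 1e-5)
  }
})

test_that("stability labels agree with perturbed forward simulation", {
  ep <- ref_extended()
  fp <- full_fixed_points(ep, 1)
  prof <- make_constant(1, 0, 120)
  tg <- seq(0, 120, by = 0.5)
  stable <- fp[fp$stable, ]
  for (i in seq_len(nrow(stable))) {
    st <- c(stable$h[i], stable$X[i], stable$Y[i])
    tr <- simulate_extended(ep, prof, tg, init = st * c(1.01, 1, 1.01))
    expect_lt(abs(tail(tr$h, 1) - st[1]) / max(st[1], 1e-12), 1e-3)
  }
  # from just off the unstable branch, trajectories run to either basin
  un <- fp[!fp$stable, ][1, ]
  up <- simulate_extended(ep, prof, tg,
                          init = c(un$h, un$X, un$Y * 1.05))
  down <- simulate_extended(ep, prof, tg,
                            init = c(un$h, un$X, un$Y * 0.95))
  expect_gt(tail(up$Y, 1), max(fp$Y) * 0.9)
  expect_lt(tail(down$Y, 1), min(fp$Y) * 1.1)
})

test_that("classification separates the adapted and switched attractors", {
  ep <- ref_extended()
  tg <- seq(0, 80, by = 0.2)
  prof <- make_constant(1, 0, 80)
  adapted <- classify_outcome(simulate_extended(ep, prof, tg), ep)
  expect_identical(adapted$classification, "adapted")
  fp <- full_fixed_points(ep, 1)
  low <- fp[fp$stable & fp$h < 0.5, ]
  switched <- classify_outcome(
    simulate_extended(ep, prof, tg, init = c(low$h, low$X, low$Y)), ep)
  expect_identical(switched$classification, "switched")
  # an unsettled trajectory is flagged, not classified
  short <- simulate_extended(ep, make_steps(1, data.frame(t = 1, fold = 8),
                                            t0 = 0, t1 = 3),
                             seq(0, 3, by = 0.1))
  expect_warning(out <- classify_outcome(short, ep), "not settled")
  expect_identical(out$classification, "undecided")
})

test_that("classification flips exactly once as the step fold grows", {
  ep <- ref_extended()
  folds <- seq(5.4, 6.3, by = 0.05)
  cls <- vapply(folds, function(f)
    mir9step:::step_response(ep, f, t_end = 250)$classification, "")
  expect_true(all(cls %in% c("adapted", "switched")))
  expect_equal(sum(diff(cls == "switched") != 0), 1)
  expect_identical(cls[1], "adapted")
  expect_identical(cls[length(cls)], "switched")
})

test_that("the switching threshold is fold-change invariant and bracketed", {
  ep <- ref_extended()
  th <- sapply(c(0.5, 1, 2), function(m0)
    find_switching_threshold(ep, m0 = m0, fold_range = c(2, 12)))
  expect_lt(max(abs(th / th[2] - 1)), 5e-3)
  expect_gt(th[2], 1)
  # a fold barely above 1 adapts
  expect_identical(mir9step:::step_response(ep, 1.05)$classification,
                   "adapted")
  expect_error(find_switching_threshold(ep, fold_range = c(1.05, 1.1)),
               "straddle")
})

test_that("weaker repression of Y lowers the switching threshold", {
  th <- sapply(c(0.45, 0.5, 0.55), function(p0) {
    ep <- extended_params(hill_h_on_y = hill_spec(5, p0))
    find_switching_threshold(ep, fold_range = c(2, 15))
  })
  expect_true(all(diff(th) < 0))
})

test_that("the switch is irreversible at constant input (hysteresis)", {
  ep <- ref_extended()
  prof <- make_steps(1, data.frame(t = c(10, 40), fold = c(1.5, 8)),
                     t0 = 0, t1 = 150)
  tr <- simulate_extended(ep, prof, seq(0, 150, by = 0.2))
  out <- classify_outcome(tr, ep)
  expect_identical(out$classification, "switched")
  n <- nrow(tr)
  cont <- simulate_extended(ep, make_constant(tail(tr$m, 1), 0, 300),
                            seq(0, 300, by = 1),
                            init = c(tr$h[n], tr$X[n], tr$Y[n]))
  hs <- steady_state_h(ep$basic)
  expect_true(all(cont$h < 0.5 * hs))
})

test_that("feasibility flags the known failure modes", {
  feas <- check_parameter_feasibility(ref_extended())
  expect_true(feas$C1 && feas$C2 && feas$C3 && feas$feasible)
  # no self-activation: no bistable switch
  f0 <- check_parameter_feasibility(extended_params(beta_Y = 0),
                                    check_threshold = FALSE)
  expect_false(f0$C1)
  # Hill coefficient 1 on self-activation: the clamped Y branch is
  # concave and cannot be bistable
  f1 <- check_parameter_feasibility(
    extended_params(hill_y_self = hill_spec(1, 0.3)),
    check_threshold = FALSE)
  expect_false(f1$C1)
})
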