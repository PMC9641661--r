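# The generator's per-cell kinetics have the closed form
# sum_loci (p/d)(1 - exp(-d (t - onset))) for t >= onset; tests check it
# against direct numerical integration and its superposition property.

one_locus_config <- function(production, onset, decay, sd = 0, basal = 1e-6,
                             n_cells = 1) {
  locus_config(n_cells = n_cells,
               loci = data.frame(name = "L1", onset_mean = onset,
                                 onset_sd = sd, production_rate = production),
               decay_rate = decay, basal = basal, t0 = 0, t1 = 20, dt = 0.05,
               seed = 1)
}

test_that("single-locus kinetics match independent numerical integration", {
  cfg <- one_locus_config(production = 0.8, onset = 0, decay = 0.3)
  pop <- simulate_locus_activation(cfg)
  # oracle: integrate d(mir)/dt = p - d * mir from 0 with deSolve
  ode_sol <- deSolve::ode(c(m = 0), pop$t,
                          function(t, y, p) list(0.8 - 0.3 * y),
                          NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(as.numeric(pop$mature[1, ]) - cfg$basal,
               as.numeric(ode_sol[, "m"]), tolerance = 1e-7)
  # and the closed form directly
  expect_equal(as.numeric(pop$mature[1, ]) - cfg$basal,
               0.8 / 0.3 * (1 - exp(-0.3 * pop$t)), tolerance = 1e-12)
})

test_that("locus contributions are additive", {
  two <- locus_config(n_cells = 3,
                      loci = data.frame(name = c("A", "B"),
                                        onset_mean = c(0, 4), onset_sd = c(0, 0),
                                        production_rate = c(0.5, 1.2)),
                      decay_rate = 0.4, basal = 1e-6,
                      t0 = 0, t1 = 20, dt = 0.1, seed = 1)
  pop2 <- simulate_locus_activation(two)
  onlyA <- two; onlyA$loci <- two$loci[1, , drop = FALSE]
  onlyB <- two; onlyB$loci <- two$loci[2, , drop = FALSE]
  popA <- simulate_locus_activation(onlyA)
  popB <- simulate_locus_activation(onlyB)
  expect_equal(pop2$mature - two$basal,
               (popA$mature - two$basal) + (popB$mature - two$basal),
               tolerance = 1e-12)
  # two identical loci active from t0 give exactly double one locus
  twin <- two
  twin$loci <- data.frame(name = c("A", "A2"), onset_mean = c(0, 0),
                          onset_sd = c(0, 0), production_rate = c(0.5, 0.5))
  popT <- simulate_locus_activation(twin)
  expect_equal(popT$mature - two$basal, 2 * (popA$mature - two$basal),
               tolerance = 1e-12)
})

test_that("activation is irreversible and mature miR-9 stays positive", {
  pop <- simulate_locus_activation(locus_config(n_cells = 50, seed = 3))
  expect_true(all(pop$mature > 0))
  # non-decreasing per-cell trajectories are not guaranteed in general
  # (decay), but with constant active production they are here
  expect_true(all(apply(pop$mature, 1, function(x) all(diff(x) > -1e-12))))
})

test_that("population mean has an upward change-point near the late onset", {
  cfg <- locus_config(n_cells = 500, seed = 11)
  pop <- simulate_locus_activation(cfg)
  popm <- colMeans(pop$mature)
  slope <- diff(popm) / diff(pop$t)
  late <- max(cfg$loci$onset_mean)
  # steepest rise of the population profile within +/- 1 h of the mean
  # onset of the late locus
  t_max_slope <- pop$t[which.max(slope)]
  expect_lt(abs(t_max_slope - late), 1)
  # and the mean slope after onset clearly exceeds the slope before
  before <- mean(slope[pop$t[-1] > late - 3 & pop$t[-1] <= late - 1])
  after <- mean(slope[pop$t[-1] > late & pop$t[-1] <= late + 2])
  expect_gt(after, 3 * max(before, 0))
})

test_that("co-expression fractions are over positive cells and sum to one", {
  cfg <- locus_config(n_cells = 400, seed = 5)
  pop <- simulate_locus_activation(cfg)
  coex <- coexpression_fractions(pop, c(29, 30, 37, 48))
  fr <- as.matrix(coex[, c("fraction_1", "fraction_2", "fraction_3")])
  ok <- coex$n_positive > 0
  expect_true(all(abs(rowSums(fr[ok, , drop = FALSE]) - 1) < 1e-12))
  # triple-positive fraction rises through development
  f3 <- coex$fraction_3[coex$time %in% c(30, 37, 48)]
  expect_true(all(diff(f3) >= 0))
  expect_gt(f3[2], f3[1]) # striking increase once the late locus is on
})

test_that("cells with a single possible locus are all single-positive", {
  cfg <- locus_config(
    n_cells = 20,
    loci = data.frame(name = c("A", "B", "C"),
                      onset_mean = c(25, 1000, 1000), onset_sd = c(0, 0, 0),
                      production_rate = c(1, 1, 1)),
    decay_rate = 0.5, basal = 0.1, t0 = 24, t1 = 48, dt = 0.1, seed = 1)
  pop <- simulate_locus_activation(cfg)
  coex <- coexpression_fractions(pop, 30)
  expect_equal(coex$fraction_1, 1)
  expect_equal(coex$fraction_2, 0)
  expect_equal(coex$fraction_3, 0)
})

test_that("times with no positive cell give NA fractions with a warning", {
  cfg <- locus_config(
    n_cells = 10,
    loci = data.frame(name = "A", onset_mean = 40, onset_sd = 0,
                      production_rate = 1),
    decay_rate = 0.5, basal = 0.1, t0 = 24, t1 = 48, dt = 0.1, seed = 1)
  pop <- simulate_locus_activation(cfg)
  expect_warning(coex <- coexpression_fractions(pop, c(30, 45)),
                 "no precursor-positive")
  expect_true(is.na(coex$fraction_1[1]))
  expect_equal(coex$fraction_1[2], 1)
  expect_error(coexpression_fractions(pop, 100), "outside")
})

test_that("identical seeds give bit-identical populations", {
  a <- simulate_locus_activation(locus_config(n_cells = 100, seed = 8))
  b <- simulate_locus_activation(locus_config(n_cells = 100, seed = 8))
  expect_identical(a$onset, b$onset)
  expect_identical(a$mature, b$mature)
  d <- simulate_locus_activation(locus_config(n_cells = 100, seed = 9))
  expect_false(identical(a$onset, d$onset))
})

test_that("degenerate configurations are rejected", {
  expect_error(locus_config(decay_rate = 0), "decay_rate")
  expect_error(locus_config(n_cells = 0), "n_cells")
  expect_error(locus_config(loci = data.frame(
    name = "A", onset_mean = 30, onset_sd = 1, production_rate = 0)),
    "production")
  expect_error(locus_config(basal = 0), "basal")
})
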