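# a cheap analytic stand-in simulator: exponential growth whose rate is the
# fitted mu and whose scale is F_in (F_out has no effect -> flat profile)
fake_simulator <- function(p) {
  t <- seq(0, 20, by = 1)
  tibble::tibble(time_day = t,
                 V_tumor_mm3 = p[["F_in"]] * 10 * exp(p[["mu"]] * 24 * t))
}

test_that("the objective is the printed weighted double sum", {
  sim0 <- function(p) tibble::tibble(time_day = c(1, 2), V_tumor_mm3 = c(0, 0))
  ser <- cohort_series(c(1, 2), c(1, 2), c(1, 1))
  expect_equal(wls_objective(c(mu = 0), ser, sim0), 5)      # 1^2 + 2^2
  ser2 <- cohort_series(c(1, 2), c(1, 2), c(2, 2))
  expect_equal(wls_objective(c(mu = 0), ser2, sim0), 5 / 4) # sigma doubled
  # perfect fit
  p <- c(F_in = 10, mu = 0.002)
  tr <- fake_simulator(p)
  ser3 <- cohort_series(tr$time_day[-1], tr$V_tumor_mm3[-1],
                        rep(5, nrow(tr) - 1))
  expect_equal(wls_objective(p, ser3, fake_simulator), 0, tolerance = 1e-12)
})

test_that("the objective is invariant under observation order", {
  p <- c(F_in = 10, mu = 0.002)
  ser <- tibble::tibble(time_day = c(3, 9, 15), volume_mm3 = c(120, 180, 260),
                        sigma_mm3 = c(5, 7, 9))
  shuffled <- ser[c(2, 3, 1), ]
  expect_equal(wls_objective(p, ser, fake_simulator),
               wls_objective(p, shuffled, fake_simulator))
})

test_that("an observation with huge sigma has vanishing influence", {
  p <- c(F_in = 10, mu = 0.002)
  tr <- fake_simulator(p)
  ser <- cohort_series(c(tr$time_day[-1], 25), c(tr$V_tumor_mm3[-1], 1e5),
                       c(rep(5, nrow(tr) - 1), 1e9))
  expect_lt(wls_objective(p, ser, fake_simulator), 1e-6)
})

test_that("simulation failure yields a finite penalty, not an exception", {
  boom <- function(p) stop("unsimulable")
  ser <- cohort_series(1:3, c(1, 2, 3), rep(1, 3))
  val <- wls_objective(c(mu = 1), ser, boom)
  expect_true(is.finite(val))
  expect_gt(val, 1e10)
  expect_match(attr(val, "failure"), "unsimulable")
})

test_that("fitting from the optimum stays there; descent holds from elsewhere", {
  p_star <- c(F_in = 10, mu = 0.002)
  tr <- fake_simulator(p_star)
  ser <- cohort_series(tr$time_day[-1], tr$V_tumor_mm3[-1], rep(5, nrow(tr) - 1))
  fit <- fit_tumor_model(ser, free = c("F_in", "mu"), p0 = p_star,
                         n_starts = 1, seed = 1, simulator = fake_simulator)
  expect_equal(fit$p_hat, p_star, tolerance = 1e-5)
  expect_lt(fit$objective_value, 1e-8)

  p0 <- c(F_in = 13, mu = 0.0028)
  fit2 <- fit_tumor_model(ser, free = c("F_in", "mu"), p0 = p0,
                          n_starts = 1, seed = 1, simulator = fake_simulator)
  expect_lte(fit2$objective_value, wls_objective(p0, ser, fake_simulator))
  expect_equal(fit2$p_hat, p_star, tolerance = 1e-3)
  expect_true(fit2$converged)
})

test_that("fits are deterministic given seed and expose tidy/glance views", {
  p_star <- c(F_in = 10, mu = 0.002)
  tr <- fake_simulator(p_star)
  set.seed(99)
  noisy <- tr$V_tumor_mm3[-1] * exp(stats::rnorm(nrow(tr) - 1, 0, 0.05))
  ser <- cohort_series(tr$time_day[-1], noisy, pmax(0.1 * noisy, 1))
  f1 <- fit_tumor_model(ser, free = c("F_in", "mu"), p0 = c(F_in = 12, mu = 0.0025),
                        n_starts = 3, seed = 5, simulator = fake_simulator)
  f2 <- fit_tumor_model(ser, free = c("F_in", "mu"), p0 = c(F_in = 12, mu = 0.0025),
                        n_starts = 3, seed = 5, simulator = fake_simulator)
  expect_identical(f1$p_hat, f2$p_hat)
  td <- tidy(f1)
  expect_identical(td$term, c("F_in", "mu"))
  expect_false(any(td$at_bound))
  gl <- glance(f1)
  expect_equal(gl$n_obs, nrow(ser))
  expect_equal(gl$seed, 5)
})

test_that("profiles have their minimum at the fit and are flat for inert parameters", {
  p_star <- c(F_in = 10, F_out = 7, mu = 0.002)
  sim3 <- function(p) fake_simulator(p)   # F_out ignored by construction
  tr <- sim3(p_star)
  ser <- cohort_series(tr$time_day[-1], tr$V_tumor_mm3[-1], rep(5, nrow(tr) - 1))
  fit <- fit_tumor_model(ser, free = c("F_in", "F_out", "mu"), p0 = p_star,
                         n_starts = 1, seed = 1, simulator = sim3)
  prof <- profile_sensitivity(fit, ser, sim3, n = 7, span = 0.2)
  for (term in c("F_in", "mu")) {
    pr <- prof[prof$term == term, ]
    expect_equal(which.min(pr$objective), which.min(abs(pr$value - fit$p_hat[[term]])),
                 label = paste("profile minimum at estimate,", term))
    # strict convexity near the optimum: positive second difference
    i <- which.min(pr$objective)
    if (i > 1 && i < nrow(pr)) {
      expect_gt(pr$objective[i - 1] + pr$objective[i + 1] - 2 * pr$objective[i], 0)
    }
  }
  flat <- prof[prof$term == "F_out", ]
  expect_lt(max(flat$objective) - min(flat$objective), 1e-10)
})

test_that("cohort series validation enforces its invariants", {
  expect_error(cohort_series(c(1, 1), c(1, 2), c(1, 1)), "increasing")
  expect_error(cohort_series(c(1, 2), c(-1, 2), c(1, 1)), "non-negative")
  expect_error(cohort_series(c(1, 2), c(1, 2), c(0, 1)), "positive")
  ser <- cohort_series(c(1, 2), c(1, 2), c(0.2, 5))
  expect_equal(ser$sigma_mm3, c(1, 5))   # sigma floor
})
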