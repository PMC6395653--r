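test_that("the redox-gated death term follows the printed formula", {
  expect_equal(death_rate(1, 1, death_law(k_d = 0.5, n = 3, k_ratio = 2)), 0)
  # rho -> 0 limit equals k_d / k_ratio^n
  law <- death_law(k_d = 0.01, n = 2, k_ratio = 0.5)
  expect_equal(death_rate(1e-9, 1, law), 0.01 / 0.25, tolerance = 1e-6)
  # hand evaluation: k_d 0.01, n 2, k_ratio 1, rho 0.5 -> 0.01 * 0.75 / 1.25
  expect_equal(death_rate(0.5, 1, death_law(k_d = 0.01, n = 2, k_ratio = 1)),
               0.006)
  # anti-death for rho > 1, preserved as written
  expect_lt(death_rate(4, 1, death_law()), 0)
  expect_error(death_rate(1, 0, death_law()), "NADH")
})

test_that("cell-volume bridge is linear with the documented default", {
  expect_equal(volume_of_cells(0), 0)
  expect_equal(volume_of_cells(1000), 1000)  # 1e9 cells -> 1000 mm^3
  x <- stats::runif(5, 0, 5000)
  expect_equal(volume_of_cells(2 * x), 2 * volume_of_cells(x))
})

test_that("derivatives vanish when all source terms vanish", {
  model <- ll2_zero_flux_model()
  st <- initial_tumor_state(model)
  perf <- perfusion_config(F_in = 0, F_out = 0, mu_blood = 0)
  d <- derivatives(st, model, perf, growth_law(mu_max = 0),
                   death_law(k_d = 0))
  expect_true(all(abs(d$dC) < 1e-12))
  expect_true(all(abs(d$r) < 1e-12))
  expect_equal(d$dX, 0)
})

test_that("capillary and tumor volume derivatives follow the printed terms", {
  model <- ll2_zero_flux_model()
  st <- initial_tumor_state(model)
  st$V_blood <- 2
  perf <- perfusion_config(F_in = 0, F_out = 0, mu_blood = 0.01)
  d <- derivatives(st, model, perf, growth_law(mu_max = 0, mode = "constant"),
                   death_law(k_d = 0))
  expect_equal(d$dV_blood, 0.02)              # mL/h
  expect_equal(d$dV_tumor, 0.02 * 1000)       # same volume change in mm^3/h
  st_bad <- st; st_bad$V_blood <- 0
  expect_error(derivatives(st_bad, model, perf), "V_blood")
})

test_that("integrated trajectories agree with the right-hand side to first order", {
  model <- ll2_model()
  set.seed(11)
  for (i in 1:3) {
    st <- initial_tumor_state(model)
    st$m <- st$m * stats::runif(length(st$m), 0.5, 1.8)
    st$C <- st$C * stats::runif(length(st$C), 0.5, 1.8)
    perf <- perfusion_config()
    growth <- growth_law(); death <- death_law()
    h_day <- 1e-6   # well below the fastest washout mode (~V_blood/F, seconds)
    tr <- simulate_tumor(model, tumor_scenario("pbs", t_end = 11), perf = perf,
                         growth = growth, death = death, state0 = st,
                         t0 = 10, t_end = 10 + 2 * h_day, dt_out = h_day,
                         rtol = 1e-10, atol = 1e-12)
    d <- derivatives(st, model, perf, growth, death)
    fd_X <- (tr$X[2] - tr$X[1]) / (h_day * 24)
    expect_equal(fd_X, d$dX, tolerance = 1e-3)
    fd_m <- (unlist(tr[2, names(st$m)]) - unlist(tr[1, names(st$m)])) / (h_day * 24)
    scale <- max(abs(d$dm)) + 1e-6
    expect_lt(max(abs(fd_m - d$dm)) / scale, 0.02)
    fd_C <- (unlist(tr[2, names(st$C)]) - unlist(tr[1, names(st$C)])) / (h_day * 24)
    scaleC <- max(abs(d$dC)) + 1e-6
    expect_lt(max(abs(fd_C - d$dC)) / scaleC, 0.02)
  }
})

test_that("capillary volume grows exactly exponentially", {
  model <- ll2_model()
  perf <- perfusion_config(mu_blood = 0.0015)
  tr <- simulate_tumor(model, tumor_scenario("pbs"), perf = perf, t_end = 30)
  t_h <- (tr$time_day - tr$time_day[1]) * 24
  expect_equal(tr$V_blood_mL, tr$V_blood_mL[1] * exp(0.0015 * t_h),
               tolerance = 1e-5)
})

test_that("with zero flux, intracellular pools follow the dilution closed form", {
  model <- ll2_zero_flux_model()
  eps <- c(G6P = 0.05, ATP = 0.2)
  growth <- growth_law(mu_max = 0.004, mode = "constant", epsilon_m = eps)
  st <- initial_tumor_state(model)
  tr <- simulate_tumor(model, tumor_scenario("pbs"), growth = growth,
                       death = death_law(k_d = 0), state0 = st, t_end = 14)
  t_h <- (tr$time_day - 10) * 24
  for (sp in c("G6P", "ATP", "NAD", "PYR")) {
    e <- if (sp %in% names(eps)) eps[[sp]] else 0
    expected <- (st$m[[sp]] + e) * exp(-0.004 * t_h) - e
    expect_equal(tr[[sp]], expected, tolerance = 1e-4,
                 label = paste("dilution closed form,", sp))
  }
})

test_that("zero cells is an absorbing state and blood drives residual growth", {
  model <- ll2_model()
  st <- initial_tumor_state(model)
  st$X <- 0
  tr <- simulate_tumor(model, tumor_scenario("pbs"), state0 = st, t_end = 20)
  expect_true(all(abs(tr$X) < 1e-8))
  expect_true(all(diff(tr$V_tumor_mm3) > 0))
  expect_equal(diff(tr$V_tumor_mm3), 1000 * diff(tr$V_blood_mL), tolerance = 1e-6)
})

test_that("blood mass balance closes along a trajectory without capillary growth", {
  model <- ll2_model()
  perf <- perfusion_config(mu_blood = 0)
  tr <- simulate_tumor(model, tumor_scenario("pbs"), perf = perf,
                       t_end = 20, dt_out = 0.25)
  Vb <- tr$V_blood_mL[1]
  C0full <- stats::setNames(numeric(length(model$engine$blood_species)),
                            model$engine$blood_species)
  C0 <- ll2_inlet(); C0full[names(C0)] <- C0
  for (sp in c("EGLC", "LAC", "EGLN")) {
    C <- tr[[sp]]
    mid <- 2:(length(C) - 1)
    dCdt <- (C[mid + 1] - C[mid - 1]) / (2 * 0.25 * 24)       # mM/h
    Sc_row <- model$network$S_c[sp, ]
    transport <- as.matrix(tr[mid, paste0("r_", names(Sc_row))]) %*% Sc_row
    rhs <- transport * tr$X[mid] / Vb + (C0full[[sp]] * perf$F_in - C[mid] * perf$F_out) / Vb
    scale <- max(abs(transport * tr$X[mid] / Vb)) + max(abs(C[mid] * perf$F_out / Vb)) + 1e-9
    expect_lt(max(abs(dCdt - rhs)) / scale, 0.01, label = paste("mass balance", sp))
  }
})

test_that("trajectories expose the derived series and deterministic order", {
  model <- ll2_model()
  tr <- simulate_tumor(model, tumor_scenario("pbs"), t_end = 15)
  expect_identical(names(tr)[1], "time_day")
  expect_identical(names(tr)[1 + seq_along(model$engine$blood_species)],
                   model$engine$blood_species)
  expect_true(all(c("V_tumor_mm3", "nad_nadh", "r_VLDH", "r_Vresp") %in% names(tr)))
  expect_equal(tr$nad_nadh, tr$NAD / tr$NADH)
  expect_gte(min(diff(tr$time_day)), 0.49)
  # CSV round trip
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$V_tumor_mm3, tr$V_tumor_mm3)
})
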