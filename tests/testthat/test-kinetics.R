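test_that("modulation factors behave at the anchor points", {
  expect_equal(modulation_factor("inhibit", 0, 0.5), 1)
  expect_equal(modulation_factor("activate", 0, 0.5), 1)
  expect_equal(modulation_factor("inhibit", 0.5, 0.5), 0.5)
  expect_equal(modulation_factor("activate", 0.5, 0.5), 1.5)
  expect_error(modulation_factor("inhibit", -1, 0.5), "non-negative")
  # ranges over random concentrations
  conc <- exp(stats::runif(50, -5, 5))
  inh <- modulation_factor("inhibit", conc, 0.3)
  act <- modulation_factor("activate", conc, 0.3)
  expect_true(all(inh > 0 & inh <= 1))
  expect_true(all(act >= 1 & act < 2))
})

test_that("reaction_rate follows multiplicative Michaelis-Menten", {
  expect_equal(reaction_rate(0, c(S = 1), conc = c(S = 5)), 0)
  # saturation limit
  v <- reaction_rate(2, c(S = 1e-6), conc = c(S = 1))
  expect_equal(v, 2, tolerance = 1e-4)
  # hand-evaluated: vmax 1, c = km, factor 0.5 -> 0.25
  expect_equal(reaction_rate(1, c(S = 1), conc = c(S = 1), factors = 0.5), 0.25)
  expect_error(reaction_rate(1, c(S = 1), conc = c(OTHER = 1)), "missing")
  expect_error(reaction_rate(1, c(S = 1), conc = c(S = -1)), "negative")
})

test_that("flux_vector respects order, zero states and zero doses", {
  model <- ll2_model()
  eng <- model$engine
  zC <- stats::setNames(numeric(length(eng$blood_species)), eng$blood_species)
  zm <- stats::setNames(numeric(length(eng$cell_species)), eng$cell_species)
  r0 <- flux_vector(model, zm, zC)
  expect_identical(names(r0), model$network$reactions$id)
  expect_lt(max(abs(r0)), 1e-12)

  st <- initial_tumor_state(model)
  r_nodose <- flux_vector(model, st$m, st$C)
  r_zerodose <- flux_vector(model, st$m, st$C,
                            doses = c(DICLO = 0, LA = 0, HCIT = 0, MET = 0))
  expect_equal(r_nodose, r_zerodose)
  expect_error(flux_vector(model, zm[-1], zC), "missing")
})

test_that("saturating diclofenac silences its targets and only its targets", {
  model <- ll2_model()
  st <- initial_tumor_state(model)
  r0 <- flux_vector(model, st$m, st$C)
  r1 <- flux_vector(model, st$m, st$C, doses = c(DICLO = 1e6))
  expect_lte(abs(r1[["VHK"]]), 1e-3 * abs(r0[["VHK"]]))
  expect_lte(abs(r1[["VLDH"]]), 1e-3 * abs(r0[["VLDH"]]))
  untouched <- setdiff(names(r0), c("VHK", "VLDH"))
  expect_equal(r1[untouched], r0[untouched])
})

test_that("saturating metformin kills VATPase and doubles the NAD leak", {
  model <- ll2_model()
  st <- initial_tumor_state(model)
  r0 <- flux_vector(model, st$m, st$C)
  r1 <- flux_vector(model, st$m, st$C, doses = c(MET = 1e9))
  expect_lte(r1[["VATPase"]], 1e-3 * r0[["VATPase"]])
  expect_equal(r1[["VNADleak"]] / r0[["VNADleak"]], 2, tolerance = 1e-4)
})

test_that("targeted fluxes are monotone in dose and drug effects are local", {
  model <- ll2_model()
  effects <- ll2_drug_effects()
  set.seed(42)
  for (i in 1:5) {
    st <- initial_tumor_state(model)
    m <- st$m * stats::runif(length(st$m), 0.2, 3)
    C <- st$C * stats::runif(length(st$C), 0.2, 3)
    doses <- sort(exp(stats::runif(4, -4, 4)))
    for (k in seq_len(nrow(effects))) {
      eff <- effects[k, ]
      fluxes <- vapply(doses, function(d) {
        flux_vector(model, m, C, doses = stats::setNames(d, eff$drug))[[eff$target]]
      }, numeric(1))
      if (eff$mode == "inhibit") {
        expect_true(all(diff(abs(fluxes)) <= 1e-12),
                    label = paste(eff$drug, eff$target, "non-increasing"))
      } else {
        expect_true(all(diff(abs(fluxes)) >= -1e-12),
                    label = paste(eff$drug, eff$target, "non-decreasing"))
      }
      # locality: untargeted rates unchanged at identical state
      r_d <- flux_vector(model, m, C, doses = stats::setNames(doses[3], eff$drug))
      r_0 <- flux_vector(model, m, C)
      targets <- effects$target[effects$drug == eff$drug]
      expect_equal(r_d[setdiff(names(r_d), targets)],
                   r_0[setdiff(names(r_0), targets)])
    }
  }
})

test_that("kinetic model validation catches inconsistent inputs", {
  net <- ll2_network()
  rl <- ll2_rate_laws()
  expect_error(build_kinetic_model(net, rl[-1, ]), "no rate law")
  rl_bad <- rl
  rl_bad$vmax_rev[rl_bad$reaction_id == "VHK"] <- 1
  expect_error(build_kinetic_model(net, rl_bad), "irreversible")
  de_bad <- ll2_drug_effects()
  de_bad$target[1] <- "VNOPE"
  expect_error(build_kinetic_model(net, rl, de_bad), "VNOPE")
})
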