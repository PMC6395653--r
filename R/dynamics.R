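#' Perfusion, growth and death configuration
#'
#' `perfusion_config()` describes the capillary compartment: a perfectly
#' mixed vessel of volume `V_blood` continuously fed at flow `F_in` (mL/h)
#' with inlet composition `C0` (mM) and drained at `F_out`, expanding at the
#' specific rate `mu_blood` (1/h).  `F_in` and `F_out` default to a common
#' blood flow.
#'
#' @param F_in,F_out Inlet / outlet blood flow (mL/h).
#' @param C0 Named inlet concentrations covering all blood species (mM);
#'   default: packaged LL/2 values.
#' @param mu_blood Capillary specific volume increase rate (1/h).
#' @return A `perfusion_config` list.
#' @export
perfusion_config <- function(F_in = 10, F_out = F_in, C0 = ll2_inlet(),
                             mu_blood = 0.001) {
  stopifnot(F_in >= 0, F_out >= 0, mu_blood >= 0, all(C0 >= 0))
  structure(list(F_in = F_in, F_out = F_out, C0 = C0, mu_blood = mu_blood),
            class = "perfusion_config")
}

#' @rdname perfusion_config
#' @param mu_max Maximal specific growth rate of tumor cells (1/h).
#' @param mode `"flux"`: the instantaneous growth rate is `mu_max` scaled by
#'   the saturation of the biomass reaction, `mu = mu_max *
#'   r[Vgrowth]/vmax[Vgrowth]` (default for simulation); `"constant"`: `mu =
#'   mu_max` throughout (the default fitting mode).
#' @param epsilon_m Named non-negative vector (mM): fraction of intracellular
#'   metabolites incorporated into cell matter, entering the growth-dilution
#'   term `-(epsilon_m + m) * mu`.  Default zero.
#' @export
growth_law <- function(mu_max = 0.0048, mode = c("flux", "constant"),
                       epsilon_m = NULL) {
  mode <- match.arg(mode)
  stopifnot(mu_max >= 0, is.null(epsilon_m) || all(epsilon_m >= 0))
  structure(list(mu_max = mu_max, mode = mode, epsilon_m = epsilon_m),
            class = "growth_law")
}

#' @rdname perfusion_config
#' @param k_d Maximal death rate (1/h).
#' @param n Hill exponent of the redox gate.
#' @param k_ratio Half-effect NAD+/NADH ratio.
#' @export
death_law <- function(k_d = 0.0022, n = 4, k_ratio = 1) {
  stopifnot(k_d >= 0, n > 0, k_ratio > 0)
  structure(list(k_d = k_d, n = n, k_ratio = k_ratio), class = "death_law")
}

#' Redox-gated death rate
#'
#' Evaluates the death term gating tumor cell loss on the intracellular
#' NAD+/NADH ratio `rho`: `k_d * (1 - rho^n) / (k_ratio^n + rho^n)`.  The
#' formula is kept exactly as written: for `rho > 1` it is negative (a net
#' pro-survival contribution), which is what lets a Warburg-state tumor
#' (high NAD+/NADH) grow faster than `mu` alone.
#'
#' @param nad,nadh NAD+ and NADH concentrations (mM); `nadh` must be
#'   positive.
#' @param law A [death_law()].
#' @return Death rate (1/h), possibly negative.
#' @export
death_rate <- function(nad, nadh, law = death_law()) {
  if (any(nadh <= 0)) stop("NADH must be positive (NAD/NADH ratio undefined)", call. = FALSE)
  rho <- nad / nadh
  law$k_d * (1 - rho^law$n) / (law$k_ratio^law$n + rho^law$n)
}

#' Cell-number to volume bridge
#'
#' Converts tumor cell amount (units of 1e6 cells) to mm^3 using the
#' single-cell volume constant `v_cell`; the default `1e-6` mm^3/cell makes
#' 1e9 cells equal 1 cm^3.
#'
#' @param X Cell amount (1e6 cells), non-negative.
#' @param v_cell Single-cell volume (mm^3/cell).
#' @return Volume (mm^3).
#' @export
volume_of_cells <- function(X, v_cell = 1e-6) {
  stopifnot(all(X >= 0), v_cell > 0)
  X * 1e6 * v_cell
}

#' Packaged inlet composition and intracellular initial state
#'
#' @return Named numeric vectors (mM): `ll2_inlet()` the default inlet blood
#'   composition `C0`; `ll2_initial_m()` the default intracellular
#'   concentrations at the simulation start.
#' @export
ll2_inlet <- function() {
  tab <- read_initial_state_table()
  x <- tab[tab$role == "C0", ]
  stats::setNames(x$value, x$species)
}

#' @rdname ll2_inlet
#' @export
ll2_initial_m <- function() {
  tab <- read_initial_state_table()
  x <- tab[tab$role == "m0", ]
  stats::setNames(x$value, x$species)
}

read_initial_state_table <- function() {
  p <- system.file("extdata", "ll2_initial_state.tsv", package = "warburgsim")
  tab <- read_network_table(p, c("species", "role", "value"))
  tab$value <- as.numeric(tab$value)
  tab
}

#' Initial tumor state
#'
#' Splits an initial tumor volume into cells and capillary blood by a blood
#' volume fraction, with blood concentrations set to the inlet composition
#' and intracellular concentrations from the packaged defaults.
#'
#' @param model A `kinetic_model`.
#' @param V_tumor Initial tumor volume (mm^3); default 154 at day 10.
#' @param blood_fraction Fraction of tumor volume that is capillary blood.
#' @param C,m Optional overrides (named, mM).
#' @param v_cell Single-cell volume (mm^3/cell).
#' @return A `tumor_state` list with fields `C`, `m`, `X` (1e6 cells),
#'   `V_blood` (mL), `V_tumor` (mm^3).
#' @export
initial_tumor_state <- function(model, V_tumor = 154, blood_fraction = 0.1,
                                C = NULL, m = NULL, v_cell = 1e-6) {
  eng <- model$engine
  C_full <- stats::setNames(numeric(length(eng$blood_species)), eng$blood_species)
  C0 <- ll2_inlet()
  C_full[names(C0)] <- C0
  tab <- read_initial_state_table()
  init <- tab[tab$role == "Cinit", ]
  C_full[init$species] <- init$value
  if (!is.null(C)) C_full[names(C)] <- C
  m_full <- stats::setNames(numeric(length(eng$cell_species)), eng$cell_species)
  m0 <- ll2_initial_m()
  m_full[names(m0)] <- m0
  if (!is.null(m)) m_full[names(m)] <- m
  V_blood_mm3 <- V_tumor * blood_fraction
  X <- (V_tumor - V_blood_mm3) / (1e6 * v_cell)
  structure(
    list(C = C_full, m = m_full, X = X,
         V_blood = V_blood_mm3 / 1000, V_tumor = V_tumor, v_cell = v_cell),
    class = "tumor_state"
  )
}

#' Right-hand side of the tumor dynamical system
#'
#' Evaluates the five coupled blocks at a given state: blood metabolites in
#' the perfused capillary compartment, intracellular metabolites with growth
#' dilution, tumor cell amount with the redox-gated death term, capillary
#' volume, and total tumor volume:
#'
#' * `dC/dt = S_c r X / V_blood + (C0 F_in - C F_out) / V_blood - mu_blood C`
#' * `dm/dt = S_m r - (epsilon_m + m) mu`
#' * `dX/dt = mu X - k_d (1 - rho^n) / (k_ratio^n + rho^n) X`, `rho = NAD/NADH`
#' * `dV_blood/dt = mu_blood V_blood`
#' * `dV_tumor/dt = dX/dt + dV_blood/dt` (cell units bridged to mm^3 by
#'   `v_cell`)
#'
#' @param state A `tumor_state` (or list with fields `C`, `m`, `X`,
#'   `V_blood`).
#' @param model A `kinetic_model`.
#' @param perf A [perfusion_config()]; `C0` may be modified by dosing.
#' @param growth A [growth_law()].
#' @param death A [death_law()].
#' @param doses Named drug concentrations (mM); default: drug entries of
#'   `state$C`.
#' @param v_cell Single-cell volume (mm^3/cell).
#' @return List with `dC`, `dm`, `dX`, `dV_blood`, `dV_tumor` (per hour),
#'   plus the flux vector `r` and instantaneous `mu` and `death` rates.
#' @export
derivatives <- function(state, model, perf, growth = growth_law(),
                        death = death_law(), doses = NULL, v_cell = 1e-6) {
  if (state$V_blood <= 0) stop("V_blood must be positive", call. = FALSE)
  eng <- model$engine
  C <- pmax(state$C, 0)
  m <- pmax(state$m, 0)
  r <- flux_vector(model, m, C, doses)
  mu <- instantaneous_mu(growth, model, r)
  dth <- death_rate(m[["NAD"]], m[["NADH"]], death)
  C0 <- stats::setNames(numeric(length(eng$blood_species)), eng$blood_species)
  C0[names(perf$C0)] <- perf$C0
  dC <- drop(model$network$S_c %*% r) * state$X / state$V_blood +
    (C0 * perf$F_in - C * perf$F_out) / state$V_blood - perf$mu_blood * C
  eps <- stats::setNames(numeric(length(m)), names(m))
  if (!is.null(growth$epsilon_m)) eps[names(growth$epsilon_m)] <- growth$epsilon_m
  dm <- drop(model$network$S_m %*% r) - (eps + m) * mu
  dX <- (mu - dth) * state$X
  dVb <- perf$mu_blood * state$V_blood
  dVt <- dX * 1e6 * v_cell + dVb * 1000
  list(dC = stats::setNames(dC, names(C)), dm = stats::setNames(dm, names(m)),
       dX = dX, dV_blood = dVb, dV_tumor = dVt,
       r = r, mu = mu, death = dth)
}

instantaneous_mu <- function(growth, model, r) {
  if (growth$mode == "constant") return(growth$mu_max)
  j <- match("Vgrowth", model$engine$rxn_ids)
  vg <- model$engine$vmax[j]
  if (vg <= 0) return(0)
  growth$mu_max * r[[j]] / vg
}

#' Simulate tumor growth
#'
#' Integrates the tumor dynamical system with a stiff-capable implicit
#' solver (`deSolve::lsoda`).  Drug exposure follows the scenario: inlet
#' drug concentrations step from zero to the scenario doses at the treatment
#' start day, so the integration is split at that discontinuity.
#'
#' Negative-state handling: concentrations are clipped at zero for rate-law
#' evaluation inside the solver; output states below `-neg_tol` raise a
#' diagnostic error naming the first offending time, values in
#' `[-neg_tol, 0)` are clipped in the returned trajectory.
#'
#' @param model A `kinetic_model`.
#' @param scenario A [tumor_scenario()] (treatment arm: doses + timing).
#' @param perf,growth,death Configuration objects (defaults: calibrated
#'   LL/2 values).
#' @param state0 Initial [initial_tumor_state()]; default 154 mm^3 at `t0`.
#' @param t0,t_end Simulation window (days post-inoculation); defaults from
#'   the scenario.
#' @param dt_out Output grid spacing (days).
#' @param rtol,atol Integrator tolerances.
#' @param neg_tol Negative-state tolerance (mM).
#' @param v_cell Single-cell volume (mm^3/cell).
#' @return A `tumor_trajectory` tibble: `time_day`, every blood species,
#'   every intracellular species, `X`, `V_blood_mL`, `V_tumor_mm3`,
#'   `nad_nadh`, `mu`, `death`, and every flux as `r_<reaction>`.
#' @export
simulate_tumor <- function(model, scenario = tumor_scenario("pbs"),
                           perf = perfusion_config(), growth = growth_law(),
                           death = death_law(), state0 = NULL,
                           t0 = scenario$t0, t_end = scenario$t_end,
                           dt_out = 0.5, rtol = 1e-6, atol = 1e-9,
                           neg_tol = 1e-6, v_cell = 1e-6) {
  stopifnot(inherits(model, "kinetic_model"), t_end > t0)
  if (is.null(state0)) state0 <- initial_tumor_state(model, v_cell = v_cell)
  eng <- model$engine
  nC <- length(eng$blood_species); nm <- length(eng$cell_species)
  y0 <- c(state0$C, state0$m, X = state0$X,
          V_blood = state0$V_blood, V_tumor = state0$V_tumor)

  # lean right-hand side over plain numeric indices; equals derivatives()
  # (checked by the test suite) but avoids per-call name handling
  ns <- nC + nm
  Sc <- unname(model$network$S_c); Sm <- unname(model$network$S_m)
  iNAD <- nC + match("NAD", eng$cell_species)
  iNADH <- nC + match("NADH", eng$cell_species)
  eps_m <- numeric(nm)
  if (!is.null(growth$epsilon_m)) {
    eps_m[match(names(growth$epsilon_m), eng$cell_species)] <- growth$epsilon_m
  }
  vg <- eng$vmax[eng$growth_j]
  eff <- eng$eff
  rhs <- function(t, y, parms) {
    conc <- y[seq_len(ns)]
    conc[conc < 0] <- 0
    sf <- conc[eng$fwd$sp] / (eng$fwd$km + conc[eng$fwd$sp])
    v <- eng$vmax * drop(exp(eng$fwd$A %*% log(pmax(sf, 1e-300))))
    if (length(eng$rev$rxn)) {
      sr <- conc[eng$rev$sp] / (eng$rev$km + conc[eng$rev$sp])
      v <- v - eng$vmax_rev * drop(exp(eng$rev$A %*% log(pmax(sr, 1e-300))))
    }
    if (length(eff$rxn)) {
      d <- conc[eff$sp]
      fac <- numeric(length(d))
      fac[eff$inhibit] <- eff$k_half[eff$inhibit] /
        (eff$k_half[eff$inhibit] + d[eff$inhibit])
      fac[!eff$inhibit] <- 1 + d[!eff$inhibit] /
        (eff$k_half[!eff$inhibit] + d[!eff$inhibit])
      for (i in seq_along(eff$rxn)) v[eff$rxn[i]] <- v[eff$rxn[i]] * fac[i]
    }
    mu <- if (growth$mode == "constant") growth$mu_max else
      if (vg > 0) growth$mu_max * v[eng$growth_j] / vg else 0
    rho <- conc[iNAD] / max(conc[iNADH], 1e-12)
    dth <- death$k_d * (1 - rho^death$n) / (death$k_ratio^death$n + rho^death$n)
    X <- max(y[ns + 1L], 0); Vb <- y[ns + 2L]
    Cv <- conc[seq_len(nC)]
    dC <- drop(Sc %*% v) * X / Vb +
      (parms$C0 * parms$F_in - Cv * parms$F_out) / Vb - parms$mu_blood * Cv
    dm <- drop(Sm %*% v) - (eps_m + conc[nC + seq_len(nm)]) * mu
    dX <- (mu - dth) * X
    dVb <- parms$mu_blood * Vb
    list(c(dC, dm, dX, dVb, dX * 1e6 * v_cell + dVb * 1000))
  }

  t_treat <- scenario$t_start
  dosed <- perf
  dosed$C0[names(scenario$doses)] <- scenario$doses
  as_parms <- function(p) {
    C0 <- stats::setNames(numeric(nC), eng$blood_species)
    C0[names(p$C0)] <- p$C0
    list(C0 = unname(C0), F_in = p$F_in, F_out = p$F_out, mu_blood = p$mu_blood)
  }
  segments <- if (length(scenario$doses) && t_treat > t0 && t_treat < t_end) {
    list(list(times = seq(t0, t_treat, by = dt_out), parms = as_parms(perf)),
         list(times = seq(t_treat, t_end, by = dt_out), parms = as_parms(dosed)))
  } else if (length(scenario$doses) && t_treat <= t0) {
    list(list(times = seq(t0, t_end, by = dt_out), parms = as_parms(dosed)))
  } else {
    list(list(times = seq(t0, t_end, by = dt_out), parms = as_parms(perf)))
  }

  # compiled right-hand side (same math as rhs above) when the package DLL
  # is loaded; the plain-R closure remains as reference and fallback
  compiled <- is.loaded("warburgsim_derivs")
  pack_parms <- function(pp) {
    mode_flux <- as.numeric(growth$mode == "flux")
    pv <- c(nC, nm, eng$n_rxn,
            length(eng$fwd$rxn), length(eng$rev$rxn), length(eng$eff$rxn),
            eng$vmax, eng$vmax_rev,
            eng$fwd$sp - 1, eng$fwd$rxn - 1, eng$fwd$km,
            eng$rev$sp - 1, eng$rev$rxn - 1, eng$rev$km,
            eng$eff$rxn - 1, eng$eff$sp - 1, as.numeric(eng$eff$inhibit),
            eng$eff$k_half,
            eng$growth_j - 1, growth$mu_max, mode_flux, vg,
            eps_m, iNAD - 1, iNADH - 1,
            death$k_d, death$n, death$k_ratio,
            pp$C0, pp$F_in, pp$F_out, pp$mu_blood, v_cell,
            as.vector(Sc), as.vector(Sm))
    c(pv, numeric(4096 - length(pv)))
  }
  rows <- list()
  y <- y0
  for (k in seq_along(segments)) {
    seg <- segments[[k]]
    times_h <- seg$times * 24
    out <- tryCatch(
      if (compiled) {
        deSolve::lsoda(y, times_h, func = "warburgsim_derivs",
                       parms = pack_parms(seg$parms), dllname = "warburgsim",
                       initfunc = "warburgsim_init",
                       rtol = rtol, atol = atol, maxsteps = 20000)
      } else {
        deSolve::lsoda(y, times_h, rhs, parms = seg$parms,
                       rtol = rtol, atol = atol, maxsteps = 20000)
      },
      warning = function(w) {
        stop("integrator failure: ", conditionMessage(w), call. = FALSE)
      }
    )
    if (nrow(out) < length(times_h)) {
      stop("integrator failure: stopped at t = ",
           signif(out[nrow(out), 1] / 24, 4), " days", call. = FALSE)
    }
    rows[[k]] <- if (k == 1) out else out[-1, , drop = FALSE]
    y <- out[nrow(out), -1]
  }
  raw <- do.call(rbind, rows)
  states <- raw[, -1, drop = FALSE]
  min_state <- min(states[, seq_len(nC + nm)])
  if (min_state < -neg_tol) {
    bad <- which(states[, seq_len(nC + nm)] < -neg_tol, arr.ind = TRUE)[1, 1]
    stop("negative state beyond tolerance at day ",
         signif(raw[bad, 1] / 24, 4), " (min ", signif(min_state, 3), " mM)",
         call. = FALSE)
  }
  states[, seq_len(nC + nm)] <- pmax(states[, seq_len(nC + nm)], 0)

  # per-row fluxes and rates on the output grid
  dose_active <- raw[, 1] / 24 >= t_treat & length(scenario$doses) > 0
  fl <- matrix(0, nrow(raw), eng$n_rxn, dimnames = list(NULL, paste0("r_", eng$rxn_ids)))
  mu_v <- numeric(nrow(raw)); death_v <- numeric(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    Ci <- stats::setNames(states[i, seq_len(nC)], eng$blood_species)
    mi <- stats::setNames(states[i, nC + seq_len(nm)], eng$cell_species)
    r <- flux_vector(model, mi, Ci)
    fl[i, ] <- r
    mu_v[i] <- instantaneous_mu(growth, model, r)
    death_v[i] <- death_rate(mi[["NAD"]], max(mi[["NADH"]], 1e-12), death)
  }
  traj <- tibble::as_tibble(as.data.frame(states))
  names(traj) <- c(eng$blood_species, eng$cell_species, "X", "V_blood_mL", "V_tumor_mm3")
  traj <- tibble::add_column(traj, time_day = raw[, 1] / 24, .before = 1)
  traj$nad_nadh <- traj$NAD / traj$NADH
  traj$mu <- mu_v
  traj$death <- death_v
  traj <- dplyr::bind_cols(traj, tibble::as_tibble(as.data.frame(fl)))
  class(traj) <- c("tumor_trajectory", class(traj))
  attr(traj, "scenario") <- scenario
  attr(traj, "config") <- list(perf = perf, growth = growth, death = death,
                               v_cell = v_cell, rtol = rtol, atol = atol)
  traj
}

#' Write a trajectory to CSV
#'
#' @param traj A `tumor_trajectory`.
#' @param path Output CSV path.
#' @return Invisibly, the trajectory.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(tibble::as_tibble(traj), path)
  invisible(traj)
}
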