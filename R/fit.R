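#' Cohort volume series
#'
#' Validates and normalises a tumor-volume series for fitting: a tibble with
#' `time_day` (strictly increasing), `volume_mm3` (non-negative observed
#' means) and `sigma_mm3` (positive weights, floored at 1 mm^3 to avoid
#' division blow-up near the start).
#'
#' @param time_day,volume_mm3,sigma_mm3 Numeric vectors of equal length.
#' @param arm Scenario label.
#' @param sigma_floor Lower bound applied to `sigma_mm3` (mm^3).
#' @return A `cohort_series` tibble.
#' @export
cohort_series <- function(time_day, volume_mm3, sigma_mm3, arm = "pbs",
                          sigma_floor = 1) {
  stopifnot(length(time_day) == length(volume_mm3),
            length(time_day) == length(sigma_mm3))
  if (any(diff(time_day) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(volume_mm3 < 0)) stop("volumes must be non-negative", call. = FALSE)
  if (any(sigma_mm3 <= 0)) stop("sigma must be positive", call. = FALSE)
  out <- tibble::tibble(time_day = time_day, volume_mm3 = volume_mm3,
                        sigma_mm3 = pmax(sigma_mm3, sigma_floor))
  attr(out, "arm") <- arm
  class(out) <- c("cohort_series", class(out))
  out
}

#' Read / write a cohort series CSV
#'
#' CSV columns: `time_day`, `volume_mm3`, `sigma_mm3` (and optionally
#' `mouse_id`, ignored here — see [summarize_cohort()] for per-mouse data).
#'
#' @param path CSV path.
#' @return A `cohort_series`.
#' @export
read_cohort_series <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_day", "volume_mm3", "sigma_mm3")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("cohort CSV lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  cohort_series(tab$time_day, tab$volume_mm3, tab$sigma_mm3)
}

#' Weighted least-squares objective
#'
#' The fitting objective: `sum(((y_obs - y_model(p)) / sigma)^2)` over all
#' observations, with the model volume interpolated from the simulated
#' trajectory at each observation time.  Simulation failures return a large
#' finite penalty (1e12) so optimizers survive bad parameter regions; the
#' failure message is attached as attribute `failure`.
#'
#' @param p Named parameter vector (subset of `F_in`, `F_out`, `mu`).
#' @param series A [cohort_series()].
#' @param simulator Function `p -> tumor_trajectory` (see
#'   [make_simulator()]).
#' @return Scalar objective (0 for a perfect fit).
#' @export
wls_objective <- function(p, series, simulator) {
  traj <- tryCatch(simulator(p), error = function(e) e)
  if (inherits(traj, "error")) {
    out <- 1e12
    attr(out, "failure") <- conditionMessage(traj)
    return(out)
  }
  y_hat <- stats::approx(traj$time_day, traj$V_tumor_mm3,
                         xout = series$time_day, rule = 2)$y
  sum(((series$volume_mm3 - y_hat) / series$sigma_mm3)^2)
}

#' Bind a model and scenario into a parameter-to-trajectory simulator
#'
#' Returns a function mapping a named parameter vector (any subset of
#' `F_in`, `F_out`, `mu`) to a simulated trajectory; unnamed parameters keep
#' their configured values.  The growth law uses the constant-mu fitting
#' mode, matching the treatment of mu as a directly fitted sensitive
#' parameter.
#'
#' @param model A `kinetic_model`.
#' @param scenario A [tumor_scenario()].
#' @param perf,growth,death Base configuration (defaults: calibrated
#'   values); `growth$mode` is forced to `"constant"` unless `mu_mode`
#'   says otherwise.
#' @param mu_mode `"constant"` (default for fitting) or `"flux"`.
#' @param rtol,atol,dt_out Integration control for fitting runs (slightly
#'   looser/coarser than simulation defaults for speed).
#' @param ... Passed to [simulate_tumor()].
#' @return Function `p -> tumor_trajectory`.
#' @export
make_simulator <- function(model, scenario = tumor_scenario("pbs"),
                           perf = perfusion_config(), growth = growth_law(),
                           death = death_law(),
                           mu_mode = c("constant", "flux"),
                           rtol = 1e-6, atol = 1e-9, dt_out = 1, ...) {
  mu_mode <- match.arg(mu_mode)
  function(p) {
    pf <- perf
    if ("F_in" %in% names(p)) {
      pf$F_in <- unname(p[["F_in"]])
      # inlet and outlet flows default to equal (the printed system has one F):
      # when F_out is not itself fitted it follows F_in
      if (!("F_out" %in% names(p))) pf$F_out <- pf$F_in
    }
    if ("F_out" %in% names(p)) pf$F_out <- unname(p[["F_out"]])
    gr <- growth
    gr$mode <- mu_mode
    if ("mu" %in% names(p)) gr$mu_max <- unname(p[["mu"]])
    simulate_tumor(model, scenario, perf = pf, growth = gr, death = death,
                   rtol = rtol, atol = atol, dt_out = dt_out, ...)
  }
}

#' Fit sensitive parameters by weighted least squares
#'
#' Bound-constrained local minimisation of [wls_objective()] over the
#' sensitive parameters (blood inflow `F_in`, outflow `F_out` and specific
#' growth rate `mu`), via `optim(method = "L-BFGS-B")`.  A seeded
#' multi-start (default 5 starts: `p0` plus jittered copies) hedges local
#' minima; set `n_starts = 1` to reproduce a plain single local search.
#'
#' @param series A [cohort_series()] (or per-mouse cohort summarised first).
#' @param model A `kinetic_model`.
#' @param scenario Scenario to fit under.
#' @param free Names of free parameters (subset of `F_in`, `F_out`, `mu`).
#' @param p0 Named initial guess (defaults: configured values).
#' @param lower,upper Named bounds.
#' @param n_starts Number of seeded starts.
#' @param seed Integer seed controlling start-point jitter.
#' @param maxit Max iterations per start.
#' @param factr `optim` L-BFGS-B convergence factor (lower = tighter).
#' @param polish Refine the best start with a derivative-free Nelder-Mead
#'   stage (helps along nearly flat parameter ridges).
#' @param simulator Optional custom simulator (default built by
#'   [make_simulator()]).
#' @param ... Passed to [make_simulator()].
#' @return A `tumor_fit` object with elements `p_hat`, `objective_value`,
#'   `converged`, `n_evaluations`, `p0`, `bounds`, `seed`, `starts`.
#' @export
fit_tumor_model <- function(series, model = ll2_model(),
                            scenario = tumor_scenario("pbs"),
                            free = c("F_in", "F_out", "mu"),
                            p0 = NULL, lower = NULL, upper = NULL,
                            n_starts = 5, seed = 1, maxit = 200, factr = 1e5,
                            polish = TRUE,
                            simulator = NULL, ...) {
  defaults <- c(F_in = perfusion_config()$F_in, F_out = perfusion_config()$F_out,
                mu = growth_law()$mu_max)
  lo_def <- c(F_in = 2, F_out = 2, mu = 5e-4)
  hi_def <- c(F_in = 40, F_out = 40, mu = 0.02)
  free <- match.arg(free, c("F_in", "F_out", "mu"), several.ok = TRUE)
  p0 <- if (is.null(p0)) defaults[free] else p0[free]
  lower <- if (is.null(lower)) lo_def[free] else lower[free]
  upper <- if (is.null(upper)) hi_def[free] else upper[free]
  stopifnot(all(is.finite(c(lower, upper))), all(lower < upper),
            all(p0 >= lower), all(p0 <= upper))
  if (is.null(simulator)) simulator <- make_simulator(model, scenario, ...)

  n_eval <- 0L
  obj <- function(x) {
    n_eval <<- n_eval + 1L
    wls_objective(stats::setNames(x, free), series, simulator)
  }
  set.seed(seed)
  starts <- list(p0)
  if (n_starts > 1) {
    for (k in seq_len(n_starts - 1)) {
      jit <- p0 * stats::runif(length(p0), 0.8, 1.25)
      starts[[k + 1]] <- pmin(pmax(jit, lower), upper)
    }
  }
  results <- lapply(starts, function(st) {
    tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = maxit, factr = factr,
                                  parscale = pmax(abs(st), 1e-4))),
      error = function(e) list(par = st, value = Inf, convergence = 99L)
    )
  })
  best <- results[[which.min(vapply(results, `[[`, numeric(1), "value"))]]
  if (polish && is.finite(best$value) && best$value > 0) {
    ref <- tryCatch(
      if (length(best$par) > 1) {
        stats::optim(best$par, obj, method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-12,
                                    parscale = pmax(abs(best$par), 1e-4)))
      } else {
        stats::optim(best$par, obj, method = "Brent",
                     lower = lower, upper = upper)
      },
      error = function(e) NULL
    )
    if (!is.null(ref) && ref$value <= best$value + 1e-5 * (1 + abs(best$value))) {
      if (ref$value <= best$value) best$par <- pmin(pmax(ref$par, lower), upper)
      best$value <- min(ref$value, best$value)
      # two independent local methods agree: report convergence
      best$convergence <- 0L
    }
  }
  structure(
    list(
      p_hat = stats::setNames(best$par, free),
      objective_value = best$value,
      converged = best$convergence == 0L,
      n_evaluations = n_eval,
      p0 = p0, lower = lower, upper = upper,
      seed = seed, n_starts = n_starts,
      n_obs = nrow(series),
      starts = lapply(results, function(r) list(par = r$par, value = r$value))
    ),
    class = "tumor_fit"
  )
}

#' @export
print.tumor_fit <- function(x, ...) {
  cat("<tumor_fit> weighted least-squares fit\n")
  cat("estimates:", paste(names(x$p_hat), signif(x$p_hat, 5),
                          sep = " = ", collapse = ", "), "\n")
  cat("objective:", signif(x$objective_value, 6),
      " converged:", x$converged,
      " evaluations:", x$n_evaluations,
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Tidy and glance methods for fits
#'
#' `tidy()` returns one row per fitted parameter (`term`, `estimate`,
#' `lower`, `upper`, `at_bound`); `glance()` a one-row model summary.
#'
#' @param x A `tumor_fit`.
#' @param ... Unused.
#' @export
tidy.tumor_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$p_hat),
    estimate = unname(x$p_hat),
    lower = unname(x$lower),
    upper = unname(x$upper),
    at_bound = unname(x$p_hat <= x$lower + 1e-12 | x$p_hat >= x$upper - 1e-12)
  )
}

#' @rdname tidy.tumor_fit
#' @export
glance.tumor_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective_value,
    converged = x$converged,
    n_evaluations = x$n_evaluations,
    n_obs = x$n_obs,
    n_starts = x$n_starts,
    seed = x$seed
  )
}

#' Profile the objective along each fitted parameter
#'
#' Evaluates the objective on a 1-D grid per free parameter with the other
#' parameters held at the fitted optimum — a direct picture of why the flows
#' and growth rate are (or are not) well-determined by tumor-volume data.
#'
#' @param fit A `tumor_fit`.
#' @param series The data used for the fit.
#' @param simulator The simulator used for the fit (rebuild with
#'   [make_simulator()] if not kept).
#' @param n Grid points per parameter.
#' @param span Multiplicative half-range of the grid around each estimate.
#' @return A tibble with `term`, `value`, `objective`.
#' @export
profile_sensitivity <- function(fit, series, simulator, n = 11, span = 0.3) {
  stopifnot(inherits(fit, "tumor_fit"))
  out <- list()
  for (term in names(fit$p_hat)) {
    center <- fit$p_hat[[term]]
    grid <- seq(max(center * (1 - span), fit$lower[[term]]),
                min(center * (1 + span), fit$upper[[term]]), length.out = n)
    vals <- vapply(grid, function(g) {
      p <- fit$p_hat
      p[[term]] <- g
      wls_objective(p, series, simulator)
    }, numeric(1))
    out[[term]] <- tibble::tibble(term = term, value = grid, objective = vals)
  }
  dplyr::bind_rows(out)
}
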