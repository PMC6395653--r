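#' Treatment scenarios
#'
#' Constructs a named treatment arm.  Dose levels map to constant inlet
#' blood concentrations as multiples of each drug's half-effect constant
#' (`low` = 1x `k_half`, `high` = 10x), applied as a step input from the
#' treatment start day — pharmacokinetics are deliberately reduced to a
#' steady exposure.  The predefined arms are:
#'
#' * `pbs` — untreated control;
#' * `cisplatin_reference` — data-only reference arm (cisplatin is an
#'   antimitotic outside the metabolic network; the arm is kept for overlay
#'   comparisons and is not mechanistically simulable);
#' * `metabloc` — alpha-lipoic acid + hydroxycitrate;
#' * `metabloc_met_low`, `metabloc_met_high` — METABLOC + metformin;
#' * `metabloc_diclo_low`, `metabloc_diclo_high` — METABLOC + diclofenac;
#' * `metablocs_full` — METABLOC + high metformin + high diclofenac;
#' * `custom` — caller-supplied `doses`.
#'
#' @param name Arm name (see above).
#' @param doses Named drug concentrations (mM) for `custom`, or to override
#'   the predefined mapping.
#' @param t_start Treatment start day (default 12, when tumors reach about
#'   130 mm^3).
#' @param t0,t_end Simulation window (days post-inoculation).
#' @param drug_effects Drug-effect table supplying `k_half` values.
#' @return A `tumor_scenario` list.
#' @export
tumor_scenario <- function(name = "pbs", doses = NULL, t_start = 12,
                           t0 = 10, t_end = 59,
                           drug_effects = ll2_drug_effects()) {
  known <- c("pbs", "cisplatin_reference", "metabloc", "metabloc_met_low",
             "metabloc_met_high", "metabloc_diclo_low", "metabloc_diclo_high",
             "metablocs_full", "custom")
  name <- match.arg(name, known)
  k <- vapply(split(drug_effects$k_half, drug_effects$drug), min, numeric(1))
  lvl <- function(drug, mult) stats::setNames(mult * k[[drug]], drug)
  base <- switch(name,
    pbs = numeric(0),
    cisplatin_reference = numeric(0),
    metabloc = c(lvl("LA", 1), lvl("HCIT", 1)),
    metabloc_met_low = c(lvl("LA", 1), lvl("HCIT", 1), lvl("MET", 1)),
    metabloc_met_high = c(lvl("LA", 1), lvl("HCIT", 1), lvl("MET", 10)),
    metabloc_diclo_low = c(lvl("LA", 1), lvl("HCIT", 1), lvl("DICLO", 1)),
    metabloc_diclo_high = c(lvl("LA", 1), lvl("HCIT", 1), lvl("DICLO", 10)),
    metablocs_full = c(lvl("LA", 1), lvl("HCIT", 1), lvl("MET", 10),
                       lvl("DICLO", 10)),
    custom = numeric(0)
  )
  if (!is.null(doses)) {
    stopifnot(all(doses >= 0))
    base[names(doses)] <- doses
  }
  structure(
    list(name = name, doses = base[base > 0], t_start = t_start,
         t0 = t0, t_end = t_end,
         mechanistic = name != "cisplatin_reference"),
    class = "tumor_scenario"
  )
}

#' @export
print.tumor_scenario <- function(x, ...) {
  cat("<tumor_scenario> ", x$name,
      if (!x$mechanistic) " (data-only reference)", "\n", sep = "")
  if (length(x$doses)) {
    cat("doses (mM):", paste(names(x$doses), signif(x$doses, 3),
                             sep = "=", collapse = ", "), "\n")
  }
  cat("days ", x$t0, "-", x$t_end, ", treatment from day ", x$t_start, "\n", sep = "")
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Loads (or takes) a model, simulates each requested arm, enumerates the
#' minimal cut sets for the growth target, optionally fits parameters to a
#' supplied cohort CSV, and writes all artifacts to a run directory:
#' per-arm trajectory CSVs, a cut-set report, a summary table of final
#' volumes, a fit report if data were given, and a provenance log.
#'
#' @param arms Character vector of scenario names (at least one).
#' @param outdir Output directory (created if missing).
#' @param model A `kinetic_model` (default: packaged LL/2 model).
#' @param seed Integer seed recorded in the log and used for any stochastic
#'   step (fitting multi-start jitter).
#' @param data Optional cohort CSV path (columns `time_day`, `volume_mm3`,
#'   `sigma_mm3`) to fit against; fitted arm is the first in `arms`.
#' @param cutset_target Target reaction for structural analysis.
#' @param ... Passed to [simulate_tumor()].
#' @return Invisibly, a list with the summary tibble and artifact paths.
#' @export
run_pipeline <- function(arms, outdir, model = ll2_model(), seed = 1,
                         data = NULL, cutset_target = "Vgrowth", ...) {
  if (length(arms) == 0) stop("no scenarios requested", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  trajs <- list(); errors <- list()
  for (a in arms) {
    sc <- tumor_scenario(a)
    if (!sc$mechanistic) next
    res <- tryCatch(simulate_tumor(model, sc, ...), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[a]] <- conditionMessage(res)
    } else {
      trajs[[a]] <- res
      write_trajectory(res, file.path(outdir, paste0("trajectory_", a, ".csv")))
    }
  }
  cs <- minimal_cut_sets(model$network, cutset_target)
  write_cutset_report(cs, file.path(outdir, "cutsets.tsv"))
  fit <- NULL
  if (!is.null(data)) {
    series <- read_cohort_series(data)
    fit <- fit_tumor_model(series, model = model, scenario = tumor_scenario(arms[1]),
                           seed = seed)
    readr::write_lines(utils::capture.output(print(fit)),
                       file.path(outdir, "fit_report.txt"))
  }
  summary <- compare_arms(trajs)
  readr::write_csv(summary, file.path(outdir, "summary.csv"))
  log <- c(
    paste0("warburgsim ", as.character(utils::packageVersion("warburgsim"))),
    paste0("seed: ", seed),
    paste0("arms: ", paste(arms, collapse = ", ")),
    paste0("cutsets: ", nrow(cs), " (target ", cutset_target, ")"),
    if (length(errors)) paste0("errors: ", paste(names(errors), unlist(errors),
                                                 sep = ": ", collapse = "; "))
  )
  readr::write_lines(log, file.path(outdir, "run_log.txt"))
  invisible(list(summary = summary, trajectories = trajs, cutsets = cs,
                 fit = fit, errors = errors, outdir = outdir))
}

#' Compare treatment arms
#'
#' Tabulates endpoint diagnostics per simulated arm: final tumor volume,
#' time to plateau (first day after which the 7-day relative volume change
#' stays below 1 percent), the sign of the lactate dehydrogenase flux late
#' in the run, and the late NAD+/NADH ratio.
#'
#' @param trajs Named list of `tumor_trajectory` objects (or a pipeline run
#'   directory containing `trajectory_<arm>.csv` files).
#' @return A tibble with one row per arm.
#' @export
compare_arms <- function(trajs) {
  if (is.character(trajs)) {
    files <- list.files(trajs, pattern = "^trajectory_.*\\.csv$", full.names = TRUE)
    nms <- sub("^trajectory_(.*)\\.csv$", "\\1", basename(files))
    trajs <- stats::setNames(lapply(files, readr::read_csv, show_col_types = FALSE), nms)
  }
  if (!length(trajs)) {
    return(tibble::tibble(arm = character(0), final_volume_mm3 = numeric(0),
                          plateau_day = numeric(0), plateaued = logical(0),
                          late_vldh = numeric(0), late_nad_nadh = numeric(0)))
  }
  purrr::imap_dfr(trajs, function(tr, arm) {
    tr <- tibble::as_tibble(tr)
    late <- tr[tr$time_day >= max(tr$time_day) - 5, ]
    tibble::tibble(
      arm = arm,
      final_volume_mm3 = tr$V_tumor_mm3[nrow(tr)],
      plateau_day = plateau_day(tr$time_day, tr$V_tumor_mm3),
      plateaued = is.finite(plateau_day(tr$time_day, tr$V_tumor_mm3)),
      late_vldh = mean(late$r_VLDH),
      late_nad_nadh = mean(late$nad_nadh)
    )
  })
}

# first day from which every subsequent 7-day relative change is < 1%
plateau_day <- function(time_day, volume) {
  f <- stats::approxfun(time_day, volume, rule = 2)
  days <- seq(min(time_day), max(time_day) - 7, by = 0.5)
  if (!length(days)) return(NA_real_)
  change <- abs(f(days + 7) - f(days)) / pmax(f(days), 1)
  ok <- rev(cumprod(rev(change < 0.01))) > 0   # holds from day onwards
  if (!any(ok)) return(NA_real_)
  days[which(ok)[1]]
}
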