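#' Read rate laws from a parameter table
#'
#' Parses the TSV rate-law dialect: one row per reaction with columns
#' `reaction_id`, `vmax`, `vmax_rev` and semicolon-separated `km` /
#' `km_rev` maps (`"EGLC:1.0;ATP:0.3"`).  Rates follow generalized
#' multiplicative Michaelis-Menten kinetics: saturation terms multiply over
#' the listed species.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `reaction_id`, `vmax`, `vmax_rev`, `km`
#'   and `km_rev` (the last two are list-columns of named numerics).
#' @export
read_rate_laws <- function(path) {
  tab <- read_network_table(path, c("reaction_id", "vmax", "vmax_rev", "km"))
  if (!"km_rev" %in% names(tab)) tab$km_rev <- NA_character_
  out <- tibble::tibble(
    reaction_id = tab$reaction_id,
    vmax = as.numeric(tab$vmax),
    vmax_rev = as.numeric(tab$vmax_rev),
    km = lapply(tab$km, parse_km_map, where = path),
    km_rev = lapply(tab$km_rev, parse_km_map, where = path)
  )
  bad <- out$vmax < 0 | out$vmax_rev < 0 | is.na(out$vmax) | is.na(out$vmax_rev)
  if (any(bad)) {
    stop("negative or missing vmax in ", path, " for: ",
         paste(out$reaction_id[bad], collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(out))) {
    ks <- c(out$km[[i]], out$km_rev[[i]])
    if (length(ks) && any(ks <= 0)) {
      stop("non-positive km for reaction ", out$reaction_id[i], call. = FALSE)
    }
  }
  out
}

# "EGLC:1.0;ATP:0.3" -> c(EGLC = 1.0, ATP = 0.3)
parse_km_map <- function(x, where = "km map") {
  if (is.na(x) || trimws(x) == "") return(stats::setNames(numeric(0), character(0)))
  pairs <- strsplit(trimws(x), ";", fixed = TRUE)[[1]]
  out <- numeric(0)
  for (p in pairs) {
    kv <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
    if (length(kv) != 2 || is.na(suppressWarnings(as.numeric(kv[2])))) {
      stop("cannot parse km entry \"", p, "\" in ", where, call. = FALSE)
    }
    out[kv[1]] <- as.numeric(kv[2])
  }
  out
}

#' Read drug-effect annotations
#'
#' @param path TSV with columns `drug`, `target`, `mode`
#'   (`inhibit`/`activate`) and `k_half` (half-effect blood concentration,
#'   mM).
#' @return A tibble with those columns.
#' @export
read_drug_effects <- function(path) {
  tab <- read_network_table(path, c("drug", "target", "mode", "k_half"))
  out <- tibble::tibble(
    drug = tab$drug, target = tab$target, mode = tab$mode,
    k_half = as.numeric(tab$k_half)
  )
  if (any(is.na(out$k_half) | out$k_half <= 0)) {
    stop("k_half must be positive in ", path, call. = FALSE)
  }
  if (!all(out$mode %in% c("inhibit", "activate"))) {
    stop("mode must be 'inhibit' or 'activate' in ", path, call. = FALSE)
  }
  if (anyDuplicated(out[c("drug", "target")])) {
    stop("duplicate (drug, target) pair in ", path, call. = FALSE)
  }
  out
}

#' Default rate laws and drug effects for the LL/2 reconstruction
#'
#' @return `ll2_rate_laws()`: the packaged default rate-law table;
#'   `ll2_drug_effects()`: the packaged drug-effect table (diclofenac
#'   inhibiting VHK and VLDH, alpha-lipoic acid activating VPDH,
#'   hydroxycitrate inhibiting VACL, metformin inhibiting VATPase and
#'   activating VNADleak).
#' @export
ll2_rate_laws <- function() {
  read_rate_laws(system.file("extdata", "ll2_rate_laws.tsv", package = "warburgsim"))
}

#' @rdname ll2_rate_laws
#' @export
ll2_drug_effects <- function() {
  read_drug_effects(system.file("extdata", "ll2_drug_effects.tsv", package = "warburgsim"))
}

#' Assemble a kinetic model
#'
#' Binds a network to rate laws and drug effects, validating that every
#' reaction has exactly one rate law, every drug effect targets an existing
#' reaction, every km species exists, and `vmax_rev > 0` only for reversible
#' reactions.
#'
#' @param net A `ccm_network`.
#' @param rate_laws Tibble from [read_rate_laws()] (default: packaged LL/2
#'   values).
#' @param drug_effects Tibble from [read_drug_effects()] (default: packaged
#'   annotations).
#' @return A `kinetic_model` object.
#' @export
build_kinetic_model <- function(net, rate_laws = ll2_rate_laws(),
                                drug_effects = ll2_drug_effects()) {
  stopifnot(inherits(net, "ccm_network"))
  ids <- net$reactions$id
  missing <- setdiff(ids, rate_laws$reaction_id)
  if (length(missing)) {
    stop("no rate law for reaction(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(rate_laws$reaction_id, ids)
  if (length(extra)) {
    stop("rate law(s) for unknown reaction(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rate_laws$reaction_id)) {
    stop("duplicated rate law entries", call. = FALSE)
  }
  rate_laws <- rate_laws[match(ids, rate_laws$reaction_id), ]
  rev_bad <- rate_laws$vmax_rev > 0 & !net$reactions$reversible
  if (any(rev_bad)) {
    stop("vmax_rev > 0 for irreversible reaction(s): ",
         paste(ids[rev_bad], collapse = ", "), call. = FALSE)
  }
  bad_t <- setdiff(drug_effects$target, ids)
  if (length(bad_t)) {
    stop("drug effect targets unknown reaction(s): ",
         paste(bad_t, collapse = ", "), call. = FALSE)
  }
  species <- net$metabolites$id
  for (i in seq_len(nrow(rate_laws))) {
    bad <- setdiff(c(names(rate_laws$km[[i]]), names(rate_laws$km_rev[[i]])), species)
    if (length(bad)) {
      stop("km references unknown species in ", ids[i], ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  model <- structure(
    list(network = net, rate_laws = rate_laws, drug_effects = drug_effects),
    class = "kinetic_model"
  )
  model$engine <- compile_flux_engine(model)
  model
}

#' Default kinetic model of the LL/2 tumor
#'
#' Convenience wrapper: packaged network + packaged rate laws + packaged
#' drug effects.
#' @return A `kinetic_model`.
#' @export
ll2_model <- function() build_kinetic_model(ll2_network())

#' @export
print.kinetic_model <- function(x, ...) {
  cat("<kinetic_model> ", nrow(x$rate_laws), " rate laws, ",
      nrow(x$drug_effects), " drug effects on ",
      length(unique(x$drug_effects$target)), " targets\n", sep = "")
  invisible(x)
}

#' Drug modulation factor
#'
#' Multiplicative factor applied to a target reaction's rate at a given
#' blood drug concentration: inhibition gives `k_half / (k_half + c)` in
#' `(0, 1]`, activation gives `1 + c / (k_half + c)` in `[1, 2)`; both equal
#' 1 exactly at zero concentration.
#'
#' @param mode `"inhibit"` or `"activate"`.
#' @param drug_conc Drug concentration (mM), non-negative.
#' @param k_half Half-effect concentration (mM), positive.
#' @return Dimensionless factor.
#' @export
modulation_factor <- function(mode, drug_conc, k_half) {
  if (any(drug_conc < 0)) stop("drug concentration must be non-negative", call. = FALSE)
  stopifnot(k_half > 0)
  switch(match.arg(mode, c("inhibit", "activate")),
    inhibit = k_half / (k_half + drug_conc),
    activate = 1 + drug_conc / (k_half + drug_conc)
  )
}

#' Single reaction rate
#'
#' Generalized multiplicative Michaelis-Menten rate:
#' `v = factors * (vmax * prod_s c_s/(km_s + c_s) - vmax_rev * prod_p c_p/(km_p + c_p))`.
#' Irreversible laws (`vmax_rev = 0`) return non-negative rates.
#'
#' @param vmax,vmax_rev Maximal forward / reverse rates.
#' @param km,km_rev Named numeric `km` maps for the forward / reverse terms.
#' @param conc Named concentration vector covering all km species (mM).
#' @param factors Product of applicable drug modulation factors (default 1).
#' @return Scalar flux.
#' @export
reaction_rate <- function(vmax, km, conc, factors = 1, vmax_rev = 0, km_rev = NULL) {
  sat <- function(kmap) {
    if (!length(kmap)) return(1)
    miss <- setdiff(names(kmap), names(conc))
    if (length(miss)) {
      stop("missing concentration(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    c_s <- conc[names(kmap)]
    if (any(c_s < 0)) stop("negative concentration", call. = FALSE)
    prod(c_s / (kmap + c_s))
  }
  factors * (vmax * sat(km) - vmax_rev * sat(km_rev))
}

#' Flux vector of a kinetic model
#'
#' Evaluates all reaction rates at a given state and drug exposure.  Each
#' rate is [reaction_rate()] times the product of the modulation factors of
#' all drug effects targeting that reaction.
#'
#' @param model A `kinetic_model`.
#' @param m Named intracellular concentrations (mM), covering all `cell`
#'   species.
#' @param C Named blood concentrations (mM), covering all `blood` species.
#' @param doses Named drug concentrations (mM); defaults to the drug species
#'   entries of `C` (zero when absent).
#' @return Named numeric flux vector in network reaction order.
#' @export
flux_vector <- function(model, m, C, doses = NULL) {
  stopifnot(inherits(model, "kinetic_model"))
  eng <- model$engine
  conc <- numeric(length(eng$species))
  names(conc) <- eng$species
  miss_m <- setdiff(eng$cell_species, names(m))
  miss_c <- setdiff(eng$blood_species, names(C))
  if (length(miss_m) || length(miss_c)) {
    stop("missing concentration(s): ",
         paste(c(miss_m, miss_c), collapse = ", "), call. = FALSE)
  }
  conc[names(m)] <- m
  conc[names(C)] <- C
  if (is.null(doses)) {
    doses <- conc[eng$drugs]
  } else {
    d <- stats::setNames(numeric(length(eng$drugs)), eng$drugs)
    d[intersect(names(doses), eng$drugs)] <- doses[intersect(names(doses), eng$drugs)]
    doses <- d
  }
  if (any(conc < 0) || any(doses < 0)) {
    stop("negative concentration passed to flux_vector", call. = FALSE)
  }
  eval_fluxes(eng, conc, doses)
}

# ---- internal flux engine ---------------------------------------------------

# Precompute index structures so the ODE right-hand side is cheap.
compile_flux_engine <- function(model) {
  net <- model$network
  rl <- model$rate_laws
  species <- net$metabolites$id
  n_rxn <- nrow(rl)
  trip <- function(col) {
    rxn <- integer(0); sp <- integer(0); km <- numeric(0)
    for (j in seq_len(n_rxn)) {
      kmap <- rl[[col]][[j]]
      if (length(kmap)) {
        rxn <- c(rxn, rep(j, length(kmap)))
        sp <- c(sp, match(names(kmap), species))
        km <- c(km, unname(kmap))
      }
    }
    A <- matrix(0, n_rxn, length(rxn))
    if (length(rxn)) A[cbind(rxn, seq_along(rxn))] <- 1
    list(rxn = rxn, sp = sp, km = km, A = A)
  }
  de <- model$drug_effects
  list(
    species = species,
    drug_idx = match(unique(de$drug), species),
    growth_j = match("Vgrowth", net$reactions$id),
    blood_species = species[net$metabolites$compartment == "blood"],
    cell_species = species[net$metabolites$compartment == "cell"],
    drugs = unique(de$drug),
    n_rxn = n_rxn,
    rxn_ids = net$reactions$id,
    vmax = rl$vmax,
    vmax_rev = rl$vmax_rev,
    fwd = trip("km"),
    rev = trip("km_rev"),
    eff = list(
      rxn = match(de$target, net$reactions$id),
      drug = match(de$drug, unique(de$drug)),
      sp = match(de$drug, species),
      inhibit = de$mode == "inhibit",
      k_half = de$k_half
    )
  )
}

# conc: full species vector (>= 0); doses: named by engine drugs.
eval_fluxes <- function(eng, conc, doses) {
  satprod <- function(tr) {
    if (!length(tr$rxn)) return(rep(1, eng$n_rxn))
    c_s <- conc[tr$sp]
    # product of saturation terms per reaction as exp of grouped log-sums;
    # rows without terms sum to 0 and give factor 1
    drop(exp(tr$A %*% log(pmax(c_s / (tr$km + c_s), 1e-300))))
  }
  v <- eng$vmax * satprod(eng$fwd) - eng$vmax_rev * satprod(eng$rev)
  f <- rep(1, eng$n_rxn)
  e <- eng$eff
  if (length(e$rxn)) {
    d <- doses[e$drug]
    fac <- ifelse(e$inhibit, e$k_half / (e$k_half + d), 1 + d / (e$k_half + d))
    for (i in seq_along(e$rxn)) f[e$rxn[i]] <- f[e$rxn[i]] * fac[i]
  }
  stats::setNames(f * v, eng$rxn_ids)
}
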