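# Shared fixtures: toy networks built in code and brute-force structural
# oracles (independent of the double-description / Berge implementation).

toy_network <- function(met, rxn) {
  met_tab <- tibble::tibble(
    id = names(met), name = names(met), compartment = unname(met), units = "mM"
  )
  rxn_tab <- tibble::tibble(
    id = names(rxn),
    equation = NA_character_,
    reversible = vapply(rxn, function(r) isTRUE(r$rev), logical(1)),
    enzyme = NA_character_, notes = NA_character_,
    stoichiometry = lapply(rxn, `[[`, "s")
  )
  rxn_tab$equation <- vapply(
    seq_len(nrow(rxn_tab)),
    function(i) warburgsim:::format_equation(rxn_tab$stoichiometry[[i]],
                                             rxn_tab$reversible[i]),
    character(1)
  )
  warburgsim:::new_ccm_network(met_tab, rxn_tab)
}

chain_net <- function() {
  toy_network(
    c(A = "blood", B = "cell", C = "blood"),
    list(r1 = list(s = c(A = -1, B = 1)),
         r2 = list(s = c(B = -1, C = 1)))
  )
}

diamond_net <- function() {
  toy_network(
    c(A = "blood", B = "cell", C = "cell", D = "cell", E = "blood"),
    list(r1 = list(s = c(A = -1, B = 1)),
         r2 = list(s = c(A = -1, C = 1)),
         r3 = list(s = c(B = -1, D = 1)),
         r4 = list(s = c(C = -1, D = 1)),
         r5 = list(s = c(D = -1, E = 1)))
  )
}

reversible_chain_net <- function() {
  toy_network(
    c(A = "blood", M = "cell", B = "blood"),
    list(r1 = list(s = c(A = -1, M = 1), rev = TRUE),
         r2 = list(s = c(M = -1, B = 1), rev = TRUE))
  )
}

# random small network: n_int internal metabolites, n_rxn reactions, each a
# sparse +-1 column; boundary exchange implicit via rows not included
random_net <- function(seed, n_int = 4, n_rxn = 6) {
  set.seed(seed)
  repeat {
    met <- c(stats::setNames(rep("blood", 2), c("X1", "X2")),
             stats::setNames(rep("cell", n_int), paste0("M", seq_len(n_int))))
    rxn <- list()
    ids <- names(met)
    for (j in seq_len(n_rxn)) {
      k <- sample(2:3, 1)
      picks <- sample(ids, k)
      coef <- stats::setNames(sample(c(-1, 1), k, replace = TRUE), picks)
      if (all(coef > 0) || all(coef < 0)) coef[1] <- -coef[1]
      rxn[[paste0("r", j)]] <- list(s = coef, rev = stats::runif(1) < 0.25)
    }
    net <- try(toy_network(met, rxn), silent = TRUE)
    if (!inherits(net, "try-error")) return(net)
  }
}

# ---- brute-force oracles ----------------------------------------------------

# all supports T of the reversibility-split system with a 1-dim strictly
# positive nullspace on T, minimal by inclusion; returned as signed patterns
# over the original reactions (excluding forward+backward two-cycles)
brute_efms <- function(net) {
  split <- warburgsim:::split_reversible(net)
  S <- split$S
  n <- ncol(S)
  modes <- list()
  for (code in seq_len(2^n - 1)) {
    T <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    ST <- S[, T, drop = FALSE]
    sv <- svd(ST, nu = 0, nv = ncol(ST))
    tol <- max(dim(ST)) * max(sv$d, 0, 1e-12) * 1e-8
    rank <- sum(sv$d > tol)
    if (length(T) - rank != 1) next
    v <- sv$v[, ncol(sv$v)]
    if (any(abs(v) < 1e-9)) next           # support not exact
    if (any(v > 1e-9) && any(v < -1e-9)) next  # not sign-fixable
    modes[[length(modes) + 1L]] <- list(T = T, v = abs(v))
  }
  # minimal supports only
  keep <- rep(TRUE, length(modes))
  for (i in seq_along(modes)) for (j in seq_along(modes)) {
    if (i != j && keep[i] && all(modes[[j]]$T %in% modes[[i]]$T) &&
        length(modes[[j]]$T) < length(modes[[i]]$T)) keep[i] <- FALSE
  }
  modes <- modes[keep]
  out <- list()
  for (mm in modes) {
    v <- numeric(max(split$map))
    for (idx in seq_along(mm$T)) {
      c0 <- mm$T[idx]
      v[split$map[c0]] <- v[split$map[c0]] + split$dir[c0] * mm$v[idx]
    }
    if (all(abs(v) < 1e-9)) next           # pure two-cycle
    fwd <- bwd <- numeric(max(split$map))
    for (idx in seq_along(mm$T)) {
      c0 <- mm$T[idx]
      if (split$dir[c0] > 0) fwd[split$map[c0]] <- mm$v[idx]
      else bwd[split$map[c0]] <- mm$v[idx]
    }
    if (any(fwd > 1e-9 & bwd > 1e-9)) next
    out[[length(out) + 1L]] <- sort(net$reactions$id[abs(v) > 1e-9])
  }
  unique(out)
}

# minimal cut sets by exhaustive subset search over original reactions,
# using brute_efms supports as the certificate of achievable flux
brute_mcs <- function(net, target) {
  efms <- brute_efms(net)
  edges <- Filter(function(s) target %in% s, efms)
  ids <- net$reactions$id
  if (!length(edges)) return(list())
  cuts <- list()
  n <- length(ids)
  for (code in seq_len(2^n - 1)) {
    cut <- ids[which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)]
    blocked <- all(vapply(edges, function(e) length(intersect(e, cut)) > 0,
                          logical(1)))
    if (blocked) cuts[[length(cuts) + 1L]] <- sort(cut)
  }
  keep <- rep(TRUE, length(cuts))
  for (i in seq_along(cuts)) for (j in seq_along(cuts)) {
    if (i != j && keep[i] && all(cuts[[j]] %in% cuts[[i]]) &&
        length(cuts[[j]]) < length(cuts[[i]])) keep[i] <- FALSE
  }
  unique(cuts[keep])
}

set_key <- function(sets) sort(vapply(sets, paste, character(1), collapse = ";"))

# all-zero rate laws for a network (so the flux vector vanishes identically)
zero_rate_laws <- function(net) {
  tibble::tibble(
    reaction_id = net$reactions$id,
    vmax = 0, vmax_rev = 0,
    km = replicate(nrow(net$reactions),
                   stats::setNames(numeric(0), character(0)), simplify = FALSE),
    km_rev = replicate(nrow(net$reactions),
                       stats::setNames(numeric(0), character(0)), simplify = FALSE)
  )
}

ll2_zero_flux_model <- function() {
  net <- ll2_network()
  build_kinetic_model(net, zero_rate_laws(net), ll2_drug_effects())
}
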