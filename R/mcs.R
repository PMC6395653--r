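#' Minimal cut sets for a target reaction
#'
#' Enumerates all minimal cut sets (MCS) blocking a target reaction: the
#' minimal sets of reactions whose deletion leaves no steady-state flux
#' distribution with nonzero flux through the target.  Computed as the
#' minimal hitting sets (Berge incremental transversal) of the supports of
#' the elementary flux modes that use the target.  Deleting a reversible
#' reaction removes both directions (enzyme-level semantics).
#'
#' @param net A `ccm_network`.
#' @param target Reaction id to block (e.g. `"Vgrowth"`).
#' @param efms Optional precomputed result of [elementary_flux_modes()]
#'   (saves recomputation when analysing several targets).
#' @return A tibble with one row per cut set, sorted by `size` then
#'   lexicographically: columns `size` and `reactions` (list of sorted
#'   reaction id vectors).  If the target supports no EFM the tibble is empty
#'   and carries attribute `already_blocked = TRUE` (with a warning).
#' @export
minimal_cut_sets <- function(net, target, efms = NULL) {
  stopifnot(inherits(net, "ccm_network"))
  if (!target %in% net$reactions$id) {
    stop("target reaction not in network: ", target, call. = FALSE)
  }
  if (is.null(efms)) efms <- elementary_flux_modes(net)
  keep <- vapply(efms$support, function(s) target %in% s, logical(1))
  edges <- efms$support[keep]
  if (!length(edges)) {
    warning("target ", target, " carries no elementary flux mode; already blocked")
    out <- tibble::tibble(size = integer(0), reactions = list())
    attr(out, "already_blocked") <- TRUE
    return(out)
  }
  ids <- net$reactions$id
  hs <- berge_hitting_sets(lapply(edges, function(s) match(s, ids)), length(ids))
  sets <- lapply(hs, function(ix) sort(ids[ix]))
  keys <- vapply(sets, paste, character(1), collapse = ";")
  ord <- order(lengths(sets), keys)
  out <- tibble::tibble(size = lengths(sets)[ord], reactions = sets[ord])
  attr(out, "already_blocked") <- FALSE
  out
}

#' Essential reactions for a target
#'
#' The size-one minimal cut sets: reactions present in every elementary flux
#' mode that carries the target, whose single deletion therefore blocks it.
#'
#' @inheritParams minimal_cut_sets
#' @return Character vector of reaction ids (network order); always contains
#'   the target itself when the target is unblocked.
#' @export
essential_reactions <- function(net, target, efms = NULL) {
  stopifnot(inherits(net, "ccm_network"))
  if (!target %in% net$reactions$id) {
    stop("target reaction not in network: ", target, call. = FALSE)
  }
  if (is.null(efms)) efms <- elementary_flux_modes(net)
  keep <- vapply(efms$support, function(s) target %in% s, logical(1))
  edges <- efms$support[keep]
  if (!length(edges)) {
    warning("target ", target, " carries no elementary flux mode; already blocked")
    return(character(0))
  }
  ess <- Reduce(intersect, edges)
  net$reactions$id[net$reactions$id %in% ess]
}

#' Write a cut-set report
#'
#' @param cutsets Result of [minimal_cut_sets()].
#' @param path Output TSV path (columns `size`, `reaction_ids`
#'   semicolon-joined, ascending by size).
#' @return Invisibly, the tibble written.
#' @export
write_cutset_report <- function(cutsets, path) {
  out <- tibble::tibble(
    size = cutsets$size,
    reaction_ids = vapply(cutsets$reactions, paste, character(1), collapse = ";")
  )
  readr::write_tsv(out, path)
  invisible(out)
}

# Berge incremental transversal: minimal hitting sets of integer-index edges.
# Sets are kept as rows of a logical incidence matrix for fast subset tests.
berge_hitting_sets <- function(edges, n) {
  edges <- edges[order(lengths(edges))]
  H <- matrix(FALSE, length(edges[[1]]), n)
  for (k in seq_along(edges[[1]])) H[k, edges[[1]][k]] <- TRUE
  for (e in edges[-1]) {
    hit <- rowSums(H[, e, drop = FALSE]) > 0
    H1 <- H[hit, , drop = FALSE]
    H2 <- H[!hit, , drop = FALSE]
    if (nrow(H2) == 0) next
    # extend every missed set by every element of the edge
    cand <- H2[rep(seq_len(nrow(H2)), each = length(e)), , drop = FALSE]
    cand[cbind(seq_len(nrow(cand)), rep(e, times = nrow(H2)))] <- TRUE
    cand <- unique(cand)
    # drop candidates containing an H1 set (non-minimal)
    if (nrow(H1)) {
      slack <- H1 %*% t(!cand)          # |h1 \ cand_j| per pair
      cand <- cand[colSums(slack == 0) == 0, , drop = FALSE]
    }
    # mutual minimality among candidates (smaller sets first)
    if (nrow(cand) > 1) {
      cand <- cand[order(rowSums(cand)), , drop = FALSE]
      keep <- rep(TRUE, nrow(cand))
      for (i in seq_len(nrow(cand) - 1)) {
        if (!keep[i]) next
        rest <- which(keep & seq_len(nrow(cand)) > i)
        if (!length(rest)) break
        sup <- cand[rest, !cand[i, ], drop = FALSE]
        keep[rest[rowSums(sup) == 0]] <- FALSE
      }
      cand <- cand[keep, , drop = FALSE]
    }
    H <- rbind(H1, cand)
  }
  lapply(seq_len(nrow(H)), function(i) which(H[i, ]))
}
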