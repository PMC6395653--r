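#' Enumerate elementary flux modes
#'
#' Computes the complete set of elementary flux modes (EFMs) of a network by
#' the double description method on the reversibility-split system: every
#' reversible reaction is split into a forward and a backward irreversible
#' column, intracellular (`cell`) metabolites are balanced at steady state,
#' and blood metabolites are treated as open boundary species.  Each EFM is a
#' minimal-support non-negative flux pattern `v` with `S_m v = 0`.
#'
#' Spurious two-cycles made of the forward and backward copies of one split
#' reaction are removed, and modes that coincide on the original reaction set
#' are deduplicated.  Output order is deterministic: lexicographic by sorted
#' support.
#'
#' @param net A `ccm_network`.
#' @return A tibble with one row per EFM: `efm` (index), `size` (support
#'   size), `support` (list of reaction id character vectors) and
#'   `coefficients` (list of named numeric flux patterns on the original
#'   reactions; entries for reversible reactions may be negative).
#' @export
elementary_flux_modes <- function(net) {
  stopifnot(inherits(net, "ccm_network"))
  if (nrow(net$S_m) == 0) {
    stop("network has no internal (cell) metabolites; EFM analysis undefined", call. = FALSE)
  }
  split <- split_reversible(net)
  R <- dd_rays(split$S)          # rows = rays over split columns
  modes <- collapse_split_modes(R, split)
  order_modes(modes, net$reactions$id)
}

# Split reversible reactions into forward/backward irreversible columns.
# Returns the split internal stoichiometric matrix and the column mapping.
split_reversible <- function(net) {
  rxn <- net$reactions
  Sm <- net$S_m
  cols <- list(); map <- integer(0); dir <- numeric(0)
  for (j in seq_len(nrow(rxn))) {
    cols[[length(cols) + 1L]] <- Sm[, j]
    map <- c(map, j); dir <- c(dir, 1)
    if (rxn$reversible[j]) {
      cols[[length(cols) + 1L]] <- -Sm[, j]
      map <- c(map, j); dir <- c(dir, -1)
    }
  }
  S <- do.call(cbind, cols)
  colnames(S) <- paste0(rxn$id[map], ifelse(dir > 0, "", "_rev"))
  list(S = S, map = map, dir = dir)
}

# Double description / canonical tableau method: extreme rays of
# {v >= 0 : S v = 0}.  Rows of the returned matrix are rays.
dd_rays <- function(S) {
  n <- ncol(S)
  R <- diag(n)
  Z <- R == 0                     # zero-pattern of each ray
  remaining <- seq_len(nrow(S))
  while (length(remaining)) {
    # pick the constraint generating the fewest pairwise combinations
    scores <- vapply(remaining, function(i) {
      a <- drop(R %*% S[i, ])
      sum(a > 1e-10) * sum(a < -1e-10)
    }, numeric(1))
    i <- remaining[which.min(scores)]
    remaining <- setdiff(remaining, i)
    a <- drop(R %*% S[i, ])
    a[abs(a) <= 1e-10] <- 0
    keep <- which(a == 0)
    pos <- which(a > 0); neg <- which(a < 0)
    newR <- list()
    if (length(pos) && length(neg)) {
      Zk <- Z[c(keep, pos, neg), , drop = FALSE]
      for (p in pos) for (q in neg) {
        zz <- Z[p, ] & Z[q, ]
        # adjacency: no third ray's zero-set contains Z(p) & Z(q)
        cand <- Zk[, zz, drop = FALSE]
        ok <- sum(rowSums(!cand) == 0) <= 2   # only p and q themselves
        if (ok) {
          v <- a[p] * R[q, ] - a[q] * R[p, ]
          v[abs(v) <= 1e-12 * max(abs(v))] <- 0
          newR[[length(newR) + 1L]] <- v / max(abs(v))
        }
      }
    }
    R <- rbind(R[keep, , drop = FALSE], do.call(rbind, newR))
    if (is.null(R) || nrow(R) == 0) break
    Z <- abs(R) <= 1e-12
  }
  if (is.null(R)) R <- matrix(0, 0, n)
  R
}

# Map split-column rays back to signed patterns on original reactions,
# dropping forward+backward two-cycles and duplicates.
collapse_split_modes <- function(R, split) {
  out <- list()
  seen <- character(0)
  nr <- max(split$map)
  for (k in seq_len(nrow(R))) {
    v <- numeric(nr)
    for (c in seq_along(split$map)) {
      v[split$map[c]] <- v[split$map[c]] + split$dir[c] * R[k, c]
    }
    v[abs(v) <= 1e-12] <- 0
    if (all(v == 0)) next                      # pure split two-cycle
    # a genuine mode must use each split reaction in one direction only
    fwd <- numeric(nr); bwd <- numeric(nr)
    for (c in seq_along(split$map)) {
      if (split$dir[c] > 0) fwd[split$map[c]] <- R[k, c] else bwd[split$map[c]] <- R[k, c]
    }
    if (any(fwd > 1e-12 & bwd > 1e-12)) next   # futile two-cycle component
    key <- paste(which(v != 0), collapse = ",")
    sig <- paste(signif(v[v != 0] / max(abs(v)), 6), collapse = ",")
    id <- paste(key, sig, sep = "|")
    if (id %in% seen) next
    seen <- c(seen, id)
    out[[length(out) + 1L]] <- v / max(abs(v))
  }
  out
}

order_modes <- function(modes, rxn_ids) {
  if (!length(modes)) {
    return(tibble::tibble(efm = integer(0), size = integer(0),
                          support = list(), coefficients = list()))
  }
  supports <- lapply(modes, function(v) sort(rxn_ids[v != 0]))
  keys <- vapply(supports, paste, character(1), collapse = ";")
  ord <- order(keys)
  modes <- modes[ord]; supports <- supports[ord]
  coeffs <- lapply(modes, function(v) stats::setNames(v, rxn_ids)[v != 0])
  tibble::tibble(
    efm = seq_along(modes),
    size = lengths(supports),
    support = supports,
    coefficients = coeffs
  )
}
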