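#' Read a two-compartment metabolic network from tabular files
#'
#' Loads a metabolic network from the package's human-editable TSV dialect:
#' a reaction table (columns `id`, `equation`, `reversible`, `enzyme`,
#' `notes`) and a metabolite table (columns `id`, `name`, `compartment`,
#' `units`).  Lines starting with `#` are comments.  The equation grammar is
#' `"1 EGLC + 1 ATP -> 1 G6P + 1 ADP"`, with `<->` marking reversible
#' reactions.
#'
#' Metabolites live in one of two compartments: `blood` (the capillary
#' microenvironment perfusing the tumor, treated as an open boundary in
#' structural analysis) and `cell` (the single intracellular pool, balanced
#' at steady state).
#'
#' @param reactions Path to the reaction TSV.
#' @param metabolites Path to the metabolite TSV.
#' @return A `ccm_network` object: a list with tibbles `metabolites` and
#'   `reactions` (the latter carries a `stoichiometry` list-column of named
#'   numeric vectors, negative for substrates) and dense stoichiometric
#'   matrices `S_c` (blood rows) and `S_m` (intracellular rows), columns in
#'   file (reaction) order.
#' @examples
#' net <- ll2_network()
#' nrow(net$reactions)
#' @export
read_ccm_network <- function(reactions, metabolites) {
  for (p in c(reactions, metabolites)) {
    if (!file.exists(p)) stop("network file not found: ", p, call. = FALSE)
  }
  met <- read_network_table(metabolites, c("id", "name", "compartment", "units"))
  rxn <- read_network_table(reactions, c("id", "equation", "reversible"))
  if (!"enzyme" %in% names(rxn)) rxn$enzyme <- NA_character_
  if (!"notes" %in% names(rxn)) rxn$notes <- NA_character_
  rxn$reversible <- parse_flag(rxn$reversible, reactions)
  rxn$stoichiometry <- purrr::map2(
    rxn$equation, seq_len(nrow(rxn)),
    function(eq, i) parse_equation(eq, where = paste0(reactions, " reaction row ", i))
  )
  new_ccm_network(met, rxn)
}

#' The packaged LL/2 Lewis lung carcinoma network reconstruction
#'
#' Returns the versioned reconstruction of the LL/2 central-carbon-metabolism
#' network shipped with the package: 35 enzymatic reactions over 52
#' metabolites split between the blood microenvironment and the intracellular
#' compartment, covering glycolysis, the pentose phosphate pathway, the TCA
#' cycle, lipogenesis, oxidative phosphorylation and amino-acid metabolism,
#' with `Vgrowth` as the biomass reaction.
#'
#' @return A `ccm_network`.
#' @export
ll2_network <- function() {
  read_ccm_network(
    reactions   = system.file("extdata", "ll2_ccm_reactions.tsv", package = "warburgsim"),
    metabolites = system.file("extdata", "ll2_ccm_metabolites.tsv", package = "warburgsim")
  )
}

# Construct + validate a ccm_network from metabolite / reaction tibbles.
new_ccm_network <- function(met, rxn) {
  met <- tibble::as_tibble(met)
  rxn <- tibble::as_tibble(rxn)
  if (anyDuplicated(met$id)) {
    stop("duplicate metabolite id(s): ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rxn$id)) {
    stop("duplicate reaction id(s): ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "), call. = FALSE)
  }
  bad_comp <- setdiff(unique(met$compartment), c("blood", "cell"))
  if (length(bad_comp)) {
    stop("unknown compartment(s): ", paste(bad_comp, collapse = ", "),
         " (must be 'blood' or 'cell')", call. = FALSE)
  }
  refs <- unique(unlist(lapply(rxn$stoichiometry, names)))
  dangling <- setdiff(refs, met$id)
  if (length(dangling)) {
    stop("reaction(s) reference undeclared metabolite(s): ",
         paste(sort(dangling), collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(rxn))) {
    s <- rxn$stoichiometry[[i]]
    if (length(s) == 0) stop("empty stoichiometry in reaction ", rxn$id[i], call. = FALSE)
    if (any(!is.finite(s)) || any(s == 0)) {
      stop("non-finite or zero coefficient in reaction ", rxn$id[i], call. = FALSE)
    }
  }
  S <- matrix(0, nrow(met), nrow(rxn), dimnames = list(met$id, rxn$id))
  for (j in seq_len(nrow(rxn))) {
    s <- rxn$stoichiometry[[j]]
    S[names(s), j] <- s
  }
  net <- structure(
    list(
      metabolites = met,
      reactions = rxn,
      S_c = S[met$id[met$compartment == "blood"], , drop = FALSE],
      S_m = S[met$id[met$compartment == "cell"], , drop = FALSE]
    ),
    class = "ccm_network"
  )
  net
}

#' Stoichiometric matrices of a network
#'
#' @param net A `ccm_network`.
#' @return A list with `S_c` (one row per blood metabolite) and `S_m` (one
#'   row per intracellular metabolite); both share one column per reaction in
#'   network order, and their rows partition the full stoichiometric matrix.
#' @export
stoichiometric_matrices <- function(net) {
  stopifnot(inherits(net, "ccm_network"))
  list(S_c = net$S_c, S_m = net$S_m)
}

#' Write a network back to the tabular dialect
#'
#' Serialises a `ccm_network` to the same two-file TSV dialect read by
#' [read_ccm_network()]; reloading gives back identical metabolite and
#' reaction sets, stoichiometries and reversibility flags.
#'
#' @param net A `ccm_network`.
#' @param reactions,metabolites Output file paths.
#' @return Invisibly, the input network.
#' @export
write_ccm_network <- function(net, reactions, metabolites) {
  stopifnot(inherits(net, "ccm_network"))
  readr::write_tsv(net$metabolites, metabolites)
  rxn <- net$reactions
  rxn$equation <- vapply(
    seq_len(nrow(rxn)),
    function(i) format_equation(rxn$stoichiometry[[i]], rxn$reversible[i]),
    character(1)
  )
  readr::write_tsv(rxn[setdiff(names(rxn), "stoichiometry")], reactions)
  invisible(net)
}

#' @export
print.ccm_network <- function(x, ...) {
  cat("<ccm_network> ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites (",
      nrow(x$S_c), " blood / ", nrow(x$S_m), " intracellular)\n", sep = "")
  rev_ids <- x$reactions$id[x$reactions$reversible]
  if (length(rev_ids)) cat("reversible:", paste(rev_ids, collapse = ", "), "\n")
  invisible(x)
}

# ---- parsing helpers --------------------------------------------------------

read_network_table <- function(path, required) {
  tab <- tryCatch(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}

parse_flag <- function(x, where) {
  out <- toupper(trimws(x)) %in% c("TRUE", "T", "1", "YES")
  bad <- !toupper(trimws(x)) %in% c("TRUE", "T", "1", "YES", "FALSE", "F", "0", "NO")
  if (any(bad)) {
    stop("unparseable reversible flag in ", where, ": ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

# "1 A + 0.5 B -> 2 C" -> c(A = -1, B = -0.5, C = 2)
parse_equation <- function(eq, where = "equation") {
  arrow <- if (grepl("<->", eq, fixed = TRUE)) "<->" else "->"
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2) {
    stop("cannot parse ", where, ": expected one '", arrow, "' in \"", eq, "\"", call. = FALSE)
  }
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (side == "") return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      tok <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(tok) == 1) tok <- c("1", tok)
      if (length(tok) != 2 || is.na(suppressWarnings(as.numeric(tok[1])))) {
        stop("cannot parse ", where, ": bad term \"", tm, "\" in \"", eq, "\"", call. = FALSE)
      }
      out[tok[2]] <- (out[tok[2]] %||% 0) + sign * as.numeric(tok[1])
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  s <- c(lhs, rhs[setdiff(names(rhs), names(lhs))])
  for (nm in intersect(names(rhs), names(lhs))) s[nm] <- s[nm] + rhs[nm]
  s <- s[s != 0]
  if (length(s) == 0) stop("cannot parse ", where, ": empty stoichiometry", call. = FALSE)
  s
}

format_equation <- function(stoich, reversible) {
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  fmt <- function(s, flip) {
    paste(paste(format(flip * unname(s), trim = TRUE, scientific = FALSE),
                names(s)), collapse = " + ")
  }
  paste(fmt(lhs, -1), if (reversible) "<->" else "->", fmt(rhs, 1))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a
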