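# Reverse ecology: per-organism metabolic networks from KO annotations,
# seed-set detection on the condensation of the network, and asymmetric
# pairwise competition / complementarity indices.
#
# Seed compounds are the metabolites an organism must take up from its
# environment: the compounds lying in source components (in-degree 0) of
# the condensation of its directed substrate->product graph. Every other
# compound is producible internally (non-seed).

#' Build an organism's metabolic network from its KO set
#'
#' A reaction of the universe is included when the organism carries any of
#' the reaction's KOs (OR semantics over ortholog annotations). Each
#' included reaction contributes a directed edge from every substrate to
#' every product; reversible reactions contribute both directions.
#' Compounds enter the network only via included reactions — no isolated
#' nodes.
#'
#' @param kos a [ko_profile()] (its KO support is used) or character
#'   vector of KO ids.
#' @param universe a [reaction_universe()].
#' @param blacklist optional compound ids (e.g. currency metabolites)
#'   removed from the network before seed detection.
#' @return Object of class `metabolic_network`: list with `organism_id`,
#'   `compounds`, `edges` (2-column from/to matrix), `source_kos`,
#'   `reactions` (included reaction ids). An organism whose KOs hit no
#'   reaction yields a flagged-empty network (`is_empty = TRUE`), not an
#'   error.
#' @export
build_network <- function(kos, universe, blacklist = character(0)) {
  stopifnot(inherits(universe, "reaction_universe"))
  organism_id <- "organism"
  if (inherits(kos, "ko_profile")) {
    organism_id <- kos$unit_id
    kos <- ko_ids(kos)
  }
  hit <- matched_reactions(kos, universe)
  from <- character(0); to <- character(0)
  for (i in hit) {
    s <- setdiff(universe$substrates[[i]], blacklist)
    p <- setdiff(universe$products[[i]], blacklist)
    if (!length(s) || !length(p)) next
    grid <- expand.grid(s = s, p = p, stringsAsFactors = FALSE)
    from <- c(from, grid$s); to <- c(to, grid$p)
    if (universe$reversible[i]) {
      from <- c(from, grid$p); to <- c(to, grid$s)
    }
  }
  edges <- unique(cbind(from = from, to = to))
  structure(list(organism_id = organism_id,
                 compounds = sort(unique(c(from, to))),
                 edges = edges,
                 source_kos = sort(unique(kos)),
                 reactions = universe$reaction_id[hit],
                 is_empty = nrow(edges) == 0),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("metabolic_network '%s': %d compounds, %d edges (%d reactions)%s\n",
              x$organism_id, length(x$compounds), nrow(x$edges),
              length(x$reactions), if (x$is_empty) " [EMPTY]" else ""))
  invisible(x)
}

#' Detect seed and non-seed compounds
#'
#' Computes the strongly connected components of the compound graph and
#' their condensation. Compounds in components with condensation in-degree
#' zero (source components) are seeds; each seed's confidence is
#' `1 / |its component|`, so confidences within one source component sum
#' to 1. All remaining compounds are non-seeds (internally producible).
#'
#' @param net a [build_network()] result.
#' @return Object of class `seed_set`: list with `organism_id`, `seeds`
#'   (named confidences in (0, 1]), `nonseeds` (character).
#' @examples
#' u <- gen_reaction_universe(8, 6, seed = 1)
#' net <- build_network(sprintf("K%05d", 1:6), u)
#' seed_set(net)
#' @export
seed_set <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  if (net$is_empty) {
    return(structure(list(organism_id = net$organism_id,
                          seeds = stats::setNames(numeric(0), character(0)),
                          nonseeds = character(0)),
                     class = "seed_set"))
  }
  g <- igraph::graph_from_edgelist(net$edges, directed = TRUE)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  verts <- igraph::V(g)$name
  # a component is a source iff no edge enters it from another component
  has_incoming <- rep(FALSE, comp$no)
  ends <- igraph::as_edgelist(g, names = TRUE)
  cross <- memb[ends[, 1]] != memb[ends[, 2]]
  has_incoming[unique(memb[ends[cross, 2]])] <- TRUE
  source_comps <- which(!has_incoming)
  is_seed <- memb[verts] %in% source_comps
  conf <- 1 / comp$csize[memb[verts]]
  seeds <- stats::setNames(conf[is_seed], verts[is_seed])
  seeds <- seeds[order(names(seeds))]
  structure(list(organism_id = net$organism_id,
                 seeds = seeds,
                 nonseeds = sort(verts[!is_seed])),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("seed_set '%s': %d seeds, %d non-seeds\n",
              x$organism_id, length(x$seeds), length(x$nonseeds)))
  invisible(x)
}

#' Pairwise competition index
#'
#' Fraction of A's seed compounds that are also seed compounds of B — how
#' much of A's required input B also requires (resource overlap). The
#' index is asymmetric: A owns the numerator's normalisation. With
#' `weighted = TRUE` the shared seeds are weighted by A's seed confidences.
#'
#' @param A,B [seed_set()] objects (A is the focal organism).
#' @param weighted weight by A's seed confidences instead of raw counts.
#' @return Fraction in `[0, 1]`; `NA` (flagged-undefined) when A has no
#'   seeds.
#' @export
competition_index <- function(A, B, weighted = FALSE) {
  stopifnot(inherits(A, "seed_set"), inherits(B, "seed_set"))
  if (!length(A$seeds)) return(NA_real_)
  shared <- intersect(names(A$seeds), names(B$seeds))
  if (weighted) {
    sum(A$seeds[shared]) / sum(A$seeds)
  } else {
    length(shared) / length(A$seeds)
  }
}

#' Pairwise complementarity index
#'
#' Fraction of A's seed compounds that are non-seed (internally
#' producible) compounds of B — the potential for B to cross-feed A.
#' Asymmetric, like [competition_index()].
#'
#' @inheritParams competition_index
#' @return Fraction in `[0, 1]`; `NA` when A has no seeds.
#' @export
complementarity_index <- function(A, B, weighted = FALSE) {
  stopifnot(inherits(A, "seed_set"), inherits(B, "seed_set"))
  if (!length(A$seeds)) return(NA_real_)
  fed <- intersect(names(A$seeds), B$nonseeds)
  if (weighted) {
    sum(A$seeds[fed]) / sum(A$seeds)
  } else {
    length(fed) / length(A$seeds)
  }
}

#' Expressed KO set from a transcript count profile
#'
#' A KO counts as actively expressed when its (replicate-summed) count is
#' at least `min_count` (default 1 mapped read — configurable because
#' "expressed" has no universal cutoff).
#'
#' @param expr a count-mode [ko_profile()].
#' @param min_count inclusive expression threshold.
#' @return Set-mode [ko_profile()], a subset of the input's KO support.
#' @export
expressed_kos <- function(expr, min_count = 1) {
  stopifnot(inherits(expr, "ko_profile"))
  if (expr$mode != "counts") stop_mg("expressed_kos expects a counts-mode profile")
  ko_profile(expr$unit_id, names(expr$kos)[expr$kos >= min_count], mode = "set")
}

#' All pairwise interaction indices for a set of organisms
#'
#' Builds each organism's network and seed set once, then computes
#' competition and complementarity for every ordered pair (diagonal
#' included: an organism competes fully with itself and cannot complement
#' itself). With `basis = "expressed"`, count-mode profiles are first
#' reduced to their expressed KO sets.
#'
#' @param organisms named list of [ko_profile()]s (>= 2).
#' @param universe a [reaction_universe()].
#' @param basis `"genome"` (use KO sets as given) or `"expressed"` (apply
#'   [expressed_kos()] first).
#' @param weighted weight indices by seed confidence.
#' @param min_count expression threshold for `basis = "expressed"`.
#' @param blacklist compound blacklist passed to [build_network()].
#' @return data.frame with columns `focal`, `partner`, `basis`,
#'   `competition`, `complementarity`, `flagged` (`TRUE` where either
#'   organism's network is empty; indices are `NA` there).
#' @export
pairwise_matrix <- function(organisms, universe,
                            basis = c("genome", "expressed"),
                            weighted = FALSE, min_count = 1,
                            blacklist = character(0)) {
  basis <- match.arg(basis)
  if (length(organisms) < 2) stop_mg("need >= 2 organisms")
  ids <- vapply(organisms, function(o) o$unit_id, character(1))
  if (anyDuplicated(ids)) stop_mg("duplicated organism ids")
  profs <- if (basis == "expressed") {
    lapply(organisms, expressed_kos, min_count = min_count)
  } else {
    organisms
  }
  nets <- lapply(profs, build_network, universe = universe,
                 blacklist = blacklist)
  seeds <- lapply(nets, seed_set)
  empty <- vapply(nets, `[[`, logical(1), "is_empty")
  grid <- expand.grid(focal = seq_along(ids), partner = seq_along(ids))
  grid <- grid[order(grid$focal, grid$partner), ]
  out <- data.frame(
    focal = ids[grid$focal],
    partner = ids[grid$partner],
    basis = basis,
    competition = mapply(function(i, j) competition_index(seeds[[i]], seeds[[j]], weighted),
                         grid$focal, grid$partner),
    complementarity = mapply(function(i, j) complementarity_index(seeds[[i]], seeds[[j]], weighted),
                             grid$focal, grid$partner),
    flagged = empty[grid$focal] | empty[grid$partner],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$competition[out$flagged] <- NA_real_
  out$complementarity[out$flagged] <- NA_real_
  out
}
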