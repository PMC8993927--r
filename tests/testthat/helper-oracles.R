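# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: hypergeometric tails are enumerated from binomial
# coefficients, and seed sets are derived from the definitional
# pairwise-reachability criterion, not from condensation.

# --- hypergeometric co-occurrence -------------------------------------------

# P(J = j) for the number of co-occurrence sites with fixed margins,
# enumerated term by term from binomial coefficients.
oracle_hyper_pmf <- function(N, nA, nB) {
  js <- max(0, nA + nB - N):min(nA, nB)
  p <- vapply(js, function(j) {
    choose(nA, j) * choose(N - nA, nB - j) / choose(N, nB)
  }, numeric(1))
  list(j = js, p = p)
}

oracle_hyper_tails <- function(j_obs, N, nA, nB) {
  pmf <- oracle_hyper_pmf(N, nA, nB)
  list(p_lt = sum(pmf$p[pmf$j <= j_obs]),
       p_gt = sum(pmf$p[pmf$j >= j_obs]))
}

# --- seed sets by definition ------------------------------------------------

# Reachability closure of a directed edge list over `nodes` (includes
# self-reachability).
oracle_reach <- function(nodes, edges) {
  n <- length(nodes)
  R <- diag(TRUE, n)
  dimnames(R) <- list(nodes, nodes)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) R[edges[i, 1], edges[i, 2]] <- TRUE
  }
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# Definitional seeds: c is a seed iff every vertex that reaches c is
# mutually reachable from c; its confidence is 1 / |SCC(c)| where SCC(c)
# is the mutual-reachability class of c.
oracle_seed_set <- function(nodes, edges) {
  R <- oracle_reach(nodes, edges)
  seeds <- numeric(0)
  nonseeds <- character(0)
  for (c_ in nodes) {
    reaches_c <- nodes[R[, c_]]
    mutual <- nodes[R[, c_] & R[c_, ]]
    if (all(reaches_c %in% mutual)) {
      seeds[c_] <- 1 / length(mutual)
    } else {
      nonseeds <- c(nonseeds, c_)
    }
  }
  list(seeds = seeds[order(names(seeds))], nonseeds = sort(nonseeds))
}

# Random digraph as an edge list over letter-ish node names.
random_digraph <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("c%02d", seq_len(n_nodes))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < p_edge
  list(nodes = nodes,
       edges = as.matrix(pairs[keep, c("from", "to")]))
}

# Wrap a bare edge list as a metabolic_network so seed_set() can run on
# arbitrary digraphs (only reachable via a reaction universe otherwise).
net_from_edges <- function(edges, organism_id = "test") {
  edges <- matrix(as.character(edges), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  structure(list(organism_id = organism_id,
                 compounds = sort(unique(c(edges[, 1], edges[, 2]))),
                 edges = edges,
                 source_kos = character(0),
                 reactions = character(0),
                 is_empty = nrow(edges) == 0),
            class = "metabolic_network")
}

# --- misc -------------------------------------------------------------------

# Brute-force recursive evaluation of a GMM step (independent of
# step_abundance's vapply formulation).
oracle_step_abundance <- function(step, cpm) {
  total <- 0
  for (alt in step) {
    worst <- Inf
    for (k in alt) {
      v <- if (k %in% names(cpm)) cpm[[k]] else 0
      if (v < worst) worst <- v
    }
    total <- total + worst
  }
  total
}

# Plain TSV matrix reader for checking CLI outputs without going through
# the package's own reader.
read_tsv_matrix_for_test <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

random_ko_profile <- function(unit, n, seed, mode = "counts") {
  set.seed(seed)
  kos <- sprintf("K%05d", sample.int(99999, n))
  ko_profile(unit, stats::setNames(rpois(n, 20) + 1, kos), mode = mode)
}
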