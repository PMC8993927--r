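chain_universe <- function() {
  # K00001: a -> b (irreversible); K00002: b <-> c; K00003: d -> c
  reaction_universe(data.frame(
    reaction_id = c("R1", "R2", "R3"),
    kos = I(list("K00001", "K00002", "K00003")),
    substrates = I(list("a", "b", "d")),
    products = I(list("b", "c", "c")),
    reversible = c(FALSE, TRUE, FALSE)))
}

test_that("build_network applies OR semantics and reversibility", {
  u <- chain_universe()
  net <- build_network(c("K00001"), u)
  expect_setequal(net$compounds, c("a", "b"))
  expect_equal(nrow(net$edges), 1)

  net2 <- build_network(c("K00002"), u)
  expect_equal(nrow(net2$edges), 2)  # b->c and c->b

  empty <- build_network(c("K99999"), u)
  expect_true(empty$is_empty)
  expect_length(empty$compounds, 0)
})

test_that("network edges match a brute-force triple loop on random universes", {
  for (s in 1:5) {
    u <- gen_reaction_universe(15, 12, max_arity = 3, seed = 100 + s)
    kos <- sprintf("K%05d", sample(1:12, 6))
    net <- build_network(kos, u)
    manual <- character(0)
    for (i in seq_len(nrow(u))) {
      if (!length(intersect(u$kos[[i]], kos))) next
      for (sub in u$substrates[[i]]) for (prd in u$products[[i]]) {
        manual <- c(manual, paste(sub, prd, sep = "->"))
        if (u$reversible[i]) manual <- c(manual, paste(prd, sub, sep = "->"))
      }
    }
    got <- paste(net$edges[, "from"], net$edges[, "to"], sep = "->")
    expect_setequal(got, unique(manual))
  }
})

test_that("seed sets on worked digraphs match frozen expectations", {
  # chain a -> b -> c: the only source is a
  s1 <- seed_set(net_from_edges(rbind(c("a", "b"), c("b", "c"))))
  expect_equal(s1$seeds, c(a = 1))
  expect_identical(s1$nonseeds, c("b", "c"))

  # a<->b cycle feeding c, plus d -> c: sources {a,b} (conf 1/2) and {d}
  s2 <- seed_set(net_from_edges(rbind(c("a", "b"), c("b", "a"),
                                      c("b", "c"), c("d", "c"))))
  expect_equal(s2$seeds, c(a = 0.5, b = 0.5, d = 1))
  expect_identical(s2$nonseeds, "c")

  # fully cyclic: every compound is a seed with confidence 1/n
  s3 <- seed_set(net_from_edges(rbind(c("a", "b"), c("b", "c"), c("c", "a"))))
  expect_equal(s3$seeds, c(a = 1/3, b = 1/3, c = 1/3))
  expect_length(s3$nonseeds, 0)
})

test_that("condensation seeds equal definitional brute force on random digraphs", {
  for (s in 1:60) {
    g <- random_digraph(sample(2:12, 1), runif(1, 0.05, 0.4), seed = 500 + s)
    if (!nrow(g$edges)) next
    got <- seed_set(net_from_edges(g$edges))
    nodes <- sort(unique(c(g$edges[, 1], g$edges[, 2])))
    want <- oracle_seed_set(nodes, g$edges)
    expect_equal(got$seeds, want$seeds, tolerance = 1e-12)
    expect_identical(got$nonseeds, want$nonseeds)
    # confidence normalisation: each source component sums to 1
    if (length(got$seeds)) {
      comp_sum <- tapply(got$seeds, round(1 / got$seeds), sum)
      expect_true(all(abs(comp_sum - round(comp_sum)) < 1e-9))
    }
  }
})

test_that("competition and complementarity are definitional set ratios", {
  mk <- function(id, seeds, nonseeds) {
    structure(list(organism_id = id,
                   seeds = stats::setNames(rep(1, length(seeds)), seeds),
                   nonseeds = nonseeds), class = "seed_set")
  }
  A <- mk("A", c("a", "b"), c("x"))
  B <- mk("B", c("b", "c"), c("a"))
  expect_equal(competition_index(A, B), 0.5)
  expect_equal(competition_index(A, A), 1)
  expect_equal(complementarity_index(A, A), 0)
  expect_equal(complementarity_index(A, B), 0.5)  # a is producible by B
  expect_equal(complementarity_index(mk("C", "x", character(0)), B), 0)
  disj <- mk("D", c("p", "q"), character(0))
  expect_equal(competition_index(A, disj), 0)
  expect_true(is.na(competition_index(mk("E", character(0), "a"), B)))
})

test_that("weighted indices use seed confidences", {
  A <- structure(list(organism_id = "A",
                      seeds = c(a = 0.5, b = 0.5, d = 1),
                      nonseeds = "c"), class = "seed_set")
  B <- structure(list(organism_id = "B",
                      seeds = c(a = 1), nonseeds = c("b", "d")),
                 class = "seed_set")
  expect_equal(competition_index(A, B, weighted = TRUE), 0.5 / 2)
  expect_equal(complementarity_index(A, B, weighted = TRUE), 1.5 / 2)
  expect_equal(competition_index(A, B), 1 / 3)
  expect_equal(complementarity_index(A, B), 2 / 3)
})

test_that("expressed_kos thresholds counts into a set profile", {
  expr <- ko_profile("e", c(K00001 = 5, K00002 = 1, K00003 = 0),
                     mode = "counts")
  expect_setequal(ko_ids(expressed_kos(expr)), c("K00001", "K00002"))
  expect_length(ko_ids(expressed_kos(expr, min_count = 10)), 0)
  set.seed(4)
  p <- random_ko_profile("r", 30, seed = 44)
  thr <- 15
  manual <- names(p$kos)[p$kos >= thr]
  expect_setequal(ko_ids(expressed_kos(p, thr)), manual)
  expect_error(expressed_kos(ko_profile("s", "K00001", mode = "set")),
               "counts-mode")
})

test_that("pairwise matrix satisfies diagonal invariants and brute force", {
  u <- gen_reaction_universe(12, 14, seed = 7)
  orgs <- lapply(1:4, function(i) {
    ko_profile(paste0("org", i), sprintf("K%05d", sample(1:14, 5)),
               mode = "set")
  })
  set.seed(71)
  mat <- pairwise_matrix(orgs, u, basis = "genome")
  expect_equal(nrow(mat), 16)
  seeds <- lapply(orgs, function(o) seed_set(build_network(o, u)))
  names(seeds) <- vapply(orgs, `[[`, character(1), "unit_id")
  for (r in seq_len(nrow(mat))) {
    if (mat$flagged[r]) next
    A <- seeds[[mat$focal[r]]]; B <- seeds[[mat$partner[r]]]
    expect_equal(mat$competition[r], competition_index(A, B))
    expect_equal(mat$complementarity[r], complementarity_index(A, B))
  }
  diag_rows <- mat[mat$focal == mat$partner & !mat$flagged, ]
  expect_true(all(diag_rows$competition == 1))
  expect_true(all(diag_rows$complementarity == 0))

  # identical organisms: full competition, no complementarity
  two <- list(ko_profile("x1", "K00001", mode = "set"),
              ko_profile("x2", "K00001", mode = "set"))
  m2 <- pairwise_matrix(two, chain_universe())
  expect_true(all(m2$competition == 1))
  expect_true(all(m2$complementarity == 0))
})

test_that("expressed basis with full expression equals genome basis", {
  u <- gen_reaction_universe(14, 12, seed = 31)
  genomes <- lapply(1:3, function(i) {
    ko_profile(paste0("g", i), sprintf("K%05d", sample(1:12, 6)), mode = "set")
  })
  set.seed(99)
  expr <- lapply(genomes, function(g) {
    p <- gen_expression_subset(g, 1.0, seed = 5)
    ko_profile(g$unit_id, p$kos, mode = "counts")
  })
  mg <- pairwise_matrix(genomes, u, basis = "genome")
  me <- pairwise_matrix(expr, u, basis = "expressed")
  expect_equal(me$competition, mg$competition)
  expect_equal(me$complementarity, mg$complementarity)
})

test_that("complementarity is monotone when B learns to make one of A's seeds", {
  # adding to B a reaction converting one of A's seeds into B's interior
  # can only increase or preserve complementarity(A -> B)
  for (s in 1:20) {
    u <- gen_reaction_universe(14, 10, p_reversible = 0, seed = 900 + s)
    a_kos <- sprintf("K%05d", sample(1:10, 4))
    b_kos <- sprintf("K%05d", sample(1:10, 4))
    sa <- seed_set(build_network(a_kos, u))
    sb <- seed_set(build_network(b_kos, u))
    if (!length(sa$seeds)) next
    target <- names(sa$seeds)[1]
    # reaction producing A's seed inside B's network, fed from a fresh
    # compound so no existing cycle can be created
    extra <- data.frame(reaction_id = "RX", kos = I(list("K99999")),
                        substrates = I(list("Cnew")),
                        products = I(list(target)), reversible = FALSE)
    u2 <- reaction_universe(rbind(u, extra))
    sb2 <- seed_set(build_network(c(b_kos, "K99999"), u2))
    base <- complementarity_index(sa, sb)
    grown <- complementarity_index(sa, sb2)
    expect_gte(grown, base - 1e-12)
  }
})
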