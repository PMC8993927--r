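# Synthetic-data generators. Every generator is a pure function of its
# parameters and a single integer seed (bit-identical on repeat calls), and
# returns its ground truth alongside the data so downstream recovery tests
# never rely on hidden state.

#' Simulate a prevalence/abundance-structured taxon table
#'
#' Emulates a large cross-sectional stool metagenome survey: each taxon is
#' present in a sample with its own prevalence probability, and nonzero
#' abundances are lognormal, renormalised per sample to sum to 1.
#'
#' @param n_samples,n_taxa dimensions (>= 1).
#' @param prevalence per-taxon presence probability, recycled to `n_taxa`.
#' @param lognormal_mean,lognormal_sd meanlog/sdlog of nonzero abundances
#'   before renormalisation. Defaults give the heavy-tailed, ~2-order-of-
#'   magnitude abundance spread typical of gut species profiles.
#' @param seed RNG seed.
#' @return [taxon_table()] with attribute `prevalence` (the truth).
#' @export
gen_abundance_table <- function(n_samples, n_taxa, prevalence = 0.5,
                                lognormal_mean = 0, lognormal_sd = 1,
                                seed = 1) {
  if (n_samples < 1 || n_taxa < 1) stop_mg("n_samples and n_taxa must be >= 1")
  prevalence <- rep_len(prevalence, n_taxa)
  if (any(prevalence < 0 | prevalence > 1)) stop_mg("prevalence must be in [0, 1]")
  with_seed(seed, {
    present <- vapply(prevalence,
                      function(p) rbinom(n_samples, 1L, p),
                      integer(n_samples))
    present <- matrix(present, nrow = n_samples)
    ab <- matrix(rlnorm(n_samples * n_taxa, lognormal_mean, lognormal_sd),
                 nrow = n_samples) * present
    rs <- rowSums(ab)
    ab[rs > 0, ] <- ab[rs > 0, , drop = FALSE] / rs[rs > 0]
    tt <- taxon_table(ab,
                      sample_ids = sprintf("S%04d", seq_len(n_samples)),
                      taxon_ids = sprintf("taxon%03d", seq_len(n_taxa)))
    attr(tt, "prevalence") <- stats::setNames(prevalence, tt$taxon_ids)
    tt
  })
}

#' Planted pairwise association for co-occurrence simulations
#'
#' @param taxa character vector of two taxon ids.
#' @param direction `"positive"` or `"negative"`.
#' @param strength shift of the co-presence probability away from the
#'   independent value `base_prob^2`, in `[0, 1]`.
#' @export
planted_association <- function(taxa, direction = c("positive", "negative"),
                                strength) {
  direction <- match.arg(direction)
  if (length(taxa) != 2 || taxa[1] == taxa[2]) stop_mg("need two distinct taxa")
  if (strength < 0 || strength > 1) stop_mg("strength must be in [0, 1]")
  structure(list(taxa = as.character(taxa), direction = direction,
                 strength = strength),
            class = "planted_association")
}

#' Simulate a presence/absence matrix with planted associations
#'
#' Unplanted taxa are independent Bernoulli(`base_prob`). A planted pair is
#' drawn jointly from the 2x2 distribution with both marginals `base_prob`
#' and co-presence probability `base_prob^2 + strength` (positive) or
#' `base_prob^2 - strength` (negative) — a mixture construction whose
#' pairwise probabilities are known analytically.
#'
#' @param n_samples,n_taxa dimensions.
#' @param base_prob marginal presence probability, in (0, 1).
#' @param planted list of [planted_association()] objects; a taxon may
#'   appear in at most one.
#' @param seed RNG seed.
#' @return [presence_absence()] with attribute `planted`.
#' @export
gen_presence_absence <- function(n_samples, n_taxa, base_prob = 0.5,
                                 planted = list(), seed = 1) {
  if (n_samples < 1 || n_taxa < 1) stop_mg("n_samples and n_taxa must be >= 1")
  if (base_prob <= 0 || base_prob >= 1) stop_mg("base_prob must be in (0, 1)")
  taxa <- sprintf("taxon%03d", seq_len(n_taxa))
  planted_taxa <- unlist(lapply(planted, `[[`, "taxa"))
  if (anyDuplicated(planted_taxa)) stop_mg("a taxon may appear in at most one planted pair")
  if (length(planted_taxa) && !all(planted_taxa %in% taxa)) {
    stop_mg("planted taxa must be among taxon001..taxon%03d", n_taxa)
  }
  p <- base_prob
  with_seed(seed, {
    m <- matrix(rbinom(n_samples * n_taxa, 1L, p), nrow = n_samples,
                dimnames = list(sprintf("S%04d", seq_len(n_samples)), taxa))
    for (pl in planted) {
      p11 <- p^2 + if (pl$direction == "positive") pl$strength else -pl$strength
      p10 <- p - p11
      p00 <- 1 - 2 * p + p11
      if (p11 < 0 || p10 < 0 || p00 < 0) {
        stop_mg("infeasible strength %.3g for base_prob %.3g (%s pair)",
                pl$strength, p, pl$direction)
      }
      # cells ordered (1,1), (1,0), (0,1), (0,0)
      cell <- sample.int(4L, n_samples, replace = TRUE,
                         prob = c(p11, p10, p10, p00))
      m[, pl$taxa[1]] <- as.integer(cell %in% c(1L, 2L))
      m[, pl$taxa[2]] <- as.integer(cell %in% c(1L, 3L))
    }
    pa <- presence_absence(m)
    attr(pa, "planted") <- planted
    pa
  })
}

#' Simulate per-sample KO profiles with a planted core
#'
#' Emulates a panel of gut metagenome KO profiles in which "core" functions
#' occur in most samples and "variable" functions in fewer, with known
#' truth labels for core-KO recovery tests.
#'
#' @param n_samples number of metagenome profiles.
#' @param n_core_kos,n_variable_kos counts of planted core / variable KOs.
#' @param core_prev per-sample presence probability of a core KO
#'   (>= the screening prevalence, conventionally 0.75).
#' @param var_prev presence probability of a variable KO (< 0.75).
#' @param seed RNG seed.
#' @return List with `profiles` (set-mode [ko_profile()]s), `core_kos`,
#'   `variable_kos` (the truth labels).
#' @export
gen_ko_profiles <- function(n_samples, n_core_kos, n_variable_kos,
                            core_prev = 0.9, var_prev = 0.3, seed = 1) {
  if (n_samples < 1) stop_mg("n_samples must be >= 1")
  if (any(c(core_prev, var_prev) < 0 | c(core_prev, var_prev) > 1)) {
    stop_mg("prevalences must be in [0, 1]")
  }
  core <- sprintf("K%05d", seq_len(n_core_kos))
  var <- sprintf("K%05d", n_core_kos + seq_len(n_variable_kos))
  with_seed(seed, {
    profiles <- lapply(seq_len(n_samples), function(i) {
      present <- c(core[runif(n_core_kos) < core_prev],
                   var[runif(n_variable_kos) < var_prev])
      ko_profile(sprintf("mg%03d", i), present, mode = "set")
    })
    list(profiles = profiles, core_kos = core, variable_kos = var)
  })
}

#' Ground truth for one simulated community
#'
#' `abundances` are on a cell-count scale; the 16S copies contributed by a
#' species are `abundance * copy_number`, which is what both the amplicon
#' read share and the qPCR total respond to.
#'
#' @param abundances named positive numeric vector, species -> abundance.
#' @param copy_numbers [copy_number_table()] covering all species.
#' @param sequencing_depth total reads to simulate (`Inf` = expected-count
#'   limit).
#' @export
community_truth <- function(abundances, copy_numbers, sequencing_depth = 1e5) {
  if (is.null(names(abundances)) || anyDuplicated(names(abundances))) {
    stop_mg("abundances need unique species names")
  }
  if (any(abundances <= 0)) stop_mg("abundances must be > 0")
  if (!all(names(abundances) %in% names(copy_numbers))) {
    stop_mg("every species needs a 16S copy number")
  }
  if (!is.infinite(sequencing_depth) && sequencing_depth < 1) {
    stop_mg("sequencing depth must be >= 1")
  }
  structure(list(abundances = abundances,
                 copy_numbers = copy_numbers,
                 sequencing_depth = sequencing_depth),
            class = "community_truth")
}

#' Simulate an amplicon + qPCR quantification experiment
#'
#' Reads are multinomial with per-species expected share proportional to
#' `abundance * copy_number` (amplicons count 16S gene copies, so high-copy
#' species are over-represented — the bias the profiling pipeline removes).
#' The qPCR total is the true total copy count `sum(abundance*copy_number)`
#' perturbed by mean-1 lognormal noise with coefficient of variation
#' `qpcr_cv`.
#'
#' @param truth a [community_truth()].
#' @param qpcr_cv coefficient of variation of the qPCR measurement (>= 0).
#' @param seed RNG seed.
#' @param sample_id sample name used in the outputs.
#' @return List with `counts` ([species_count_table()], one sample),
#'   `qpcr` ([qpcr_totals()]) and `truth`: the input truth plus
#'   `total_copies` and `expected_absolute`, the ground-truth absolute
#'   profile on the pipeline's output scale
#'   (`abundance/sum(abundance) * total_copies`).
#' @export
gen_amplicon_experiment <- function(truth, qpcr_cv = 0.05, seed = 1,
                                    sample_id = "S1") {
  stopifnot(inherits(truth, "community_truth"))
  if (qpcr_cv < 0) stop_mg("qpcr_cv must be >= 0")
  a <- truth$abundances
  cn <- as.numeric(unclass(truth$copy_numbers)[names(a)])
  copies <- a * cn
  share <- copies / sum(copies)
  with_seed(seed, {
    depth <- truth$sequencing_depth
    counts <- if (is.infinite(depth)) {
      share * 1e6  # expected-count limit at a nominal depth
    } else {
      as.numeric(rmultinom(1, size = depth, prob = share))
    }
    total <- if (qpcr_cv == 0) {
      sum(copies)
    } else {
      sdlog <- sqrt(log(1 + qpcr_cv^2))
      sum(copies) * rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    truth$total_copies <- sum(copies)
    truth$expected_absolute <- a / sum(a) * sum(copies)
    list(
      counts = species_count_table(matrix(counts, ncol = 1,
                                          dimnames = list(names(a), sample_id))),
      qpcr = qpcr_totals(stats::setNames(total, sample_id)),
      truth = truth
    )
  })
}

#' Simulate a toy reaction universe
#'
#' Random irreversible/reversible reactions over a compound pool, each with
#' its own (unique) KOs, suitable for planting cross-feeding pairs.
#'
#' @param n_compounds,n_reactions pool sizes.
#' @param max_arity maximum substrates (and products) per reaction.
#' @param p_reversible probability a reaction is reversible.
#' @param seed RNG seed.
#' @return [reaction_universe()].
#' @export
gen_reaction_universe <- function(n_compounds, n_reactions, max_arity = 2,
                                  p_reversible = 0.25, seed = 1) {
  if (n_compounds < 2 || n_reactions < 1) {
    stop_mg("need >= 2 compounds and >= 1 reaction")
  }
  cmpd <- sprintf("C%05d", seq_len(n_compounds))
  with_seed(seed, {
    recs <- lapply(seq_len(n_reactions), function(r) {
      ns <- sample.int(max_arity, 1)
      np <- sample.int(max_arity, 1)
      picks <- sample(cmpd, min(ns + np, n_compounds))
      ns <- min(ns, length(picks) - 1)
      list(reaction_id = sprintf("R%05d", r),
           kos = sprintf("K%05d", r),
           substrates = picks[seq_len(ns)],
           products = picks[-seq_len(ns)],
           reversible = runif(1) < p_reversible)
    })
    reaction_universe(data.frame(
      reaction_id = vapply(recs, `[[`, character(1), "reaction_id"),
      kos = I(lapply(recs, `[[`, "kos")),
      substrates = I(lapply(recs, `[[`, "substrates")),
      products = I(lapply(recs, `[[`, "products")),
      reversible = vapply(recs, `[[`, logical(1), "reversible"),
      stringsAsFactors = FALSE
    ))
  })
}

# Reactions of `universe` whose KO set intersects `kos`.
matched_reactions <- function(kos, universe) {
  which(vapply(universe$kos, function(k) length(intersect(k, kos)) > 0,
               logical(1)))
}

#' Plant a cross-feeding pair of organisms in a reaction universe
#'
#' Constructs KO profiles A and B such that, by construction, at least one
#' seed compound of A (required from the environment) is a non-seed
#' (internally producible) compound of B — i.e. B can feed A. The returned
#' certificate names the compound and the donor/acceptor reactions; the
#' construction is verified combinatorially here, independently of the
#' seed-set machinery it is used to test.
#'
#' @param universe a [reaction_universe()].
#' @param seed RNG seed (randomises which feasible pair is picked).
#' @return List `a`, `b` (set-mode [ko_profile()]s) and `certificate`
#'   (`compound`, `donor_reaction` in B, `acceptor_reaction` in A).
#' @export
gen_crossfeeding_pair <- function(universe, seed = 1) {
  stopifnot(inherits(universe, "reaction_universe"))
  n <- nrow(universe)
  irrev <- which(!universe$reversible)
  with_seed(seed, {
    for (rb in sample(irrev)) {
      for (ra in sample(irrev)) {
        if (ra == rb) next
        p <- intersect(universe$products[[rb]], universe$substrates[[ra]])
        if (!length(p)) next
        p <- p[1]
        a_kos <- universe$kos[[ra]]
        b_kos <- universe$kos[[rb]]
        # verify the construction on the implied reaction sets
        a_rxn <- matched_reactions(a_kos, universe)
        b_rxn <- matched_reactions(b_kos, universe)
        # p must be a pure source in A's network ...
        a_prod <- unlist(universe$products[a_rxn])
        a_rev_sub <- unlist(universe$substrates[a_rxn[universe$reversible[a_rxn]]])
        if (p %in% a_prod || p %in% a_rev_sub) next
        # ... and a pure sink (with an incoming edge) in B's network
        b_sub <- unlist(universe$substrates[b_rxn])
        b_rev_prod <- unlist(universe$products[b_rxn[universe$reversible[b_rxn]]])
        if (p %in% b_sub || p %in% b_rev_prod) next
        return(list(
          a = ko_profile("orgA", a_kos, mode = "set"),
          b = ko_profile("orgB", b_kos, mode = "set"),
          certificate = list(compound = p,
                             donor_reaction = universe$reaction_id[rb],
                             acceptor_reaction = universe$reaction_id[ra])
        ))
      }
    }
    stop_mg("universe too small to plant a cross-feeding pair")
  })
}

#' Subsample a genome KO set into an expressed transcriptome
#'
#' Models "actively expressed" genes as a random subset of the genome's
#' KOs, with counts drawn per expressed KO, as when only part of a genome
#' is transcribed under a given condition.
#'
#' @param genome a [ko_profile()] (any mode; its KO support is used).
#' @param expressed_fraction fraction of genome KOs expressed, in (0, 1].
#' @param seed RNG seed.
#' @param weights optional nonnegative sampling weights named by KO;
#'   unnamed KOs get weight 1. Use to express some KOs preferentially.
#' @return Count-mode [ko_profile()] whose KO set is a subset of the
#'   genome's.
#' @export
gen_expression_subset <- function(genome, expressed_fraction, seed = 1,
                                  weights = NULL) {
  stopifnot(inherits(genome, "ko_profile"))
  if (expressed_fraction <= 0 || expressed_fraction > 1) {
    stop_mg("expressed_fraction must be in (0, 1]")
  }
  pool <- ko_ids(genome)
  k <- max(1L, round(expressed_fraction * length(pool)))
  with_seed(seed, {
    w <- rep(1, length(pool))
    if (!is.null(weights)) {
      hit <- match(pool, names(weights))
      w[!is.na(hit)] <- weights[hit[!is.na(hit)]]
    }
    expressed <- if (k >= length(pool)) pool else sample(pool, k, prob = w)
    counts <- 1 + rpois(length(expressed), lambda = 9)
    ko_profile(paste0(genome$unit_id, "_expr"),
               stats::setNames(counts, expressed), mode = "counts")
  })
}
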