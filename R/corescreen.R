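# Core-microbiota screening, probabilistic species co-occurrence, and
# consortium functional (KO) coverage. All threshold comparisons are
# inclusive: "at least 50% occupancy" and "a minimum relative abundance of
# x" both read as >=.

#' Per-taxon occupancy at a detection threshold
#'
#' Occupancy of a taxon is the fraction of samples in which its relative
#' abundance is at or above `detection`.
#'
#' @param table a [taxon_table()].
#' @param detection inclusive relative-abundance threshold (>= 0). Note
#'   that `detection = 0` counts every cell, zeros included.
#' @return Named numeric vector taxon -> occupancy in `[0, 1]`.
#' @export
compute_occupancy <- function(table, detection = 1e-4) {
  stopifnot(inherits(table, "taxon_table"))
  if (detection < 0) stop_mg("detection must be >= 0")
  if (nrow(table$values) == 0 || ncol(table$values) == 0) {
    stop_mg("empty taxon table")
  }
  colMeans(table$values >= detection)
}

#' Select the core microbiota
#'
#' Core taxa are those detected (abundance >= `detection`) in at least
#' `occupancy_min` of the samples — the standard occupancy/detection core
#' screen (e.g. 50% of subjects at minimum relative abundance 1e-4).
#'
#' @inheritParams compute_occupancy
#' @param occupancy_min inclusive occupancy threshold in `[0, 1]`.
#' @return Object of class `core_screen_result`: list with `occupancy`,
#'   `detection`, `occupancy_min`, `core_taxa`.
#' @export
select_core <- function(table, detection = 1e-4, occupancy_min = 0.5) {
  if (occupancy_min < 0 || occupancy_min > 1) {
    stop_mg("occupancy_min must be in [0, 1]")
  }
  occ <- compute_occupancy(table, detection)
  structure(list(occupancy = occ,
                 detection = detection,
                 occupancy_min = occupancy_min,
                 core_taxa = names(occ)[occ >= occupancy_min]),
            class = "core_screen_result")
}

#' @export
print.core_screen_result <- function(x, ...) {
  cat(sprintf(
    "core screen: %d/%d taxa core (occupancy >= %g at detection %g)\n",
    length(x$core_taxa), length(x$occupancy), x$occupancy_min, x$detection))
  invisible(x)
}

#' Occupancy-abundance summary per taxon
#'
#' For each taxon: occupancy at `detection`, and its mean relative
#' abundance over the samples where it is detected. A taxon never detected
#' gets occupancy 0 and `mean_abundance = NA` with `detected = FALSE`
#' (flagged, not silently propagated).
#'
#' @inheritParams compute_occupancy
#' @return data.frame with columns `taxon_id`, `occupancy`,
#'   `mean_abundance`, `detected`.
#' @export
occupancy_abundance <- function(table, detection = 1e-4) {
  occ <- compute_occupancy(table, detection)
  mean_ab <- vapply(seq_along(occ), function(j) {
    v <- table$values[, j]
    v <- v[v >= detection]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  data.frame(taxon_id = names(occ), occupancy = unname(occ),
             mean_abundance = mean_ab, detected = !is.na(mean_ab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Probabilistic co-occurrence of one species pair
#'
#' The hypergeometric (fixed-margins) model of species co-occurrence: with
#' `nA` and `nB` presences among `N` samples, the number of co-occurrence
#' sites under random placement is hypergeometric, and the observed count
#' `j_obs` is scored by its two tail probabilities
#' `p_lt = P(J <= j_obs)` and `p_gt = P(J >= j_obs)` (both tails include
#' the observed value). Pairs with expected co-occurrence
#' `nA*nB/N < min_expected` are classified `excluded`; otherwise
#' `positive` if `p_gt < alpha`, `negative` if `p_lt < alpha`, else
#' `random`.
#'
#' @param pa a [presence_absence()] matrix.
#' @param A,B distinct taxon ids present in the matrix.
#' @param alpha significance level for the one-tailed tests.
#' @param min_expected exclusion threshold on expected co-occurrences.
#' @return Object of class `cooccurrence_pair`: list with `taxa`, `N`,
#'   `nA`, `nB`, `j_obs`, `expected`, `p_lt`, `p_gt`, `class`.
#' @examples
#' pa <- presence_absence(diag(1, 4, 2))
#' pair_cooccurrence(pa, "taxon1", "taxon2")$class
#' @export
pair_cooccurrence <- function(pa, A, B, alpha = 0.05, min_expected = 1.0) {
  stopifnot(inherits(pa, "presence_absence"))
  if (identical(A, B)) stop_mg("A and B must be distinct taxa")
  for (t in c(A, B)) {
    if (!t %in% pa$taxon_ids) stop_mg("taxon '%s' not in matrix", t)
  }
  va <- pa$values[, A]
  vb <- pa$values[, B]
  N <- length(va)
  nA <- sum(va)
  nB <- sum(vb)
  j_obs <- sum(va & vb)
  expected <- nA * nB / N
  # J ~ Hypergeometric(N, nA, nB): both tails include P(J = j_obs)
  p_lt <- phyper(j_obs, nA, N - nA, nB)
  p_gt <- phyper(j_obs - 1, nA, N - nA, nB, lower.tail = FALSE)
  cls <- if (expected < min_expected) "excluded"
         else if (p_gt < alpha) "positive"
         else if (p_lt < alpha) "negative"
         else "random"
  structure(list(taxa = c(A, B), N = N, nA = nA, nB = nB, j_obs = j_obs,
                 expected = expected, p_lt = p_lt, p_gt = p_gt, class = cls),
            class = "cooccurrence_pair")
}

#' @export
print.cooccurrence_pair <- function(x, ...) {
  cat(sprintf("%s ~ %s: j=%d (exp %.2f), p_lt=%.3g, p_gt=%.3g -> %s\n",
              x$taxa[1], x$taxa[2], x$j_obs, x$expected,
              x$p_lt, x$p_gt, x$class))
  invisible(x)
}

#' All pairwise co-occurrence classifications
#'
#' @inheritParams pair_cooccurrence
#' @param taxa taxa to test (default: all in the matrix).
#' @param p_adjust apply a Benjamini-Hochberg correction to each tail
#'   across pairs before classification (off by default, matching the
#'   convention of the probabilistic co-occurrence model).
#' @return data.frame, one row per unordered pair, columns `taxon_A`,
#'   `taxon_B`, `N`, `nA`, `nB`, `j_obs`, `expected`, `p_lt`, `p_gt`,
#'   `class`.
#' @export
cooccurrence_table <- function(pa, taxa = pa$taxon_ids, alpha = 0.05,
                               min_expected = 1.0, p_adjust = FALSE) {
  if (length(taxa) < 2) {
    return(data.frame(taxon_A = character(0), taxon_B = character(0),
                      N = integer(0), nA = integer(0), nB = integer(0),
                      j_obs = integer(0), expected = numeric(0),
                      p_lt = numeric(0), p_gt = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  idx <- utils::combn(taxa, 2)
  rows <- lapply(seq_len(ncol(idx)), function(i) {
    p <- pair_cooccurrence(pa, idx[1, i], idx[2, i], alpha, min_expected)
    data.frame(taxon_A = p$taxa[1], taxon_B = p$taxa[2], N = p$N,
               nA = p$nA, nB = p$nB, j_obs = p$j_obs, expected = p$expected,
               p_lt = p$p_lt, p_gt = p$p_gt, class = p$class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust) {
    keep <- out$class != "excluded"
    out$p_lt[keep] <- stats::p.adjust(out$p_lt[keep], "BH")
    out$p_gt[keep] <- stats::p.adjust(out$p_gt[keep], "BH")
    out$class[keep] <- ifelse(out$p_gt[keep] < alpha, "positive",
                       ifelse(out$p_lt[keep] < alpha, "negative", "random"))
  }
  out
}

#' Fraction of samples containing every focal taxon
#'
#' @param pa a [presence_absence()] matrix.
#' @param focal_taxa nonempty subset of the matrix's taxa.
#' @return List with `fraction` (samples with all focal taxa present) and
#'   `richness` (per-sample count of focal taxa present).
#' @export
consortium_copresence <- function(pa, focal_taxa) {
  stopifnot(inherits(pa, "presence_absence"))
  if (!length(focal_taxa)) stop_mg("focal taxon set is empty")
  missing <- setdiff(focal_taxa, pa$taxon_ids)
  if (length(missing)) stop_mg("taxa not in matrix: %s",
                               paste(missing, collapse = ", "))
  sub <- pa$values[, focal_taxa, drop = FALSE]
  richness <- rowSums(sub)
  list(fraction = mean(richness == length(focal_taxa)),
       richness = richness)
}

#' Fraction of positively co-occurring pairs
#'
#' Among non-excluded pairs, the fraction classified positive. Because the
#' convention on whether excluded pairs belong in the denominator varies,
#' the fraction over all pairs is reported alongside.
#'
#' @param pairs a data.frame from [cooccurrence_table()] (or any with a
#'   `class` column).
#' @return List with `fraction` (positive / non-excluded; `NA` if every
#'   pair was excluded), `fraction_all_pairs`, `n_positive`,
#'   `n_nonexcluded`, `n_pairs`.
#' @export
positive_pair_fraction <- function(pairs) {
  cls <- pairs$class
  if (!length(cls)) stop_mg("no pairs supplied")
  nonex <- cls != "excluded"
  list(
    fraction = if (any(nonex)) mean(cls[nonex] == "positive") else NA_real_,
    fraction_all_pairs = mean(cls == "positive"),
    n_positive = sum(cls == "positive"),
    n_nonexcluded = sum(nonex),
    n_pairs = length(cls)
  )
}

#' Core KO set across metagenome profiles
#'
#' A KO is core when it is present at least once in at least `prevalence`
#' of the profiles (presence = abundance > 0).
#'
#' @param profiles nonempty list of [ko_profile()]s (set or counts mode).
#' @param prevalence inclusive prevalence threshold, conventionally 0.75.
#' @return Character vector of core KO ids (sorted).
#' @export
core_kos <- function(profiles, prevalence = 0.75) {
  if (!length(profiles)) stop_mg("empty profile list")
  if (prevalence < 0 || prevalence > 1) stop_mg("prevalence must be in [0, 1]")
  sets <- lapply(profiles, ko_ids)
  tab <- table(unlist(sets))
  sort(names(tab)[tab / length(profiles) >= prevalence])
}

#' Consortium coverage of a core KO set
#'
#' Coverage is the fraction of core KOs found in the union of the
#' consortium genomes' KO sets — how much of the core functional repertoire
#' a defined community captures.
#'
#' @param core nonempty character vector of core KO ids.
#' @param genomes list of [ko_profile()]s, one per consortium member.
#' @return Object of class `coverage_result`: list with `core_ko_set`,
#'   `consortium_kos`, `covered_kos`, `coverage`.
#' @export
ko_coverage <- function(core, genomes) {
  if (!length(core)) stop_mg("core KO set is empty")
  union_kos <- sort(unique(unlist(lapply(genomes, ko_ids))))
  covered <- intersect(core, union_kos)
  structure(list(core_ko_set = sort(unique(core)),
                 consortium_kos = union_kos,
                 covered_kos = covered,
                 coverage = length(covered) / length(unique(core))),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("KO coverage: %d/%d core KOs covered (%.1f%%)\n",
              length(x$covered_kos), length(x$core_ko_set),
              100 * x$coverage))
  invisible(x)
}
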