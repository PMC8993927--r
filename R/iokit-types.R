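#' Taxon relative-abundance table
#'
#' A samples-by-taxa matrix of relative abundances in `[0, 1]`. Per-sample
#' sums may be below 1 (tables may be partial, e.g. after dropping
#' unclassified taxa) but never meaningfully above it.
#'
#' @param values numeric matrix, rows = samples, columns = taxa.
#' @param sample_ids,taxon_ids identifiers; default to `dimnames(values)`.
#' @return An object of class `taxon_table` with elements `values`,
#'   `sample_ids`, `taxon_ids`.
#' @examples
#' tt <- taxon_table(matrix(c(0.5, 0.2, 0.5, 0.8), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("taxA", "taxB"))))
#' tt$values
#' @export
taxon_table <- function(values, sample_ids = rownames(values),
                        taxon_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%d", seq_len(nrow(values)))
  if (is.null(taxon_ids)) taxon_ids <- sprintf("taxon%d", seq_len(ncol(values)))
  dimnames(values) <- list(sample_ids, taxon_ids)
  out <- structure(
    list(values = values, sample_ids = sample_ids, taxon_ids = taxon_ids),
    class = "taxon_table"
  )
  validate_taxon_table(out)
}

#' @rdname taxon_table
#' @param x a `taxon_table`.
#' @export
validate_taxon_table <- function(x) {
  v <- x$values
  if (!is.numeric(v)) stop_mg("taxon_table values must be numeric")
  if (anyNA(v)) stop_mg("taxon_table contains missing values; missing cells are errors, not zeros")
  if (any(v < 0)) stop_mg("taxon_table contains negative abundances")
  if (anyDuplicated(x$sample_ids)) stop_mg("duplicated sample identifiers")
  if (anyDuplicated(x$taxon_ids)) stop_mg("duplicated taxon identifiers")
  if (nrow(v) > 0 && ncol(v) > 0 && any(rowSums(v) > 1 + 1e-9)) {
    stop_mg("per-sample abundance sums exceed 1 (max %.6g)", max(rowSums(v)))
  }
  x
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("taxon_table: %d samples x %d taxa\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Presence/absence matrix
#'
#' @param values matrix over `{0, 1}`, rows = samples, columns = taxa.
#' @inheritParams taxon_table
#' @return An object of class `presence_absence`.
#' @export
presence_absence <- function(values, sample_ids = rownames(values),
                             taxon_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%d", seq_len(nrow(values)))
  if (is.null(taxon_ids)) taxon_ids <- sprintf("taxon%d", seq_len(ncol(values)))
  dimnames(values) <- list(sample_ids, taxon_ids)
  if (anyNA(values) || !all(values %in% c(0L, 1L))) {
    stop_mg("presence_absence values must all be 0 or 1")
  }
  if (anyDuplicated(sample_ids)) stop_mg("duplicated sample identifiers")
  if (anyDuplicated(taxon_ids)) stop_mg("duplicated taxon identifiers")
  structure(list(values = values, sample_ids = sample_ids,
                 taxon_ids = taxon_ids),
            class = "presence_absence")
}

#' Threshold a taxon table into presence/absence
#'
#' A taxon is present in a sample when its relative abundance exceeds
#' `threshold` (strict, so the default 0 means "any nonzero abundance",
#' matching the usual conversion of abundance tables before co-occurrence
#' analysis).
#'
#' @param x a [taxon_table()].
#' @param threshold strict lower bound on abundance for presence.
#' @return A [presence_absence()] matrix of the same dimensions.
#' @export
pa_from_taxon_table <- function(x, threshold = 0) {
  stopifnot(inherits(x, "taxon_table"))
  presence_absence((x$values > threshold) * 1L,
                   sample_ids = x$sample_ids, taxon_ids = x$taxon_ids)
}

#' KEGG ortholog (KO) profile of one unit
#'
#' A named vector of KO abundances for one unit — a metagenome sample, a
#' genome, or one species' transcriptome. `mode` records the abundance
#' semantics: `"set"` (0/1 presence), `"counts"` (reads), or `"cpm"`
#' (counts per million).
#'
#' @param unit_id identifier of the unit.
#' @param kos named numeric vector, names `K#####`, values >= 0. For
#'   `mode = "set"` a bare character vector of KO ids is also accepted.
#' @param mode one of `"set"`, `"counts"`, `"cpm"`.
#' @return An object of class `ko_profile`.
#' @export
ko_profile <- function(unit_id, kos, mode = c("set", "counts", "cpm")) {
  mode <- match.arg(mode)
  if (is.character(kos) && is.null(names(kos))) {
    kos <- stats::setNames(rep(1, length(kos)), kos)
  }
  kos <- kos[order(names(kos))]
  bad <- names(kos)[!is_ko_token(names(kos))]
  if (length(bad)) {
    stop_mg("malformed KO identifiers (expect K + 5 digits): %s",
            paste(head(bad, 5), collapse = ", "))
  }
  if (anyDuplicated(names(kos))) stop_mg("duplicated KO identifiers in profile '%s'", unit_id)
  if (anyNA(kos) || any(kos < 0)) stop_mg("KO abundances must be nonnegative")
  if (mode == "set" && !all(kos %in% c(0, 1))) {
    stop_mg("set-mode profile must have abundances in {0, 1}")
  }
  structure(list(unit_id = as.character(unit_id), kos = kos, mode = mode),
            class = "ko_profile")
}

#' @export
print.ko_profile <- function(x, ...) {
  cat(sprintf("ko_profile '%s' (%s): %d KOs\n",
              x$unit_id, x$mode, length(x$kos)))
  invisible(x)
}

#' KO identifiers present in a profile
#'
#' @param x a `ko_profile`.
#' @return Character vector of KO ids with abundance > 0.
#' @export
ko_ids <- function(x) {
  stopifnot(inherits(x, "ko_profile"))
  names(x$kos)[x$kos > 0]
}

#' 16S rRNA gene copy-number table
#'
#' @param copies named integer vector, species id -> 16S rRNA gene copy
#'   number (from the strain genomes). Copy numbers are integers >= 1.
#' @return Object of class `copy_number_table` (a named integer vector).
#' @export
copy_number_table <- function(copies) {
  if (is.null(names(copies)) || anyDuplicated(names(copies))) {
    stop_mg("copy numbers need unique species names")
  }
  if (anyNA(copies) || any(copies < 1) || any(copies != round(copies))) {
    stop_mg("16S copy numbers must be integers >= 1")
  }
  structure(stats::setNames(as.integer(copies), names(copies)),
            class = "copy_number_table")
}

#' qPCR total 16S rRNA gene copies per sample
#'
#' Replicate measurements, when given, are aggregated by arithmetic mean.
#'
#' @param totals named numeric vector sample id -> total copies, or a list
#'   of replicate vectors per sample (aggregated by mean).
#' @return Object of class `qpcr_totals`: named numeric vector with a
#'   `replicates` attribute when replicates were supplied.
#' @export
qpcr_totals <- function(totals) {
  reps <- NULL
  if (is.list(totals)) {
    reps <- totals
    totals <- vapply(totals, function(v) mean(as.numeric(v)), numeric(1))
  }
  if (is.null(names(totals)) || anyDuplicated(names(totals))) {
    stop_mg("qPCR totals need unique sample names")
  }
  if (anyNA(totals) || any(totals <= 0)) stop_mg("qPCR totals must be > 0")
  out <- as.numeric(totals)
  names(out) <- names(totals)
  structure(out, class = "qpcr_totals", replicates = reps)
}

#' Reaction universe: the KO -> reaction -> compound mapping
#'
#' An explicit table of the reaction knowledge used to build per-organism
#' metabolic networks: each record links a reaction to the KOs encoding it,
#' its substrate and product compounds, and whether it is reversible.
#'
#' @param reactions data.frame with columns `reaction_id` (character),
#'   `kos`, `substrates`, `products` (list columns of character vectors),
#'   `reversible` (logical).
#' @return Object of class `reaction_universe`.
#' @export
reaction_universe <- function(reactions) {
  need <- c("reaction_id", "kos", "substrates", "products", "reversible")
  if (!all(need %in% names(reactions))) {
    stop_mg("reaction universe needs columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(reactions$reaction_id)) stop_mg("duplicated reaction ids")
  for (i in seq_len(nrow(reactions))) {
    s <- reactions$substrates[[i]]; p <- reactions$products[[i]]
    k <- reactions$kos[[i]]
    if (length(k) < 1 || length(s) < 1 || length(p) < 1) {
      stop_mg("reaction '%s' needs >=1 KO, substrate and product",
              reactions$reaction_id[i])
    }
    if (length(intersect(s, p))) {
      stop_mg("reaction '%s' lists a compound as both substrate and product",
              reactions$reaction_id[i])
    }
    if (!all(is_ko_token(k))) {
      stop_mg("reaction '%s' has malformed KO identifiers", reactions$reaction_id[i])
    }
  }
  reactions$reversible <- as.logical(reactions$reversible)
  structure(reactions, class = c("reaction_universe", "data.frame"))
}

#' @export
print.reaction_universe <- function(x, ...) {
  cat(sprintf("reaction_universe: %d reactions, %d compounds, %d KOs\n",
              nrow(x),
              length(unique(unlist(c(x$substrates, x$products)))),
              length(unique(unlist(x$kos)))))
  invisible(x)
}

#' Species-level amplicon read-count table
#'
#' @param counts nonnegative numeric matrix, rows = species, columns =
#'   samples. Fractional values are allowed (expected-count limits,
#'   copy-number-corrected counts).
#' @param species_ids,sample_ids identifiers; default to `dimnames(counts)`.
#' @return Object of class `species_count_table`.
#' @export
species_count_table <- function(counts, species_ids = rownames(counts),
                                sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(species_ids)) species_ids <- sprintf("sp%d", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%d", seq_len(ncol(counts)))
  dimnames(counts) <- list(species_ids, sample_ids)
  if (anyNA(counts) || any(counts < 0)) stop_mg("counts must be nonnegative")
  if (anyDuplicated(species_ids) || anyDuplicated(sample_ids)) {
    stop_mg("duplicated species or sample identifiers")
  }
  structure(list(counts = counts, species_ids = species_ids,
                 sample_ids = sample_ids),
            class = "species_count_table")
}
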