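# Quantitative microbiota profiling: ASV -> species aggregation, 16S rRNA
# gene copy-number correction, and scaling to qPCR-measured total copies.
# Order of operations follows the bench method: divide raw species counts
# by copy number first, then renormalise and scale to the qPCR total.
# Corrected counts stay fractional throughout (rounding would bias the
# renormalisation).

#' Aggregate ASV counts to species level
#'
#' ASVs mapping to the same species are summed; ASVs absent from the map
#' are treated as unclassified and dropped, with their per-sample read
#' fraction reported. Samples in which every read is unclassified are
#' flagged (they cannot be scaled downstream).
#'
#' @param asv_counts numeric matrix, rows = ASV ids, columns = samples.
#' @param asv_map named character vector ASV id -> species id; ASVs not in
#'   the map (or mapping to `NA`/`""`) are unclassified.
#' @return [species_count_table()] with attributes `unclassified_fraction`
#'   (per sample) and `flagged_samples` (zero classified reads).
#' @export
aggregate_species <- function(asv_counts, asv_map) {
  asv_counts <- as.matrix(asv_counts)
  if (is.null(rownames(asv_counts))) stop_mg("ASV counts need row names")
  if (anyNA(asv_counts) || any(asv_counts < 0)) stop_mg("counts must be nonnegative")
  sp <- asv_map[rownames(asv_counts)]
  classified <- !is.na(sp) & nzchar(sp)
  totals <- colSums(asv_counts)
  cls_counts <- asv_counts[classified, , drop = FALSE]
  uncls_frac <- ifelse(totals > 0, 1 - colSums(cls_counts) / totals, 0)
  agg <- rowsum(cls_counts, group = sp[classified])
  out <- species_count_table(agg)
  attr(out, "unclassified_fraction") <- stats::setNames(uncls_frac,
                                                        colnames(asv_counts))
  flagged <- colnames(asv_counts)[colSums(cls_counts) == 0]
  attr(out, "flagged_samples") <- flagged
  out
}

#' Correct species counts for 16S rRNA gene copy number
#'
#' Divides each species' raw counts by its genome's 16S rRNA gene copy
#' number, removing the over-representation of high-copy species in
#' amplicon reads. Results are fractional by design.
#'
#' @param counts a [species_count_table()].
#' @param cn a [copy_number_table()] covering every species in `counts`.
#' @return [species_count_table()] of corrected (fractional) counts.
#' @export
copy_number_correct <- function(counts, cn) {
  stopifnot(inherits(counts, "species_count_table"),
            inherits(cn, "copy_number_table"))
  missing <- setdiff(counts$species_ids, names(cn))
  if (length(missing)) {
    stop_mg("species without 16S copy number: %s",
            paste(missing, collapse = ", "))
  }
  divisor <- as.numeric(unclass(cn)[counts$species_ids])
  species_count_table(counts$counts / divisor)
}

#' Scale corrected counts to qPCR total 16S copies
#'
#' Each sample's corrected counts are renormalised to proportions and
#' multiplied by that sample's qPCR-measured total 16S rRNA gene copies,
#' correcting for sequencing depth and yielding absolute abundances.
#' Samples whose corrected counts sum to zero cannot be scaled and are
#' excluded with a flag.
#'
#' @param corrected a [species_count_table()] of copy-number-corrected
#'   counts.
#' @param totals a [qpcr_totals()] covering every retained sample.
#' @return Object of class `absolute_abundance_table`: list with `values`
#'   (species x samples, 16S copies), `species_ids`, `sample_ids`,
#'   `totals`, and `flagged_samples` (excluded, zero corrected sum).
#' @export
scale_to_qpcr <- function(corrected, totals) {
  stopifnot(inherits(corrected, "species_count_table"),
            inherits(totals, "qpcr_totals"))
  csum <- colSums(corrected$counts)
  flagged <- corrected$sample_ids[csum == 0]
  keep <- corrected$sample_ids[csum > 0]
  missing <- setdiff(keep, names(totals))
  if (length(missing)) {
    stop_mg("samples without qPCR total: %s", paste(missing, collapse = ", "))
  }
  m <- corrected$counts[, keep, drop = FALSE]
  tot <- as.numeric(unclass(totals)[keep])
  vals <- sweep(m, 2, colSums(m), "/")
  vals <- sweep(vals, 2, tot, "*")
  structure(list(values = vals,
                 species_ids = corrected$species_ids,
                 sample_ids = keep,
                 totals = stats::setNames(tot, keep),
                 flagged_samples = flagged),
            class = "absolute_abundance_table")
}

#' @export
print.absolute_abundance_table <- function(x, ...) {
  cat(sprintf("absolute_abundance_table: %d species x %d samples (16S copies)\n",
              nrow(x$values), ncol(x$values)))
  if (length(x$flagged_samples)) {
    cat("  flagged (excluded):", paste(x$flagged_samples, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Quantitative profiling pipeline
#'
#' Convenience wrapper chaining [copy_number_correct()] and
#' [scale_to_qpcr()] (optionally preceded by [aggregate_species()]).
#'
#' @param counts [species_count_table()], or an ASV matrix when `asv_map`
#'   is given.
#' @param cn [copy_number_table()].
#' @param totals [qpcr_totals()].
#' @param asv_map optional ASV -> species map.
#' @return [scale_to_qpcr()] result.
#' @export
quantify_absolute <- function(counts, cn, totals, asv_map = NULL) {
  if (!is.null(asv_map)) counts <- aggregate_species(counts, asv_map)
  scale_to_qpcr(copy_number_correct(counts, cn), totals)
}

#' Per-species fold change between two samples
#'
#' @param abund an `absolute_abundance_table`.
#' @param t,t0 sample ids (numerator and baseline).
#' @return data.frame with `species_id`, `ratio`, `defined` (`FALSE` where
#'   the baseline is zero; `ratio` is `NA` there, not infinite).
#' @export
fold_change <- function(abund, t, t0) {
  stopifnot(inherits(abund, "absolute_abundance_table"))
  for (s in c(t, t0)) {
    if (!s %in% abund$sample_ids) stop_mg("sample '%s' not in table", s)
  }
  num <- abund$values[, t]
  den <- abund$values[, t0]
  ratio <- ifelse(den > 0, num / den, NA_real_)
  data.frame(species_id = abund$species_ids, ratio = unname(ratio),
             defined = unname(den > 0), stringsAsFactors = FALSE,
             row.names = NULL)
}
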