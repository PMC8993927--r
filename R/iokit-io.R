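# Readers and writers for the package's plain-text formats. Everything is
# TSV with a header row; tables default to the common microbiome convention
# of taxa as rows and samples as columns. Missing cells are errors, never
# zeros, and identifiers are case-sensitive with whitespace trimmed only at
# field edges.

read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stop_mg("file not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character",
                   strip.white = TRUE)
  if (ncol(df) < 2) stop_mg("%s: expected an id column plus data columns", path)
  ids <- trimws(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(apply(m, c(1, 2), function(cell) as.numeric(trimws(cell))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop_mg("%s: malformed or missing numeric cell at row '%s', column '%s'",
            path, ids[bad[1]], colnames(m)[bad[2]])
  }
  rownames(num) <- ids
  num
}

write_tsv_matrix <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a taxon relative-abundance table
#'
#' TSV with a header row. By default taxa are rows and samples are columns
#' (`taxa_as_rows = TRUE`); set the flag to `FALSE` for transposed files.
#' Negative values, missing cells and duplicated identifiers are rejected.
#'
#' @param path file path.
#' @param taxa_as_rows orientation of the file on disk.
#' @return [taxon_table()] (in memory always samples x taxa).
#' @export
read_taxon_table <- function(path, taxa_as_rows = TRUE) {
  m <- read_tsv_matrix(path)
  if (taxa_as_rows) m <- t(m)
  taxon_table(m)
}

#' @rdname read_taxon_table
#' @param x a `taxon_table`.
#' @export
write_taxon_table <- function(x, path, taxa_as_rows = TRUE) {
  stopifnot(inherits(x, "taxon_table"))
  m <- if (taxa_as_rows) t(x$values) else x$values
  write_tsv_matrix(m, path, if (taxa_as_rows) "taxon_id" else "sample_id")
}

#' Read locus-tag to KO annotations into a set-mode KO profile
#'
#' Parses two-column annotation exports (locus_tag TAB KO), the format
#' produced by KEGG annotation servers for a genome or transcriptome. Loci
#' with an empty KO field (unannotated) are dropped; the number dropped is
#' recorded in the `n_unannotated` attribute. Duplicate KO assignments
#' collapse to a unique set.
#'
#' @param path two-column TSV, no header: locus_tag, KO (may be blank).
#' @param unit_id identifier for the resulting profile; defaults to the
#'   file name without extension.
#' @return Set-mode [ko_profile()] with attribute `n_unannotated`.
#' @export
read_ko_annotations <- function(path, unit_id = NULL) {
  if (!file.exists(path)) stop_mg("file not found: %s", path)
  unit_id <- unit_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  kos <- character(0)
  n_drop <- 0L
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    ko <- if (length(fields) >= 2) fields[2] else ""
    if (!nzchar(ko)) {
      n_drop <- n_drop + 1L
      next
    }
    if (!is_ko_token(ko)) {
      stop_mg("%s line %d: '%s' is not a KO identifier (K#####)", path, i, ko)
    }
    kos <- c(kos, ko)
  }
  prof <- ko_profile(unit_id, unique(kos), mode = "set")
  attr(prof, "n_unannotated") <- n_drop
  prof
}

#' Read a KO count table into per-unit count-mode profiles
#'
#' TSV with KO ids as rows and units (species, samples, or
#' species-by-timepoint) as columns.
#'
#' @param path file path.
#' @return Named list of count-mode [ko_profile()] objects, one per column.
#' @export
read_ko_counts <- function(path) {
  m <- read_tsv_matrix(path)
  if (!all(is_ko_token(rownames(m)))) {
    bad <- rownames(m)[!is_ko_token(rownames(m))][1]
    stop_mg("%s: row id '%s' is not a KO identifier", path, bad)
  }
  out <- lapply(colnames(m), function(u) ko_profile(u, m[, u], mode = "counts"))
  stats::setNames(out, colnames(m))
}

#' Read / write 16S rRNA gene copy numbers
#'
#' Two-column TSV with header: `species_id`, `copy_number`.
#'
#' @param path file path.
#' @return [copy_number_table()].
#' @export
read_copy_numbers <- function(path) {
  m <- read_tsv_matrix(path)
  copy_number_table(stats::setNames(m[, 1], rownames(m)))
}

#' @rdname read_copy_numbers
#' @param x a `copy_number_table`.
#' @export
write_copy_numbers <- function(x, path) {
  m <- matrix(as.integer(x), ncol = 1,
              dimnames = list(names(x), "copy_number"))
  write_tsv_matrix(m, path, "species_id")
}

#' Read / write qPCR totals
#'
#' TSV with header: `sample_id` then one or more numeric replicate columns.
#' Multiple replicate columns are aggregated by arithmetic mean.
#'
#' @param path file path.
#' @return [qpcr_totals()].
#' @export
read_qpcr_totals <- function(path) {
  m <- read_tsv_matrix(path)
  if (ncol(m) == 1) {
    qpcr_totals(stats::setNames(m[, 1], rownames(m)))
  } else {
    reps <- stats::setNames(lapply(seq_len(nrow(m)), function(i) m[i, ]),
                            rownames(m))
    qpcr_totals(reps)
  }
}

#' @rdname read_qpcr_totals
#' @param x a `qpcr_totals`.
#' @export
write_qpcr_totals <- function(x, path) {
  m <- matrix(as.numeric(x), ncol = 1, dimnames = list(names(x), "total_copies"))
  write_tsv_matrix(m, path, "sample_id")
}

#' Read / write a reaction universe
#'
#' TSV with header columns `reaction_id`, `kos`, `substrates`, `products`
#' (semicolon-joined lists) and `reversible` (0/1).
#'
#' @param path file path.
#' @return [reaction_universe()].
#' @export
read_reaction_universe <- function(path) {
  if (!file.exists(path)) stop_mg("file not found: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", strip.white = TRUE)
  need <- c("reaction_id", "kos", "substrates", "products", "reversible")
  if (!all(need %in% names(df))) {
    stop_mg("%s: expected columns %s", path, paste(need, collapse = ", "))
  }
  split_semi <- function(v) lapply(strsplit(v, ";", fixed = TRUE), trimws)
  reaction_universe(data.frame(
    reaction_id = trimws(df$reaction_id),
    kos = I(split_semi(df$kos)),
    substrates = I(split_semi(df$substrates)),
    products = I(split_semi(df$products)),
    reversible = as.integer(df$reversible) == 1L,
    stringsAsFactors = FALSE
  ))
}

#' @rdname read_reaction_universe
#' @param x a `reaction_universe`.
#' @export
write_reaction_universe <- function(x, path) {
  join <- function(col) vapply(col, paste, character(1), collapse = ";")
  df <- data.frame(reaction_id = x$reaction_id,
                   kos = join(x$kos),
                   substrates = join(x$substrates),
                   products = join(x$products),
                   reversible = as.integer(x$reversible),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a species count table
#'
#' TSV, species as rows and samples as columns.
#' @param path file path.
#' @export
read_species_counts <- function(path) species_count_table(read_tsv_matrix(path))

#' @rdname read_species_counts
#' @param x a `species_count_table`.
#' @export
write_species_counts <- function(x, path) {
  write_tsv_matrix(x$counts, path, "species_id")
}

#' Write run parameters as a YAML-style config log
#'
#' Flat `key: value` lines so every analysis records the thresholds and
#' options it was run with.
#'
#' @param params named list of scalar parameters.
#' @param path output path.
#' @export
write_run_log <- function(params, path) {
  stopifnot(!is.null(names(params)), all(nzchar(names(params))))
  lines <- vapply(names(params), function(k) {
    v <- params[[k]]
    sprintf("%s: %s", k, paste(format(v, trim = TRUE), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
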