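# Gut metabolic module (GMM) machinery: module-definition grammar, CPM
# normalisation, and per-unit module scoring.
#
# Module file dialect (the established GMM convention):
#   MF0001<TAB>module name
#   K00001              one step
#   K00002,K00003       comma = alternative KOs for a step
#   K00004+K00005       '+' = jointly required KOs (enzyme complex)
#   ///                 end of module
# Lines starting with '#' are comments. Scoring semantics: an alternative's
# abundance is the minimum over its jointly required KOs (limiting
# subunit); a step's abundance is the sum over its alternatives.

#' Construct a GMM definition
#'
#' @param module_id identifier (e.g. `MF0001`).
#' @param name human-readable module name.
#' @param steps list of steps; each step a list of alternatives; each
#'   alternative a character vector of jointly required KO ids.
#' @return Object of class `gmm_definition`.
#' @export
gmm_definition <- function(module_id, name, steps) {
  if (!length(steps)) stop_mg("module '%s' has no steps", module_id)
  for (s in steps) {
    if (!length(s)) stop_mg("module '%s' has an empty step", module_id)
    for (alt in s) {
      if (!length(alt) || !all(is_ko_token(alt))) {
        stop_mg("module '%s' has a malformed alternative", module_id)
      }
    }
  }
  structure(list(module_id = as.character(module_id),
                 name = as.character(name), steps = steps),
            class = "gmm_definition")
}

#' @export
print.gmm_definition <- function(x, ...) {
  cat(sprintf("gmm_definition %s (%s): %d steps\n",
              x$module_id, x$name, length(x$steps)))
  invisible(x)
}

parse_gmm_step <- function(line, path, lineno) {
  alts <- strsplit(trimws(line), ",", fixed = TRUE)[[1]]
  alts <- trimws(alts[nzchar(trimws(alts))])
  parsed <- lapply(alts, function(a) trimws(strsplit(a, "+", fixed = TRUE)[[1]]))
  ok <- length(parsed) > 0 &&
    all(vapply(parsed, function(k) length(k) > 0 && all(is_ko_token(k)),
               logical(1)))
  if (!ok) {
    stop_mg("%s line %d: step '%s' has no valid KO token", path, lineno, line)
  }
  parsed
}

#' Read / write GMM definition files
#'
#' @param path module-definition file in the dialect described above.
#' @return List of [gmm_definition()] objects, named by module id.
#' @export
read_gmm_definitions <- function(path) {
  if (!file.exists(path)) stop_mg("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  mods <- list()
  cur_id <- NULL; cur_name <- NULL; cur_steps <- list()
  flush <- function() {
    if (is.null(cur_id)) return()
    if (cur_id %in% names(mods)) stop_mg("%s: duplicate module id '%s'", path, cur_id)
    mods[[cur_id]] <<- gmm_definition(cur_id, cur_name, cur_steps)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln)) || startsWith(trimws(ln), "#")) next
    if (trimws(ln) == "///") {
      flush(); cur_id <- NULL; cur_name <- NULL; cur_steps <- list()
    } else if (grepl("\t", ln) && grepl("^M", trimws(ln))) {
      flush()
      fields <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1]])
      cur_id <- fields[1]
      cur_name <- if (length(fields) > 1) fields[2] else fields[1]
      cur_steps <- list()
    } else {
      if (is.null(cur_id)) stop_mg("%s line %d: step before any module header", path, i)
      cur_steps <- c(cur_steps, list(parse_gmm_step(ln, path, i)))
    }
  }
  flush()
  mods
}

#' @rdname read_gmm_definitions
#' @param modules list of [gmm_definition()]s.
#' @export
write_gmm_definitions <- function(modules, path) {
  out <- character(0)
  for (m in modules) {
    out <- c(out, paste(m$module_id, m$name, sep = "\t"))
    for (s in m$steps) {
      out <- c(out, paste(vapply(s, paste, character(1), collapse = "+"),
                          collapse = ","))
    }
    out <- c(out, "///")
  }
  writeLines(out, path)
  invisible(path)
}

#' Counts-per-million normalisation of a KO profile
#'
#' `cpm(k) = count(k) / library_size * 1e6` — removes library-size
#' differences before module scoring.
#'
#' @param counts a count-mode [ko_profile()] with positive library size.
#' @return CPM-mode [ko_profile()].
#' @export
cpm_normalize <- function(counts) {
  stopifnot(inherits(counts, "ko_profile"))
  if (counts$mode != "counts") stop_mg("cpm_normalize expects a counts-mode profile")
  lib <- sum(counts$kos)
  if (lib <= 0) stop_mg("zero library size for unit '%s'", counts$unit_id)
  ko_profile(counts$unit_id, counts$kos / lib * 1e6, mode = "cpm")
}

#' Abundance of one module step in a KO profile
#'
#' Alternative abundance = min over its jointly required KOs (a missing KO
#' counts as 0); step abundance = sum over alternatives.
#'
#' @param step one step of a [gmm_definition()] (list of alternatives).
#' @param kos a cpm- (or counts-) mode [ko_profile()].
#' @return Nonnegative abundance.
#' @export
step_abundance <- function(step, kos) {
  stopifnot(inherits(kos, "ko_profile"))
  v <- kos$kos
  sum(vapply(step, function(alt) {
    present <- v[alt]
    present[is.na(present)] <- 0
    min(present)
  }, numeric(1)))
}

#' Score one module in one unit's KO profile
#'
#' Coverage is the fraction of steps with nonzero abundance. The score is
#' the `estimator` (default median; even step counts average the middle
#' two) of the abundances of covered steps, 0 when no step is covered. A
#' module is `reported` when coverage reaches `coverage_cutoff`
#' (inclusive) and at least `min_kos` distinct KOs of the module are
#' observed in the profile. KO abundance is never split across modules: a
#' KO contributes fully to every module containing it.
#'
#' @param module a [gmm_definition()].
#' @param kos a cpm-mode [ko_profile()].
#' @param estimator `"median"` or `"mean"` over covered steps.
#' @param coverage_cutoff inclusive coverage threshold for reporting.
#' @param min_kos minimum distinct observed module KOs for reporting.
#' @return Object of class `module_score`: list with `module_id`,
#'   `unit_id`, `score`, `coverage`, `n_observed_kos`, `reported`.
#' @export
score_module <- function(module, kos, estimator = c("median", "mean"),
                         coverage_cutoff = 0.5, min_kos = 2) {
  stopifnot(inherits(module, "gmm_definition"), inherits(kos, "ko_profile"))
  estimator <- match.arg(estimator)
  ab <- vapply(module$steps, step_abundance, numeric(1), kos = kos)
  covered <- ab > 0
  coverage <- mean(covered)
  score <- if (any(covered)) {
    if (estimator == "median") median(ab[covered]) else mean(ab[covered])
  } else 0
  module_kos <- unique(unlist(module$steps))
  n_obs <- sum(kos$kos[intersect(module_kos, names(kos$kos))] > 0)
  structure(list(module_id = module$module_id, unit_id = kos$unit_id,
                 score = score, coverage = coverage,
                 n_observed_kos = n_obs,
                 reported = coverage >= coverage_cutoff && n_obs >= min_kos),
            class = "module_score")
}

#' @export
print.module_score <- function(x, ...) {
  cat(sprintf("%s in %s: score %.3g, coverage %.2f%s\n",
              x$module_id, x$unit_id, x$score, x$coverage,
              if (x$reported) "" else " (not reported)"))
  invisible(x)
}

#' Species-function linkage table
#'
#' Scores every module in every unit (species, or species-by-timepoint)
#' and returns one long table, deterministically ordered by (unit, module).
#' Count-mode profiles are CPM-normalised first.
#'
#' @param profiles list of [ko_profile()]s (counts or cpm mode), unique
#'   unit ids.
#' @param modules list of [gmm_definition()]s.
#' @inheritParams score_module
#' @return data.frame with columns `unit_id`, `module_id`, `name`,
#'   `score`, `coverage`, `n_observed_kos`, `reported`.
#' @export
species_function_table <- function(profiles, modules,
                                   estimator = c("median", "mean"),
                                   coverage_cutoff = 0.5, min_kos = 2) {
  estimator <- match.arg(estimator)
  if (!length(profiles) || !length(modules)) {
    stop_mg("need >= 1 unit and >= 1 module")
  }
  ids <- vapply(profiles, function(p) p$unit_id, character(1))
  if (anyDuplicated(ids)) stop_mg("duplicated unit ids: %s",
                                  paste(unique(ids[duplicated(ids)]), collapse = ", "))
  profiles <- lapply(profiles, function(p) {
    if (p$mode == "counts") cpm_normalize(p) else p
  })
  profiles <- profiles[order(ids)]
  mod_ids <- vapply(modules, function(m) m$module_id, character(1))
  modules <- modules[order(mod_ids)]
  rows <- list()
  for (p in profiles) {
    for (m in modules) {
      s <- score_module(m, p, estimator, coverage_cutoff, min_kos)
      rows[[length(rows) + 1]] <- data.frame(
        unit_id = s$unit_id, module_id = s$module_id, name = m$name,
        score = s$score, coverage = s$coverage,
        n_observed_kos = s$n_observed_kos, reported = s$reported,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
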