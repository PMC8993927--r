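fixture_path <- function() {
  system.file("extdata", "gmm_modules_synthetic.txt", package = "minimalgut")
}

test_that("GMM grammar parses steps, alternatives and complexes", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("MF0001\ttwo-step module", "K00001", "K00002,K00003", "///",
               "MF0002\tcomplex module", "K00004+K00005", "///"), path)
  mods <- read_gmm_definitions(path)
  expect_length(mods, 2)
  expect_length(mods$MF0001$steps, 2)
  expect_length(mods$MF0001$steps[[2]], 2)           # two alternatives
  expect_identical(mods$MF0002$steps[[1]][[1]], c("K00004", "K00005"))

  writeLines(c("MF0001\tx", "notako", "///"), path)
  expect_error(read_gmm_definitions(path), "no valid KO token")
  writeLines(c("MF0001\tx", "K00001", "///", "MF0001\ty", "K00002", "///"),
             path)
  expect_error(read_gmm_definitions(path), "duplicate module id")
})

test_that("parse -> serialize -> parse is structurally identical", {
  mods <- read_gmm_definitions(fixture_path())
  expect_gte(length(mods), 6)
  path <- withr::local_tempfile(fileext = ".txt")
  write_gmm_definitions(mods, path)
  back <- read_gmm_definitions(path)
  expect_identical(lapply(back, `[[`, "steps"), lapply(mods, `[[`, "steps"))
  expect_identical(names(back), names(mods))

  # random modules round-trip too
  set.seed(13)
  rand <- lapply(1:5, function(i) {
    steps <- lapply(seq_len(sample(1:4, 1)), function(s) {
      lapply(seq_len(sample(1:3, 1)), function(a) {
        sprintf("K%05d", sample.int(99999, sample(1:3, 1)))
      })
    })
    gmm_definition(sprintf("MR%04d", i), paste("random", i), steps)
  })
  write_gmm_definitions(rand, path)
  back <- read_gmm_definitions(path)
  expect_identical(unname(lapply(back, `[[`, "steps")),
                   lapply(rand, `[[`, "steps"))
})

test_that("cpm normalisation conserves a million", {
  p <- cpm_normalize(ko_profile("u", c(K00001 = 1, K00002 = 3),
                                mode = "counts"))
  expect_equal(unname(p$kos), c(250000, 750000))
  expect_identical(p$mode, "cpm")
  single <- cpm_normalize(ko_profile("u", c(K00001 = 17), mode = "counts"))
  expect_equal(unname(single$kos), 1e6)
  expect_error(cpm_normalize(ko_profile("u", c(K00001 = 0), mode = "counts")),
               "zero library")
  for (s in 1:5) {
    p <- cpm_normalize(random_ko_profile("r", 25, seed = 60 + s))
    expect_equal(sum(p$kos), 1e6, tolerance = 1e-6)
  }
})

test_that("step abundance: alternatives sum, complexes take the minimum", {
  cpm <- ko_profile("u", c(K00001 = 10, K00002 = 5), mode = "cpm")
  expect_equal(step_abundance(list("K00001", "K00002"), cpm), 15)
  expect_equal(step_abundance(list(c("K00001", "K00002")), cpm), 5)
  expect_equal(step_abundance(list("K00099"), cpm), 0)   # missing KO = 0

  set.seed(21)
  for (rep in 1:10) {
    prof <- random_ko_profile("r", 15, seed = 300 + rep, mode = "cpm")
    step <- lapply(seq_len(sample(1:3, 1)), function(a) {
      sample(c(names(prof$kos), "K99998", "K99997"), sample(1:3, 1))
    })
    expect_equal(step_abundance(step, prof),
                 oracle_step_abundance(step, as.list(prof$kos)))
  }
})

test_that("module scoring follows median/coverage/min-KO reporting rules", {
  mod <- gmm_definition("M1", "m", list(
    list("K00001", "K00002"),  # step 1: abundance 15
    list("K00010")))           # step 2: absent
  cpm <- ko_profile("u", c(K00001 = 10, K00002 = 5), mode = "cpm")
  s <- score_module(mod, cpm)
  expect_equal(s$coverage, 0.5)
  expect_equal(s$score, 15)
  expect_true(s$reported)      # cutoff inclusive at 0.5, 2 KOs observed

  # all steps zero: never reported, score 0
  none <- score_module(mod, ko_profile("u", c(K09999 = 3), mode = "cpm"))
  expect_equal(none$score, 0)
  expect_equal(none$coverage, 0)
  expect_false(none$reported)

  # median over covered steps; even counts average the middle two
  mod3 <- gmm_definition("M3", "m3",
                         list(list("K00001"), list("K00002"), list("K00003")))
  cpm3 <- ko_profile("u", c(K00001 = 2, K00002 = 8, K00003 = 4), mode = "cpm")
  expect_equal(score_module(mod3, cpm3)$score, 4)
  mod4 <- gmm_definition("M4", "m4",
                         list(list("K00001"), list("K00002"),
                              list("K00003"), list("K00004")))
  cpm4 <- ko_profile("u", c(K00001 = 2, K00002 = 8, K00003 = 4, K00004 = 6),
                     mode = "cpm")
  expect_equal(score_module(mod4, cpm4)$score, 5)

  # min_kos gate: one observed KO is not enough
  one <- score_module(gmm_definition("M5", "m5", list(list("K00001"))),
                      ko_profile("u", c(K00001 = 9), mode = "cpm"))
  expect_equal(one$coverage, 1)
  expect_false(one$reported)
})

test_that("scoring is monotone in KO abundance and bounded by step range", {
  set.seed(37)
  mods <- read_gmm_definitions(fixture_path())
  for (rep in 1:20) {
    prof <- random_ko_profile("r", 10, seed = 400 + rep, mode = "cpm")
    # overwrite names so some module KOs are hit
    hit <- sample(unique(unlist(lapply(mods, function(m) unlist(m$steps)))), 6)
    kos <- stats::setNames(prof$kos[1:6], hit)
    prof <- ko_profile("r", kos, mode = "cpm")
    m <- mods[[sample(length(mods), 1)]]
    s0 <- score_module(m, prof)
    ab <- vapply(m$steps, step_abundance, numeric(1), kos = prof)
    if (any(ab > 0)) {
      expect_gte(s0$score, min(ab[ab > 0]) - 1e-12)
      expect_lte(s0$score, max(ab) + 1e-12)
    }
    # increase one KO: score and coverage never decrease
    k <- sample(names(prof$kos), 1)
    kos2 <- prof$kos; kos2[k] <- kos2[k] + runif(1, 1, 50)
    s1 <- score_module(m, ko_profile("r", kos2, mode = "cpm"))
    expect_gte(s1$score, s0$score - 1e-12)
    expect_gte(s1$coverage, s0$coverage)
  }
})

test_that("species-function table is deterministic and order-invariant", {
  mods <- read_gmm_definitions(fixture_path())
  set.seed(8)
  profs <- lapply(c("spB", "spA"), function(u) {
    kos <- sample(unique(unlist(lapply(mods, function(m) unlist(m$steps)))), 8)
    ko_profile(u, stats::setNames(rpois(8, 30) + 1, kos), mode = "counts")
  })
  tab <- species_function_table(profs, mods)
  expect_equal(nrow(tab), 2 * length(mods))
  expect_identical(tab$unit_id, rep(c("spA", "spB"), each = length(mods)))
  tab_perm <- species_function_table(rev(profs), mods)
  expect_identical(tab, tab_perm)
  expect_error(species_function_table(list(profs[[1]], profs[[1]]), mods),
               "duplicated unit ids")

  # single unit, single module row agrees with score_module
  one <- species_function_table(profs[1], mods[1])
  s <- score_module(mods[[1]], cpm_normalize(profs[[1]]))
  expect_equal(one$score, s$score)
  expect_equal(one$coverage, s$coverage)
  expect_identical(one$reported, s$reported)
})

test_that("planted active modules are the ones reported", {
  mods <- read_gmm_definitions(fixture_path())
  active <- mods$MGM0002     # express every KO of this module
  inactive <- mods$MGM0005
  kos_active <- unique(unlist(active$steps))
  profs <- list(
    ko_profile("on", stats::setNames(rep(50, length(kos_active)), kos_active),
               mode = "counts"),
    ko_profile("off", c(K99999 = 50), mode = "counts"))
  tab <- species_function_table(profs, list(active, inactive))
  expect_true(tab$reported[tab$unit_id == "on" & tab$module_id == "MGM0002"])
  expect_false(tab$reported[tab$unit_id == "on" & tab$module_id == "MGM0005"])
  expect_false(any(tab$reported[tab$unit_id == "off"]))
})
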