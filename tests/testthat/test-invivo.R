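make_pirna_reps <- function(prefixes, ctrl_ppm, mut_ppm, unique_mapping = TRUE) {
  tidyr::crossing(prefix25 = prefixes,
                  genotype = c("control", "mutant")) |>
    dplyr::rowwise() |>
    dplyr::reframe(prefix25 = prefix25, genotype = genotype,
                   replicate = seq_len(ifelse(genotype == "control", 12, 9)),
                   ppm = if (genotype == "control") {
                     rep(ctrl_ppm[[prefix25]], 12)
                   } else rep(mut_ppm[[prefix25]], 9)) |>
    dplyr::mutate(unique_mapping = unique_mapping)
}

test_that("prefix-group retention thresholds are inclusive", {
  reps <- make_pirna_reps(c("p1", "p2", "p3"),
                          ctrl_ppm = list(p1 = 1.0, p2 = 5, p3 = 5),
                          mut_ppm = list(p1 = 5, p2 = 0.1, p3 = 0.11))
  # p1 sits exactly at 1 ppm in every control replicate: retained
  out <- group_pirnas(reps)
  expect_true(out$retained[out$prefix25 == "p1"])
  # mutant mean exactly 0.1 ppm counts as undetectable -> targeted
  expect_equal(out$set[out$prefix25 == "p2"], "targeted")
  expect_equal(out$set[out$prefix25 == "p3"], "control")
})

test_that("a single sub-threshold control replicate drops the group", {
  reps <- make_pirna_reps("p1", list(p1 = 5), list(p1 = 5))
  reps$ppm[reps$genotype == "control" & reps$replicate == 7] <- 0.5
  out <- group_pirnas(reps)
  expect_false(out$retained)
  # ambiguously mapping groups are dropped no matter how abundant
  reps2 <- make_pirna_reps("p1", list(p1 = 5), list(p1 = 5),
                           unique_mapping = FALSE)
  expect_false(group_pirnas(reps2)$retained)
  # replicate-count mismatch is a configuration error
  expect_error(group_pirnas(dplyr::filter(reps, replicate < 9)),
               "control replicates")
})

test_that("retention equals a literal application of the three rules", {
  set.seed(23)
  n <- 120
  prefixes <- sprintf("p%03d", seq_len(n))
  ctrl <- lapply(prefixes, function(p) runif(12, 0, 3))
  mut <- lapply(prefixes, function(p) runif(9, 0, 0.3))
  names(ctrl) <- names(mut) <- prefixes
  um <- setNames(runif(n) < 0.8, prefixes)
  reps <- tidyr::crossing(prefix25 = prefixes,
                          genotype = c("control", "mutant")) |>
    dplyr::rowwise() |>
    dplyr::reframe(prefix25 = prefix25, genotype = genotype,
                   replicate = seq_len(ifelse(genotype == "control", 12, 9)),
                   ppm = if (genotype == "control") ctrl[[prefix25]]
                         else mut[[prefix25]]) |>
    dplyr::mutate(unique_mapping = unname(um[prefix25]))
  out <- group_pirnas(reps)
  for (p in prefixes) {
    want_keep <- um[[p]] && all(ctrl[[p]] >= 1)
    expect_equal(out$retained[out$prefix25 == p], unname(want_keep))
    if (want_keep) {
      want_set <- if (mean(mut[[p]]) <= 0.1) "targeted" else "control"
      expect_equal(out$set[out$prefix25 == p], want_set)
    }
  }
})

test_that("absolute quantification is linear and matches the closed form", {
  d <- tibble::tibble(species = c("a", "b"), count = c(100, 50))
  # 10 molecules per cell in a 1 pL cell is about 16.6 pM
  q <- absolute_quantify(tibble::tibble(species = "a", count = 10),
                         spike_counts = 100, spike_molecules = 100,
                         n_cells = 1, cell_volume_pl = 1)
  expect_equal(q$molecules_per_cell, 10)
  expect_equal(q$abundance_pm, 10 / (6.02214076e23 * 1e-12) * 1e12,
               tolerance = 1e-6)
  expect_equal(round(q$abundance_pm, 1), 16.6)
  # doubling all counts with fixed spike-ins doubles the concentration
  q1 <- absolute_quantify(d, 200, 1000)
  q2 <- absolute_quantify(dplyr::mutate(d, count = count * 2), 200, 1000)
  expect_equal(q2$abundance_pm, 2 * q1$abundance_pm)
  expect_error(absolute_quantify(d, 0, 1000), "calibration")
})

test_that("spike-ins self-quantify within counting noise", {
  set.seed(4)
  input_molecules <- c(1e5, 1e6, 1e7)
  rate <- 1e-3                       # reads per molecule
  counts <- rpois(3, input_molecules * rate)
  q <- absolute_quantify(tibble::tibble(count = counts),
                         spike_counts = counts,
                         spike_molecules = input_molecules)
  expect_equal(sum(q$molecules_per_cell), sum(input_molecules))
  expect_lt(max(abs(q$molecules_per_cell / input_molecules - 1)), 0.05)
})

test_that("planted sites are found with the non-overlap rule enforced", {
  set.seed(41)
  guide <- paste(sample(c("A", "C", "G", "U"), 25, replace = TRUE),
                 collapse = "")
  tx <- piwikit:::plant_site_transcript(guide, 2, 20)
  species <- tibble::tibble(species_id = "s1", transcript = "tx1",
                            position = 30L)
  pirnas <- tibble::tibble(prefix25 = guide, set = "targeted",
                           abundance_pm = 100)
  hits <- find_candidates(species, pirnas, c(tx1 = tx),
                          configurations = tibble::tibble(g_start = 2,
                                                          g_end = 16:21))
  expect_equal(hits$configuration, "g2-g20")
  # queried as g2-g21 it is not a candidate: g21 is unpaired
  expect_false("g2-g21" %in% hits$configuration)
})

test_that("candidate classes equal the planted classes across 200 sites", {
  set.seed(42)
  rows <- list()
  txs <- character(0)
  for (i in 1:200) {
    x <- sample(16:20, 1)
    guide <- paste(sample(c("A", "C", "G", "U"), 25, replace = TRUE),
                   collapse = "")
    tx <- piwikit:::plant_site_transcript(guide, 2, x)
    id <- sprintf("tx%03d", i)
    txs[id] <- tx
    rows[[i]] <- tibble::tibble(species_id = sprintf("s%03d", i),
                                transcript = id, position = 30L,
                                prefix25 = guide, planted = x)
  }
  tab <- dplyr::bind_rows(rows)
  hits <- find_candidates(
    dplyr::select(tab, species_id, transcript, position),
    tibble::tibble(prefix25 = tab$prefix25, set = "targeted",
                   abundance_pm = 1),
    txs, configurations = tibble::tibble(g_start = 2, g_end = 16:20))
  # each species' own guide yields exactly its planted class
  own <- dplyr::inner_join(hits, tab,
                           by = c("species_id", "transcript", "position",
                                  "prefix25"))
  expect_equal(nrow(own), 200)
  expect_equal(own$g_end, own$planted)
})

deterministic_abundances <- function(ids, decreased, ppm = 10) {
  tidyr::crossing(species_id = ids, genotype = c("control", "mutant"),
                  replicate = 1:4) |>
    dplyr::mutate(ppm = ifelse(genotype == "mutant" &
                                 species_id %in% decreased,
                               ppm / 16, ppm))
}

test_that("fraction cleaved is the background-subtracted difference", {
  cand <- tibble::tibble(
    species_id = c(sprintf("t%02d", 1:10), sprintf("c%02d", 1:20)),
    set = rep(c("targeted", "control"), c(10, 20)),
    configuration = "g2-g20")
  ab <- deterministic_abundances(cand$species_id,
                                 c(sprintf("t%02d", 1:6), "c01", "c02"))
  fc <- fraction_cleaved(cand, ab, n_boot = 200)
  expect_equal(fc$f_decreased_targeted, 0.6)
  expect_equal(fc$f_decreased_control, 0.1)
  expect_equal(fc$f_cleaved, 0.5)
  expect_equal(nrow(tidy(fc)), 16)   # all 4 x 4 replicate pairings
})

test_that("an exactly 8-fold decrease counts as decreased", {
  cand <- tibble::tibble(species_id = c("t1", "c1"),
                         set = c("targeted", "control"),
                         configuration = "g2-g20")
  ab <- tidyr::crossing(species_id = c("t1", "c1"),
                        genotype = c("control", "mutant"),
                        replicate = 1:4) |>
    dplyr::mutate(ppm = dplyr::case_when(
      species_id == "t1" & genotype == "mutant" ~ 1,
      species_id == "t1" ~ 8,            # exactly control/8
      TRUE ~ 5))
  fc <- fraction_cleaved(cand, ab, n_boot = 50)
  expect_equal(fc$f_decreased_targeted, 1)
})

test_that("duplicate explaining piRNAs never change the site fractions", {
  cand <- tibble::tibble(
    species_id = c(sprintf("t%02d", 1:10), sprintf("c%02d", 1:10)),
    set = rep(c("targeted", "control"), each = 10),
    configuration = "g2-g20")
  ab <- deterministic_abundances(cand$species_id, c("t01", "t02"))
  fc1 <- fraction_cleaved(cand, ab, n_boot = 100)
  # a second piRNA explaining an already-counted site
  cand2 <- dplyr::bind_rows(cand, cand[1, ])
  fc2 <- fraction_cleaved(cand2, ab, n_boot = 100)
  expect_equal(fc1$f_decreased_targeted, fc2$f_decreased_targeted)
  expect_equal(fc1$f_cleaved, fc2$f_cleaved)
})

test_that("a missing control set is flagged, not computed", {
  cand <- tibble::tibble(species_id = "t1", set = "targeted",
                         configuration = "g2-g20")
  ab <- deterministic_abundances("t1", character(0))
  fc <- fraction_cleaved(cand, ab, n_boot = 10)
  expect_true(fc$flagged)
  expect_true(is.na(fc$f_cleaved))
})

test_that("an exchangeable cohort has median fraction cleaved near zero", {
  sim <- sim_degradome(phi = 0.05, background = 0.05,
                       n_targeted_sites = 120, n_control_sites = 240,
                       seed = 19)
  fc <- fraction_cleaved(sim$candidates, sim$species_abundances,
                         n_boot = 2000)
  expect_true(fc$ci_lo <= 0 & 0 <= fc$ci_hi)
})

test_that("planted cleavage above background is recovered", {
  sim <- sim_degradome(phi = 0.4, background = 0.05, seed = 7)
  fc <- fraction_cleaved(sim$candidates, sim$species_abundances,
                         n_boot = 2000)
  expect_true(fc$ci_lo <= 0.35 & 0.35 <= fc$ci_hi)
})

test_that("sites are binned by cumulative explaining-piRNA concentration", {
  cand <- tibble::tibble(
    species_id = c("s1", "s1", "s2", "s3"),
    set = c("targeted", "targeted", "targeted", "control"),
    configuration = "g2-g20",
    abundance_pm = c(300, 300, 30, 40))
  cum <- site_cumulative_abundance(cand)
  expect_equal(cum$cumulative_abundance_pm[cum$species_id == "s1"], 600)
  ab <- deterministic_abundances(c("s1", "s2", "s3"), "s1")
  binned <- bin_by_concentration(cand, ab, n_boot = 10)
  # s1 (600 pM) lands in >500; s2 at exactly 30 pM falls in 30-50
  # (lower-inclusive), alongside the 40 pM control site s3
  expect_setequal(as.character(binned$bin), c("30-50", ">500"))
  b_hi <- binned[binned$bin == ">500", ]
  expect_equal(b_hi$n_targeted, 1L)
  expect_true(b_hi$flagged)          # no control site in this bin
  b_mid <- binned[binned$bin == "30-50", ]
  expect_equal(b_mid$f_cleaved, 0)
})
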