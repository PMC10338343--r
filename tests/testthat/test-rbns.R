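test_guide <- "UGAGGUAGUAGGUUGUAUAGUUUU"  # 24 nt

test_windows <- tibble::tibble(g_start = c(2, 2, 4, 2),
                               g_end = c(8, 10, 14, 13),
                               site = c("g2-g8", "g2-g10", "g4-g14",
                                        "g2-g13"))

test_that("the site catalog encodes motifs and flank rules", {
  cat <- rbns_site_catalog(test_guide, test_windows)
  expect_equal(nrow(cat), 4)
  g <- strsplit(test_guide, "", fixed = TRUE)[[1]]
  row <- cat[cat$site == "g2-g10", ]
  expect_equal(row$motif, rna_reverse_complement(substr(test_guide, 2, 10)))
  # <= 10 nt: both flanks constrained; 11 nt: 5' side only; 12 nt: none
  expect_false(is.na(row$flank5_forbidden))
  expect_false(is.na(row$flank3_forbidden))
  row11 <- cat[cat$site == "g4-g14", ]
  expect_false(is.na(row11$flank5_forbidden))
  expect_true(is.na(row11$flank3_forbidden))
  row12 <- cat[cat$site == "g2-g13", ]
  expect_true(is.na(row12$flank5_forbidden))
  # the 8-mer seed site appends the t1 nucleotide to the motif
  cat8 <- rbns_site_catalog(test_guide,
                            tibble::tibble(g_start = 2, g_end = 8, t1 = "A"))
  expect_equal(nchar(cat8$motif), 8)
  expect_true(endsWith(cat8$motif, "A"))
})

test_that("single planted motifs are assigned, multiple motifs rejected", {
  cat <- rbns_site_catalog(test_guide, test_windows)
  m10 <- cat$motif[cat$site == "g2-g10"]
  bad5 <- cat$flank5_forbidden[cat$site == "g2-g10"]
  bad3 <- cat$flank3_forbidden[cat$site == "g2-g10"]
  flank5 <- setdiff(c("A", "C", "G", "U"), bad5)[1]
  flank3 <- setdiff(c("A", "C", "G", "U"), bad3)[1]
  pad <- 20 - nchar(m10) - 2
  read <- paste0("GAUC", flank5, m10, flank3, strrep("A", pad), "UGGA")
  res <- assign_sites(read, cat)
  expect_equal(res$site, "g2-g10")
  # two disjoint copies of the seed motif -> reject
  m8 <- cat$motif[cat$site == "g2-g8"]
  f5 <- setdiff(c("A", "C", "G", "U"),
                cat$flank5_forbidden[cat$site == "g2-g8"])[1]
  f3 <- setdiff(c("A", "C", "G", "U"),
                cat$flank3_forbidden[cat$site == "g2-g8"])[1]
  read2 <- paste0("GAUC", f5, m8, f3, f5, m8, f3,
                  strrep("A", 20 - 2 * (nchar(m8) + 2)), "UGGA")
  expect_equal(assign_sites(read2, cat)$site, "reject")
  expect_error(assign_sites("ACGT", cat), "malformed read layout")
})

test_that("assignment equals the exhaustive sliding-window brute force", {
  cat <- rbns_site_catalog(test_guide, test_windows)
  reads <- sim_rbns_reads(cat, 2500,
                          c("g2-g8" = 0.1, "g2-g10" = 0.1, "g4-g14" = 0.1,
                            "g2-g13" = 0.1), seed = 12)
  got <- assign_sites(reads$read, cat)$site
  want <- vapply(reads$read, oracle_assign, character(1),
                 guide = test_guide, windows = test_windows,
                 USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("generated bound counts at saturating RISC mirror the input", {
  # E_T far above every Kd: occupancies approach 1 and bound frequencies
  # approach the input frequencies
  sim <- sim_rbns_counts(c(s1 = 1e-5, s2 = 1e-4, no_site = 1e-3),
                         c(s1 = 0.3, s2 = 0.3),
                         concentrations_nm = c(bound_hi = 1),
                         stock_scale = 1000, n_reads = 4e5,
                         lib_conc_nm = 0.001, seed = 5)
  wide <- tidyr::pivot_wider(sim$counts, names_from = sample,
                             values_from = count)
  f_in <- wide$input / sum(wide$input)
  f_b <- wide$bound_hi / sum(wide$bound_hi)
  expect_lt(max(abs(f_in - f_b)), 0.01)
})

test_that("sites with identical truth get matching Kd estimates", {
  sim <- sim_rbns_counts(c(a = 0.05, b = 0.05, no_site = 2000),
                         c(a = 0.001, b = 0.001),
                         n_reads = 3e5, seed = 21)
  fit <- fit_kd_mle(sim$counts, guess_grid_nm = c(0.5, 2))
  kd <- fit$kd_pm[match(c("a", "b"), fit$site)]
  expect_lt(abs(log(kd[1] / kd[2])), log(1.3))
})

test_that("degenerate tables are handled with warnings and errors", {
  sim <- sim_rbns_counts(c(a = 0.05, no_site = 2000), c(a = 0.001),
                         n_reads = 1e5, seed = 3)
  counts <- sim$counts
  # a site absent from the input is excluded with a warning
  extra <- counts[counts$site == "a", ]
  extra$site <- "ghost"
  extra$count <- ifelse(extra$sample == "input", 0L, 5L)
  expect_warning(fit_kd_mle(rbind(counts, extra),
                            guess_grid_nm = c(1)), "absent from input")
  expect_error(fit_kd_mle(counts[counts$sample != "input", ]), "input")
  # sites long enough to be sliced are excluded from fitting by default
  wide_site <- counts[counts$site == "a", ]
  wide_site$site <- "g2-g17"
  counts2 <- rbind(counts, wide_site)
  counts2$width <- ifelse(counts2$site == "g2-g17", 16L, 9L)
  expect_warning(fit_kd_mle(counts2, guess_grid_nm = c(1)),
                 "width >= 15")
})

test_that("the closed-form binding curve obeys its limits", {
  expect_equal(filter_binding_fraction(2, 1, 0), 1)        # E_T >= S_T, Kd = 0
  expect_equal(filter_binding_fraction(0, 1, 0.05), 0)     # no RISC
  # S_T -> 0 at E_T = Kd: half of the target bound
  expect_equal(filter_binding_fraction(0.05, 1e-9, 0.05), 0.5,
               tolerance = 1e-4)
})

test_that("filter-binding fits recover Kd from noise-free curves", {
  et <- 10^seq(-3.5, 0.5, length.out = 12)
  for (kd_true in c(0.003, 0.05, 0.4)) {
    f <- filter_binding_fraction(et, 1e-4, kd_true)
    fit <- fit_filter_binding(et, f, 1e-4)
    expect_true(fit$converged)
    expect_lt(abs(fit$kd / kd_true - 1), 0.01)
  }
  # flat data are flagged unidentifiable
  flat <- fit_filter_binding(et, rep(0.02, 12), 1e-4)
  expect_true(flat$flagged)
})

test_that("energy regression reports r2 and a permutation P value", {
  x <- 1:10
  res <- energy_regression(2 * x + 3, x, n_perm = 200)
  expect_equal(res$r2, 1)
  expect_equal(res$pearson_r, 1)
  expect_lt(res$p_perm, 0.02)
  # two points: every permutation attains |r| = 1, so P = 1
  expect_error(energy_regression(c(1, 2), c(1, 2), n_perm = 10), "at least 3")
  res2 <- energy_regression(c(1, 2, 3), c(1, 2, 3), n_perm = 50)
  expect_true(res2$p_perm <= 1)
  # constant predictor: correlation undefined, flagged
  resc <- energy_regression(c(1, 2, 3), c(5, 5, 5), n_perm = 10)
  expect_true(resc$flagged)
})

test_that("null-data permutation P values are uniform across datasets", {
  set.seed(77)
  pvals <- replicate(100, {
    x <- rnorm(20); y <- rnorm(20)
    energy_regression(y, x, n_perm = 199)$p_perm
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})
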