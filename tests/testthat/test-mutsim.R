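random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

test_that("the mutation spectrum weights transitions over transversions", {
  sp <- mutation_spectrum(ts_tv_ratio = 2)
  expect_equal(nrow(sp), 12)
  expect_equal(sum(sp$weight), 1)
  w_ts <- sp$weight[sp$from == "A" & sp$to == "G"]
  w_tv <- sp$weight[sp$from == "A" & sp$to == "C"]
  expect_equal(w_ts / w_tv, 2)
  expect_error(mutation_spectrum(weights = c("A>X" = 1)), "unknown")
})

test_that("synonymous-only acceptance follows the genetic code", {
  # TTT (Phe): third-position T->C is synonymous, T->A (Leu) is not
  seq_chars <- strsplit("ATGTTTAAA", "", fixed = TRUE)[[1]]
  orf <- tibble::tibble(start = 0L, end = 9L)
  expect_true(piwikit:::substitution_synonymous(seq_chars, 6L, "C", orf))
  expect_false(piwikit:::substitution_synonymous(seq_chars, 6L, "A", orf))
  # outside any ORF everything is accepted
  expect_true(piwikit:::substitution_synonymous(seq_chars, 6L, "A",
                                                tibble::tibble(start = integer(0),
                                                               end = integer(0))))
  # overlapping ORFs must all stay synonymous
  orf2 <- tibble::tibble(start = c(0L, 3L), end = c(9L, 9L))
  expect_true(piwikit:::substitution_synonymous(seq_chars, 6L, "C", orf2))
})

test_that("a degenerate spectrum yields only the permitted substitution", {
  set.seed(21)
  sp <- mutation_spectrum(weights = c("A>G" = 1))
  seq_chars <- strsplit(random_dna(200), "", fixed = TRUE)[[1]]
  for (i in 1:25) {
    step <- mutate_step(seq_chars, sp)
    expect_equal(step$from, "A")
    expect_equal(step$to, "G")
  }
})

test_that("competence boundaries are exact", {
  set.seed(22)
  cons <- random_dna(200)
  rep1 <- sim_repertoire(cons, 1, seed = 5)
  seq_chars <- strsplit(cons, "", fixed = TRUE)[[1]]
  idx <- piwikit:::guide_site_indices(rep1$anchor, 26)
  # introduce mismatches one at a time at positions outside the critical set
  safe_gpos <- c(14, 15, 16, 17, 18, 22, 23)
  for (n_mm in c(6, 7)) {
    mut <- seq_chars
    for (g in safe_gpos[seq_len(n_mm)]) {
      p <- idx[g]
      mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
    }
    ct <- competence_table(mut, rep1)
    expect_equal(ct$mm_total, n_mm)
    expect_equal(ct$pirna_competent, n_mm <= 6)
  }
  # a single mismatch at g10 kills the siRNA but not the piRNA
  mut <- seq_chars
  mut[idx[10]] <- setdiff(c("A", "C", "G", "T"), mut[idx[10]])[1]
  ct <- competence_table(mut, rep1)
  expect_true(ct$pirna_competent)
  expect_false(ct$sirna_competent)
})

test_that("competence equals the brute-force positional checker", {
  set.seed(23)
  cons <- random_dna(500)
  rep_tbl <- sim_repertoire(cons, 40, seed = 6)
  for (i in 1:50) {
    mut <- strsplit(cons, "", fixed = TRUE)[[1]]
    n_mut <- sample(0:60, 1)
    pos <- sample(500, n_mut)
    mut[pos] <- sample(c("A", "C", "G", "T"), n_mut, replace = TRUE)
    ct <- competence_table(mut, rep_tbl)
    for (g in seq_len(nrow(rep_tbl))) {
      want <- oracle_competence(mut, rep_tbl$sequence[g], rep_tbl$anchor[g])
      expect_equal(ct$pirna_competent[g], want$pirna)
      expect_equal(ct$sirna_competent[g], want$sirna)
    }
  }
})

test_that("restricted rule dominance holds where it is provable", {
  # mismatches confined to the first 21 positions with total <= 5:
  # siRNA competence implies piRNA competence
  set.seed(24)
  cons <- random_dna(300)
  rep_tbl <- sim_repertoire(cons, 20, seed = 7)
  for (i in 1:30) {
    mut <- strsplit(cons, "", fixed = TRUE)[[1]]
    g <- sample(nrow(rep_tbl), 1)
    idx <- piwikit:::guide_site_indices(rep_tbl$anchor[g], 26)
    n_mm <- sample(0:5, 1)
    for (gp in sample(21, n_mm)) {
      mut[idx[gp]] <- setdiff(c("A", "C", "G", "T"), mut[idx[gp]])[1]
    }
    ct <- competence_table(mut, rep_tbl[g, ])
    if (ct$sirna_competent) expect_true(ct$pirna_competent)
  }
})

test_that("escape simulation starts at full competence and is reproducible", {
  set.seed(25)
  cons <- random_dna(600)
  orfs <- tibble::tibble(start = 60L, end = 360L)
  rep_tbl <- sim_repertoire(cons, 30, seed = 8)
  expect_equal(count_competent(cons, rep_tbl),
               tibble::tibble(n_pirna = 30L, n_sirna = 30L))
  t1 <- simulate_escape(cons, rep_tbl, orfs, n_steps = 50, n_sims = 2,
                        seed = 9)
  t2 <- simulate_escape(cons, rep_tbl, orfs, n_steps = 50, n_sims = 2,
                        seed = 9)
  expect_identical(t1, t2)
  expect_equal(t1$n_pirna[t1$step == 0], c(30L, 30L))
  expect_true(all(t1$n_pirna >= 0 & t1$n_pirna <= 30))
  # incremental bookkeeping agrees with a fresh count at the end
  last <- dplyr::filter(t1, sim == 1, step == 50)
  # replay lineage 1 to recover its final sequence
  sp <- mutation_spectrum()
  set.seed(9 + 1)
  sq <- strsplit(cons, "", fixed = TRUE)[[1]]
  wmat <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"),
                                          c("A","C","G","T")))
  sp_w <- sp
  wmat[cbind(sp_w$from, sp_w$to)] <- sp_w$weight
  for (st in 1:50) {
    repeat {
      pos <- sample.int(length(sq), 1L)
      to <- sample(c("A","C","G","T"), 1L, prob = wmat[sq[pos], ])
      if (piwikit:::substitution_synonymous(sq, pos, to, orfs)) break
    }
    sq[pos] <- to
  }
  fresh <- count_competent(paste(sq, collapse = ""), rep_tbl)
  expect_equal(last$n_pirna, fresh$n_pirna)
  expect_equal(last$n_sirna, fresh$n_sirna)
})

test_that("decay rates recover a constructed linear trajectory", {
  traj <- tibble::tibble(sim = 1L, step = 0:1000,
                         n_pirna = 1000L - 0:1000,
                         n_sirna = 1000L - 0:1000)
  rates <- decay_rate(traj, n_guides = 1000)
  expect_equal(rates$loss_pct_of_means[rates$class == "pirna"], 0.1,
               tolerance = 1e-8)
  expect_equal(rates$loss_pct_median[rates$class == "pirna"], 0.1,
               tolerance = 1e-8)
})

test_that("piRNA decay is no faster than siRNA decay on shared lineages", {
  set.seed(26)
  cons <- random_dna(800)
  rep_tbl <- sim_repertoire(cons, 60, seed = 10)
  traj <- simulate_escape(cons, rep_tbl, NULL, n_steps = 300, n_sims = 4,
                          seed = 11)
  rates <- decay_rate(traj)
  expect_lte(rates$loss_pct_of_means[rates$class == "pirna"],
             rates$loss_pct_of_means[rates$class == "sirna"])
})

test_that("simulated guide loss matches an independent site-level process", {
  # one guide, no ORFs: a lineage hits the 26-nt site with probability
  # 26/len per step, at a uniform site position, and redraws the base
  # from the spectrum row of the current base; mismatches accumulate and
  # can revert. Re-simulate exactly that marginal process independently
  # and compare the surviving-guide fraction after 200 steps.
  set.seed(27)
  len <- 400
  cons <- random_dna(len)
  rep_tbl <- sim_repertoire(cons, 1, seed = 12)
  traj <- simulate_escape(cons, rep_tbl, NULL, n_steps = 200, n_sims = 100,
                          seed = 13)
  sim_frac <- mean(traj$n_pirna[traj$step == 200])
  sp <- mutation_spectrum()
  wmat <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  wmat[cbind(sp$from, sp$to)] <- sp$weight
  site0 <- strsplit(substr(chartr("U", "T", cons), rep_tbl$anchor + 1,
                           rep_tbl$anchor + 26), "", fixed = TRUE)[[1]]
  set.seed(14)
  mc <- replicate(4000, {
    site <- site0
    for (s in 1:200) {
      if (runif(1) < 26 / len) {
        p <- sample.int(26, 1)
        site[p] <- sample(c("A", "C", "G", "T"), 1, prob = wmat[site[p], ])
      }
    }
    sum(site != site0) <= 6
  })
  expect_lt(abs(sim_frac - mean(mc)), 0.15)
})
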