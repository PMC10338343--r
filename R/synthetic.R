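# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes, with known ground truth. All randomness flows
# from the single `seed` argument of each generator.

rand_seq <- function(n, len, alphabet = c("A", "C", "G", "U")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate Bind-n-Seq site-level count tables from the equilibrium model
#'
#' Input reads are multinomial over the site-type input frequencies; each
#' bound sample draws reads with probability proportional to
#' `f_input * theta` where the occupancies come from the same free-RISC
#' conservation solved by the estimator's model at the given true Kd
#' values. This is the generative inverse of [fit_kd_mle()] at the level
#' of its sufficient statistics (site counts).
#'
#' @param true_kd_nm Named vector of true dissociation constants (nM),
#'   including a `"no_site"` entry.
#' @param site_freq Named vector of input frequencies for the non-no_site
#'   sites (no_site takes the remainder).
#' @param concentrations_nm Named vector of bound-sample concentrations.
#' @param n_reads Reads per sample.
#' @param lib_conc_nm Total library concentration (nM).
#' @param stock_scale True stock-concentration scale (1 = nominal).
#' @param seed Integer seed.
#' @return List: `counts` (long tibble `site`, `sample`, `count`),
#'   `truth` (site, kd_pm).
#' @export
sim_rbns_counts <- function(true_kd_nm, site_freq,
                            concentrations_nm = setNames(
                              RBNS_CONCENTRATIONS_NM,
                              paste0("bound_", RBNS_CONCENTRATIONS_NM)),
                            n_reads = 1e6, lib_conc_nm = 100,
                            stock_scale = 1, seed = 1) {
  set.seed(seed)
  stopifnot("no_site" %in% names(true_kd_nm),
            all(names(site_freq) %in% names(true_kd_nm)),
            sum(site_freq) < 1)
  sites <- names(true_kd_nm)
  f <- setNames(numeric(length(sites)), sites)
  f[names(site_freq)] <- site_freq
  f["no_site"] <- 1 - sum(site_freq)
  kd <- unname(true_kd_nm[sites])
  s_conc <- unname(f) * lib_conc_nm
  counts <- list(tibble(site = sites, sample = "input",
                        count = as.integer(rmultinom(1, n_reads, unname(f)))))
  e_total <- stock_scale * unname(concentrations_nm)
  e_free <- solve_free_risc(e_total, s_conc, kd)
  for (j in seq_along(e_total)) {
    theta <- if (e_free[j] > 0) e_free[j] / (e_free[j] + kd) else rep(0, length(kd))
    p <- unname(f) * theta
    if (sum(p) == 0) p <- unname(f)  # no RISC: bound sample = input
    counts[[j + 1L]] <- tibble(site = sites,
                               sample = names(concentrations_nm)[j],
                               count = as.integer(rmultinom(1, n_reads,
                                                            p / sum(p))))
  }
  list(counts = list_rbind(counts),
       truth = tibble(site = sites, kd_pm = kd * 1000))
}

#' Simulate Bind-n-Seq reads with planted binding sites
#'
#' Each read is a 20-nt random region in the constant GATC...TGGA layout;
#' with the given probabilities a catalog motif is planted at a uniformly
#' chosen position, its immediate flanks redrawn to satisfy the catalog's
#' non-complementarity rules.
#'
#' @param catalog A [rbns_site_catalog()].
#' @param n_reads Number of reads.
#' @param site_prob Named vector of planting probabilities per catalog
#'   site (remainder = unplanted random reads).
#' @param seed Integer seed.
#' @return Tibble `read`, `planted_site` (`"none"` for unplanted reads).
#' @export
sim_rbns_reads <- function(catalog, n_reads, site_prob, seed = 1) {
  set.seed(seed)
  stopifnot(all(names(site_prob) %in% catalog$site), sum(site_prob) <= 1)
  labels <- sample(c(names(site_prob), "none"), n_reads, replace = TRUE,
                   prob = c(site_prob, 1 - sum(site_prob)))
  reads <- character(n_reads)
  for (i in seq_len(n_reads)) {
    region <- sample(RNA_BASES, 20, replace = TRUE)
    if (labels[i] != "none") {
      row <- catalog[catalog$site == labels[i], ]
      motif <- strsplit(row$motif, "", fixed = TRUE)[[1]]
      w <- length(motif)
      if (w <= 20) {
        s <- sample.int(20 - w + 1L, 1L)
        region[s:(s + w - 1L)] <- motif
        if (!is.na(row$flank5_forbidden) && s > 1L) {
          region[s - 1L] <- sample(setdiff(RNA_BASES, row$flank5_forbidden), 1L)
        }
        if (!is.na(row$flank3_forbidden) && s + w <= 20L) {
          region[s + w] <- sample(setdiff(RNA_BASES, row$flank3_forbidden), 1L)
        }
      }
    }
    reads[i] <- paste0("GAUC", paste(region, collapse = ""), "UGGA")
  }
  tibble(read = reads, planted_site = labels)
}

#' Simulate Cleave-n-Seq time-course counts
#'
#' Uncleaved target abundance decays as `1 - burst_fraction(t)`; counts
#' are multinomial across the library at the configured depth per sample.
#' Normalizer variants (at most 7 nt complementarity, uncleavable) are
#' included with zero planted rate.
#'
#' @param true_k Tibble `variant_id`, `k` (min^-1) and optionally
#'   `e_relative` (default 1) and `k3` (default 0).
#' @param timepoints_fast,timepoints_slow The two sampling subsets
#'   (minutes).
#' @param n_trials Trials per subset (default 3).
#' @param depth Reads per sample (default 1e5).
#' @param n_normalizers Number of uncleavable normalizer variants.
#' @param seed Integer seed.
#' @return List: `counts` (tibble `variant_id`, `trial`, `timepoint_min`,
#'   `count`), `normalizer_ids`, `truth`.
#' @export
sim_cns <- function(true_k, timepoints_fast = CNS_TIMEPOINTS_FAST,
                    timepoints_slow = CNS_TIMEPOINTS_SLOW, n_trials = 3,
                    depth = 1e5, n_normalizers = 20, seed = 1) {
  set.seed(seed)
  if (!"e_relative" %in% names(true_k)) true_k$e_relative <- 1
  if (!"k3" %in% names(true_k)) true_k$k3 <- 0
  norm_ids <- sprintf("norm_%02d", seq_len(n_normalizers))
  lib <- bind_rows(true_k,
                   tibble(variant_id = norm_ids, k = 0, e_relative = 1,
                          k3 = 0))
  w <- rep(1 / nrow(lib), nrow(lib))
  samples <- crossing(subset = c("fast", "slow"),
                      trial_i = seq_len(n_trials)) |>
    mutate(trial = paste0(.data$subset, "_", .data$trial_i))
  counts <- pmap(samples, function(subset, trial_i, trial) {
    tp <- if (subset == "fast") timepoints_fast else timepoints_slow
    map(tp, function(t) {
      u <- 1 - burst_fraction(t, lib$e_relative, lib$k - lib$k3, lib$k3)
      p <- w * u
      tibble(variant_id = lib$variant_id, trial = trial, timepoint_min = t,
             count = as.integer(rmultinom(1, depth, p / sum(p))))
    }) |> list_rbind()
  }) |> list_rbind()
  list(counts = counts, normalizer_ids = norm_ids,
       truth = select(true_k, "variant_id", "k", "e_relative", "k3"))
}

plant_site_transcript <- function(guide, g_start, g_end, tx_len = 60,
                                  position = 30L) {
  g <- strsplit(guide, "", fixed = TRUE)[[1]]
  n <- length(g)
  tx <- sample(RNA_BASES, tx_len, replace = TRUE)
  for (i in seq_len(n)) {
    idx <- position + 10L - i  # 0-based index opposite g_i
    if (idx >= 0 && idx < tx_len) {
      if (i >= g_start && i <= g_end) {
        tx[idx + 1L] <- RNA_COMPLEMENT[[g[i]]]
      } else if (i == g_end + 1L || (i == g_start - 1L && i >= 2L)) {
        tx[idx + 1L] <- g[i]  # same base never pairs (WC or wobble)
      }
    }
  }
  paste(tx, collapse = "")
}

#' Simulate a degradome cohort with planted cleavage
#'
#' Emits piRNA abundance tables (12 control + 9 mutant small-RNA
#' replicates), 5'-monophosphorylated species tables (4 control + 4 mutant
#' degradome replicates), transcripts with planted target sites, the
#' planted candidate table, and per-site truth labels.
#'
#' The generator plants the marginal decreased fractions directly:
#' a targeted-set site is reduced `drop_fold`-fold in mutants with
#' probability `phi` (the planted cleavage fraction, background included),
#' a control-set site with probability `background` (the sampling-error
#' rate for short-lived species), so the expected value of the
#' background-subtracted statistic is exactly `phi - background`. Setting
#' `phi = background` gives the exchangeable no-signal null.
#'
#' @param phi Planted fraction of targeted-set sites decreased at least
#'   8-fold in mutants.
#' @param background Planted decreased fraction among control-set sites.
#' @param configuration Pairing class planted at every site (`g_start`,
#'   `g_end`).
#' @param n_targeted_sites,n_control_sites Candidate sites per set.
#' @param n_targeted_pirnas,n_control_pirnas Repertoire sizes.
#' @param depth Degradome reads per replicate (Poisson counting noise).
#' @param drop_fold Planted fold-reduction of decreased sites.
#' @param site_ppm_meanlog,site_ppm_sdlog Log-normal control-abundance
#'   parameters for species (ppm).
#' @param abundance_meanlog,abundance_sdlog Log-normal piRNA intracellular
#'   concentration parameters (pM).
#' @param seed Integer seed.
#' @return List: `pirna_replicates` (input for [group_pirnas()]),
#'   `pirnas` (prefix25, set, abundance_pm, abundance_ppm), `species`,
#'   `species_abundances`, `transcripts`, `candidates`, `truth`.
#' @export
sim_degradome <- function(phi = 0.5, background = 0.05,
                          configuration = c(g_start = 2, g_end = 20),
                          n_targeted_sites = 150, n_control_sites = 300,
                          n_targeted_pirnas = 30, n_control_pirnas = 60,
                          depth = 5e6, drop_fold = 100,
                          site_ppm_meanlog = log(5), site_ppm_sdlog = 0.6,
                          abundance_meanlog = log(30),
                          abundance_sdlog = 1.5, seed = 1) {
  set.seed(seed)
  n_pi <- n_targeted_pirnas + n_control_pirnas
  pirnas <- tibble(
    prefix25 = rand_seq(n_pi, 25),
    set = rep(c("targeted", "control"),
              c(n_targeted_pirnas, n_control_pirnas)),
    abundance_pm = rlnorm(n_pi, abundance_meanlog, abundance_sdlog)) |>
    mutate(abundance_ppm = .data$abundance_pm / 16.6)
  # small-RNA replicate table: targeted piRNAs vanish in mutants
  reps <- crossing(prefix25 = pirnas$prefix25,
                   genotype = c("control", "mutant")) |>
    left_join(pirnas, by = "prefix25") |>
    mutate(n_rep = ifelse(.data$genotype == "control", 12L, 9L))
  pirna_replicates <- reps |>
    rowwise() |>
    reframe(prefix25 = .data$prefix25, genotype = .data$genotype,
            replicate = seq_len(.data$n_rep),
            ppm = {
      base <- pmax(.data$abundance_ppm, 1.5)
      mean_ppm <- if (.data$genotype == "mutant" && .data$set == "targeted") {
        0.01
      } else base
      pmax(rnorm(.data$n_rep, mean_ppm, 0.05 * mean_ppm), 0)
    }) |>
    mutate(unique_mapping = TRUE, .before = 1)

  n_sites <- n_targeted_sites + n_control_sites
  site_set <- rep(c("targeted", "control"), c(n_targeted_sites,
                                              n_control_sites))
  explain_idx <- ifelse(site_set == "targeted",
                        sample.int(n_targeted_pirnas, n_sites, replace = TRUE),
                        n_targeted_pirnas +
                          sample.int(n_control_pirnas, n_sites, replace = TRUE))
  g_start <- configuration[["g_start"]]; g_end <- configuration[["g_end"]]
  cfg <- sprintf("g%d-g%d", g_start, g_end)
  transcripts <- setNames(
    vapply(explain_idx, function(i) {
      plant_site_transcript(pirnas$prefix25[i], g_start, g_end)
    }, character(1)),
    sprintf("tx_%04d", seq_len(n_sites)))
  species <- tibble(species_id = sprintf("sp_%04d", seq_len(n_sites)),
                    transcript = names(transcripts), position = 30L)
  decreased <- ifelse(site_set == "targeted",
                      runif(n_sites) < phi, runif(n_sites) < background)
  ctrl_ppm <- pmax(rlnorm(n_sites, site_ppm_meanlog, site_ppm_sdlog), 0.04)
  species_abundances <- crossing(i = seq_len(n_sites),
                                 genotype = c("control", "mutant"),
                                 replicate = 1:4) |>
    mutate(species_id = species$species_id[.data$i],
           mean_ppm = ifelse(.data$genotype == "mutant" & decreased[.data$i],
                             ctrl_ppm[.data$i] / drop_fold,
                             ctrl_ppm[.data$i]),
           ppm = rpois(dplyr::n(), .data$mean_ppm * depth / 1e6) * 1e6 /
             depth) |>
    select("species_id", "genotype", "replicate", "ppm")
  candidates <- tibble(species_id = species$species_id,
                       transcript = species$transcript,
                       position = species$position,
                       prefix25 = pirnas$prefix25[explain_idx],
                       set = site_set,
                       abundance_pm = pirnas$abundance_pm[explain_idx],
                       configuration = cfg,
                       g_start = g_start, g_end = g_end)
  list(pirna_replicates = pirna_replicates,
       pirnas = select(pirnas, "prefix25", "set", "abundance_pm",
                       "abundance_ppm"),
       species = species, species_abundances = species_abundances,
       transcripts = transcripts, candidates = candidates,
       truth = tibble(species_id = species$species_id, set = site_set,
                      configuration = cfg, decreased = decreased,
                      phi = phi, background = background))
}

#' Simulate a guide repertoire over a consensus sequence
#'
#' Antisense 26-nt guides are sampled uniformly along the consensus with
#' exact-match anchors (zero initial mismatches); abundances are
#' log-normal, with defaults placing a small upper tail above 500 pM.
#'
#' @param consensus Consensus sequence (DNA string).
#' @param n_guides Number of guides.
#' @param guide_length Guide length (default 26).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance
#'   parameters (pM).
#' @param seed Integer seed.
#' @return Tibble `guide_id`, `sequence` (RNA, 5'->3'), `anchor` (0-based
#'   site start on the consensus), `abundance_pm`.
#' @export
sim_repertoire <- function(consensus, n_guides, guide_length = 26,
                           abundance_meanlog = log(30),
                           abundance_sdlog = 1.5, seed = 1) {
  set.seed(seed)
  consensus <- toupper(chartr("U", "T", consensus))
  len <- nchar(consensus)
  if (len < guide_length) abort("consensus shorter than the guide length")
  anchors <- sample.int(len - guide_length + 1L, n_guides, replace = TRUE) - 1L
  sites <- substring(consensus, anchors + 1L, anchors + guide_length)
  guides <- chartr("T", "U", dna_revcomp(sites))
  tibble(guide_id = sprintf("pi_%04d", seq_len(n_guides)),
         sequence = guides, anchor = anchors,
         abundance_pm = rlnorm(n_guides, abundance_meanlog, abundance_sdlog))
}

#' Simulate a cleavage cohort from a known logistic decision function
#'
#' Generates piRNA-site records whose cleavage labels are drawn from a
#' known logistic model over the 35 features, with the abundance
#' coefficient above the energy coefficient above every positional
#' coefficient by default.
#'
#' @param n Number of piRNA-site pairs.
#' @param prevalence Target cleaved fraction; the generating intercept is
#'   set so the mean cleavage probability matches it.
#' @param beta_abundance,beta_energy,beta_positional,beta_paired_total
#'   Generating coefficients (on the min-max-rescaled features).
#' @param seed Integer seed.
#' @return List: `data` (input for [build_features()], including the drawn
#'   `cleaved` labels), `features` (the built feature table), `beta_true`
#'   (named generating coefficients on x1..x35).
#' @export
sim_logit_cohort <- function(n = 2000, prevalence = 0.3, beta_abundance = 5,
                             beta_energy = 2.5, beta_positional = 0.3,
                             beta_paired_total = 0.5, seed = 1) {
  set.seed(seed)
  paired_n <- sample(19:24, n, replace = TRUE)
  pairing <- vapply(paired_n, function(np) {
    st <- rep(".", 25)
    st[1] <- "."
    st[1 + sample.int(24, np)] <- "|"  # paired positions among g2..g25
    paste(st, collapse = "")
  }, character(1))
  # log-normal abundance clipped to a detection ceiling so the min-max
  # rescaled feature has a stable range across cohort realizations
  abundance <- pmin(pmax(rlnorm(n, log(5), 0.8), 0.11), 50)
  # pairing energy tracks the paired count only loosely: most of its
  # variation is identity-dependent, which keeps the feature separable
  # from the positional indicators
  delta_g0 <- -(0.5 * paired_n + rnorm(n, 6, 3))
  data <- tibble(pairing = pairing,
                 abundance_ppm = abundance,
                 delta_g0 = delta_g0,
                 t1 = sample(c("A", "U", "C", "G"), n, replace = TRUE),
                 region = sample(c("5utr", "orf", "3utr", "none"), n,
                                 replace = TRUE),
                 lncrna = runif(n) < 0.2,
                 cleaved = 0)
  feat <- build_features(data)
  beta <- setNames(numeric(35), paste0("x", 1:35))
  beta[paste0("x", 1:24)] <- beta_positional
  beta["x25"] <- beta_paired_total
  beta["x26"] <- beta_abundance
  beta["x27"] <- beta_energy
  eta0 <- drop(as.matrix(feat[, paste0("x", 1:35)]) %*% beta)
  beta0 <- log(prevalence / (1 - prevalence)) - mean(eta0)
  eta <- beta0 + eta0
  cleaved <- as.numeric(runif(nrow(feat)) < 1 / (1 + exp(-eta)))
  data$cleaved <- cleaved   # no rows filtered by construction
  feat$cleaved <- cleaved
  list(data = data, features = feat, beta_true = beta, beta0 = beta0)
}
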