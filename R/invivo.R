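# Degradome analysis: piRNA 25-nt prefix grouping, absolute quantification,
# candidate 3'-cleavage-product identification, and the background-
# subtracted fraction-cleaved statistic with permutation and bootstrap
# uncertainty.

AVOGADRO <- 6.02214076e23

#' Filter and partition piRNA 25-nt prefix groups
#'
#' Reads are grouped by their 5' 25-nt prefix (3' trimming makes piRNA 3'
#' ends heterogeneous). A prefix group is retained when it maps
#' unambiguously to a single genomic position and is at or above
#' `min_control_ppm` in every control replicate. Retained groups are split
#' into the targeted set (undetectable in mutants: mean mutant abundance at
#' or below `mutant_undetectable_ppm`) and the control set. All thresholds
#' are inclusive.
#'
#' @param pirnas Long tibble with columns `prefix25`, `unique_mapping`
#'   (logical), `genotype` (`"control"` / `"mutant"`), `replicate`, `ppm`.
#' @param n_control_replicates Expected number of control replicates (the
#'   all-replicates rule is checked against this; default 12).
#' @param min_control_ppm Retention threshold (ppm) applied to every
#'   control replicate.
#' @param mutant_undetectable_ppm Mean-mutant threshold below which a group
#'   is called eliminated in the mutant.
#' @return Tibble `prefix25`, `mean_control_ppm`, `mean_mutant_ppm`,
#'   `retained`, `set` (`"targeted"` / `"control"`, NA when dropped).
#' @export
group_pirnas <- function(pirnas, n_control_replicates = 12,
                         min_control_ppm = 1,
                         mutant_undetectable_ppm = 0.1) {
  stopifnot(all(c("prefix25", "unique_mapping", "genotype", "replicate",
                  "ppm") %in% names(pirnas)))
  n_ctrl <- pirnas |>
    filter(.data$genotype == "control") |>
    distinct(.data$replicate) |>
    nrow()
  if (n_ctrl != n_control_replicates) {
    abort(sprintf("expected %d control replicates, found %d",
                  n_control_replicates, n_ctrl))
  }
  pirnas |>
    group_by(.data$prefix25) |>
    summarize(
      unique_mapping = .data$unique_mapping[1],
      mean_control_ppm = mean(.data$ppm[.data$genotype == "control"]),
      mean_mutant_ppm = mean(.data$ppm[.data$genotype == "mutant"]),
      .min_ctrl = min(.data$ppm[.data$genotype == "control"]),
      .n_ctrl = sum(.data$genotype == "control"),
      .groups = "drop") |>
    mutate(retained = .data$unique_mapping &
             .data$.n_ctrl == n_control_replicates &
             .data$.min_ctrl >= min_control_ppm,
           set = case_when(
             !.data$retained ~ NA_character_,
             .data$mean_mutant_ppm <= mutant_undetectable_ppm ~ "targeted",
             TRUE ~ "control")) |>
    select(-".min_ctrl", -".n_ctrl")
}

#' Absolute quantification through spike-in calibration
#'
#' Spike-in oligonucleotides of known molecular input give a linear
#' reads-to-molecules calibration (fit through the origin, pooled over
#' spikes); molecule counts per cell are converted to intracellular molar
#' concentration by dividing by Avogadro's number times the cell volume.
#'
#' @param data Tibble with a `count` column (reads per species per sample).
#' @param spike_counts Reads observed for each spike-in.
#' @param spike_molecules Known input molecules for each spike-in (same
#'   order), per the amount of material corresponding to `n_cells`.
#' @param n_cells Number of cells the sample represents.
#' @param cell_volume_pl Cell volume in picolitres (default 1 pL,
#'   approximately a mouse primary spermatocyte).
#' @return `data` plus columns `molecules_per_cell` and `abundance_pm`.
#' @export
absolute_quantify <- function(data, spike_counts, spike_molecules,
                              n_cells = 1, cell_volume_pl = 1) {
  stopifnot(length(spike_counts) == length(spike_molecules))
  if (sum(spike_counts) <= 0) abort("zero spike-in recovery: calibration failed")
  molecules_per_read <- sum(spike_molecules) / sum(spike_counts)
  vol_l <- cell_volume_pl * 1e-12
  data |>
    mutate(molecules_per_cell = .data$count * molecules_per_read / n_cells,
           abundance_pm = .data$molecules_per_cell / (AVOGADRO * vol_l) * 1e12)
}

#' Find piRNAs explaining 5'-monophosphorylated RNA species
#'
#' For every species (a distinct 5'-monophosphorylated RNA 5' end) and
#' every retained piRNA, the guide is laid antiparallel on the transcript
#' with t10 at the species 5' end (so the scissile t10|t11 bond coincides
#' with the observed 5' monophosphate) and the pairing annotated. The
#' species is a candidate for configuration `gA-gB` when guide positions
#' A..B are all paired, and the guide nucleotides immediately outside the
#' paired region (gA-1 when A > 2, gB+1 when present) are unpaired, so
#' that configuration classes do not overlap.
#'
#' @param species Tibble `species_id`, `transcript`, `position` (0-based
#'   coordinate of the species 5' end = t10).
#' @param pirnas Tibble `prefix25` (25-nt guide prefix sequence), `set`,
#'   and optionally `abundance_pm`.
#' @param transcripts Named character vector (or tibble `transcript`,
#'   `sequence`) of transcript sequences.
#' @param configurations Tibble with columns `g_start`, `g_end` describing
#'   the contiguous pairing classes to query (default g2-gX for X = 16..20).
#' @param wobble Pairing convention passed to [annotate_pairing()].
#' @return Tibble of candidates: `species_id`, `transcript`, `position`,
#'   `prefix25`, `set`, `abundance_pm`, `configuration`, `g_start`,
#'   `g_end`. Species with missing sequence context are skipped with a
#'   warning.
#' @export
find_candidates <- function(species, pirnas, transcripts,
                            configurations = tibble(g_start = 2,
                                                    g_end = 16:20),
                            wobble = c("paired", "mismatch")) {
  wobble <- match.arg(wobble)
  if (is.data.frame(transcripts)) {
    transcripts <- setNames(transcripts$sequence, transcripts$transcript)
  }
  transcripts <- vapply(transcripts, normalize_rna, character(1))
  if (!"abundance_pm" %in% names(pirnas)) pirnas$abundance_pm <- NA_real_
  n_skipped <- 0L
  out <- vector("list", nrow(species))
  for (si in seq_len(nrow(species))) {
    tx <- transcripts[[species$transcript[si]]]
    if (is.null(tx) || is.na(tx)) { n_skipped <- n_skipped + 1L; next }
    c0 <- species$position[si]
    rows <- vector("list", nrow(pirnas))
    for (pi in seq_len(nrow(pirnas))) {
      guide <- pirnas$prefix25[pi]
      n <- nchar(guide)
      lo <- c0 + 10L - n
      hi <- c0 + 9L
      if (lo < 0 || hi >= nchar(tx)) next
      pr <- annotate_pairing(guide, tx, t1_index = hi, wobble = wobble)
      paired_states <- if (wobble == "paired") c("wc", "gu") else "wc"
      paired <- pr$state %in% paired_states
      ok <- vapply(seq_len(nrow(configurations)), function(r) {
        a <- configurations$g_start[r]; b <- configurations$g_end[r]
        b <= n && all(paired[a:b]) &&
          (a <= 2 || !paired[a - 1L]) &&
          (b >= n || !paired[b + 1L])
      }, logical(1))
      hits <- configurations[ok, , drop = FALSE]
      if (nrow(hits) == 0) next
      rows[[pi]] <- tibble(species_id = species$species_id[si],
                           transcript = species$transcript[si],
                           position = c0,
                           prefix25 = guide,
                           set = pirnas$set[pi],
                           abundance_pm = pirnas$abundance_pm[pi],
                           configuration = sprintf("g%d-g%d", hits$g_start,
                                                   hits$g_end),
                           g_start = hits$g_start, g_end = hits$g_end)
    }
    out[[si]] <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  }
  if (n_skipped > 0) {
    warn(sprintf("%d species skipped for missing sequence context", n_skipped))
  }
  list_rbind(out[!vapply(out, is.null, logical(1))])
}

# decreased-indicator matrix: sites x (control x mutant pairings)
decreased_matrix <- function(ab_wide, sites, fold_threshold, floor_ppm) {
  ctrl <- as.matrix(ab_wide[match(sites, ab_wide$species_id),
                            grep("^control_", names(ab_wide)), drop = FALSE])
  mut <- as.matrix(ab_wide[match(sites, ab_wide$species_id),
                           grep("^mutant_", names(ab_wide)), drop = FALSE])
  n_pair <- ncol(ctrl) * ncol(mut)
  dec <- matrix(FALSE, nrow = length(sites), ncol = n_pair)
  k <- 0L
  for (i in seq_len(ncol(ctrl))) {
    for (j in seq_len(ncol(mut))) {
      k <- k + 1L
      dec[, k] <- mut[, j] == 0 |
        ctrl[, i] / pmax(mut[, j], floor_ppm) >= fold_threshold
    }
  }
  dec
}

#' Fraction of candidate cleavage sites lost in the mutant
#'
#' For each pairing configuration, the fraction of non-redundant candidate
#' sites whose abundance drops at least `fold_threshold`-fold in the mutant
#' (`f_decreased`) is computed for the targeted-piRNA set and for the
#' control-piRNA set (sampling-error background), under each of the 16
#' single-animal pairings of 4 control and 4 mutant replicates;
#' `f_cleaved = f_decreased_targeted - f_decreased_control` per pairing,
#' summarized as the median over the 16 pairings with a bootstrap
#' confidence interval over candidate sites.
#'
#' A site counted in several explaining piRNAs is counted once per set; a
#' site absent from a mutant replicate always counts as decreased, and
#' otherwise the mutant abundance is floored at one read-equivalent
#' (`floor_ppm`) before the fold change is taken. The fold threshold is
#' inclusive.
#'
#' @param candidates Output of [find_candidates()] (columns `species_id`,
#'   `set`, `configuration`).
#' @param abundances Tibble `species_id`, `genotype`, `replicate`, `ppm`
#'   with 4 control and 4 mutant replicates.
#' @param fold_threshold Inclusive fold-decrease threshold (default 8).
#' @param n_boot Bootstrap iterations over candidate sites (default 10000).
#' @param floor_ppm Floor for mutant abundances; defaults to the smallest
#'   positive mutant ppm observed (one read-equivalent).
#' @param conf_level Bootstrap confidence level (default 0.95).
#' @return A `piwikit_fcleaved` tibble: one row per configuration with
#'   `n_targeted`, `n_control`, `f_decreased_targeted`,
#'   `f_decreased_control`, `f_cleaved` (medians over the 16 pairings),
#'   `ci_lo`, `ci_hi`, `flagged`; per-pairing values in attribute
#'   `permutations`.
#' @export
fraction_cleaved <- function(candidates, abundances, fold_threshold = 8,
                             n_boot = 10000, floor_ppm = NULL,
                             conf_level = 0.95) {
  stopifnot(all(c("species_id", "set", "configuration") %in% names(candidates)))
  ab_wide <- abundances |>
    mutate(col = paste0(.data$genotype, "_", .data$replicate)) |>
    select("species_id", "col", "ppm") |>
    pivot_wider(names_from = "col", values_from = "ppm")
  if (is.null(floor_ppm)) {
    mut_ppm <- abundances$ppm[abundances$genotype == "mutant"]
    floor_ppm <- if (any(mut_ppm > 0)) min(mut_ppm[mut_ppm > 0]) else 1
  }
  alpha <- (1 - conf_level) / 2
  perms <- list()
  res <- candidates |>
    distinct(.data$configuration) |>
    pull() |>
    map(function(cfg) {
      cand <- filter(candidates, .data$configuration == cfg)
      t_sites <- unique(cand$species_id[cand$set == "targeted"])
      c_sites <- unique(cand$species_id[cand$set == "control"])
      if (length(c_sites) == 0 || length(t_sites) == 0) {
        return(tibble(configuration = cfg, n_targeted = length(t_sites),
                      n_control = length(c_sites),
                      f_decreased_targeted = NA_real_,
                      f_decreased_control = NA_real_,
                      f_cleaved = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, flagged = TRUE))
      }
      dt <- decreased_matrix(ab_wide, t_sites, fold_threshold, floor_ppm)
      dc <- decreased_matrix(ab_wide, c_sites, fold_threshold, floor_ppm)
      ft <- colMeans(dt)
      fc <- colMeans(dc)
      perms[[cfg]] <<- tibble(configuration = cfg,
                              permutation = seq_along(ft),
                              f_decreased_targeted = ft,
                              f_decreased_control = fc,
                              f_cleaved = ft - fc)
      # bootstrap over sites, targeted and control resampled independently
      nt <- nrow(dt); nc <- nrow(dc)
      wt <- rmultinom(n_boot, nt, rep(1 / nt, nt))
      wc_ <- rmultinom(n_boot, nc, rep(1 / nc, nc))
      bt <- crossprod(dt, wt) / nt     # 16 x n_boot
      bc <- crossprod(dc, wc_) / nc
      stat <- apply(bt - bc, 2, median)
      ci <- quantile(stat, c(alpha, 1 - alpha), names = FALSE)
      tibble(configuration = cfg, n_targeted = nt, n_control = nc,
             f_decreased_targeted = median(ft),
             f_decreased_control = median(fc),
             f_cleaved = median(ft - fc),
             ci_lo = ci[1], ci_hi = ci[2], flagged = FALSE)
    }) |>
    list_rbind()
  structure(res, class = c("piwikit_fcleaved", class(res)),
            permutations = list_rbind(perms),
            fold_threshold = fold_threshold, n_boot = n_boot,
            floor_ppm = floor_ppm)
}

#' Cumulative explaining piRNA abundance per candidate site
#'
#' Even when a site is explained by several piRNAs it is counted once; the
#' abundances of all explaining piRNAs are summed to assess concentration
#' dependence.
#'
#' @param candidates Output of [find_candidates()].
#' @return Tibble `species_id`, `configuration`, `set`,
#'   `cumulative_abundance_pm`.
#' @export
site_cumulative_abundance <- function(candidates) {
  candidates |>
    group_by(.data$species_id, .data$configuration, .data$set) |>
    summarize(cumulative_abundance_pm = sum(.data$abundance_pm),
              .groups = "drop")
}

#' Fraction cleaved binned by explaining-piRNA concentration
#'
#' Sites are partitioned by the cumulative intracellular concentration of
#' their explaining piRNAs into the bins <30, 30-50, 50-100, 100-500 and
#' >500 pM (lower-inclusive: a site at exactly 30 pM falls in 30-50), and
#' the fraction-cleaved statistic recomputed inside each bin.
#'
#' @inheritParams fraction_cleaved
#' @param breaks_pm Bin edges in pM.
#' @return Tibble: one row per configuration x bin with the
#'   [fraction_cleaved()] columns plus `bin`.
#' @export
bin_by_concentration <- function(candidates, abundances, fold_threshold = 8,
                                 n_boot = 10000, floor_ppm = NULL,
                                 breaks_pm = c(0, 30, 50, 100, 500, Inf)) {
  labs <- c(sprintf("<%g", breaks_pm[2]),
            sprintf("%g-%g", breaks_pm[2:(length(breaks_pm) - 2)],
                    breaks_pm[3:(length(breaks_pm) - 1)]),
            sprintf(">%g", breaks_pm[length(breaks_pm) - 1]))
  cum <- site_cumulative_abundance(candidates) |>
    mutate(bin = cut(.data$cumulative_abundance_pm, breaks = breaks_pm,
                     labels = labs, right = FALSE, include.lowest = TRUE))
  binned <- candidates |>
    left_join(cum, by = c("species_id", "configuration", "set"))
  binned |>
    distinct(.data$bin) |>
    arrange(.data$bin) |>
    pull() |>
    map(function(b) {
      sub <- filter(binned, .data$bin == b)
      as_tibble(fraction_cleaved(sub, abundances, fold_threshold,
                                 n_boot, floor_ppm)) |>
        mutate(bin = b, .before = 1)
    }) |>
    list_rbind()
}

#' @export
tidy.piwikit_fcleaved <- function(x, ...) attr(x, "permutations")

#' @export
glance.piwikit_fcleaved <- function(x, ...) {
  tibble(n_configurations = nrow(x),
         fold_threshold = attr(x, "fold_threshold"),
         n_boot = attr(x, "n_boot"),
         floor_ppm = attr(x, "floor_ppm"))
}
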