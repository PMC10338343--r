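# Transposon mutagenesis escape simulation: iterated single-nucleotide
# substitutions under a mutation spectrum, synonymous-only inside ORFs,
# with counting of cleavage-competent piRNA and siRNA guides.
#
# Competence rules: a 26-nt piRNA remains competent with at most 6 total
# mismatches at any position; a 21-nt siRNA (the piRNA 5' prefix) with at
# most 5 total mismatches, at most 1 mismatch between g2 and g8, and no
# mismatch at g9, g10, g11 or g13. G:U is counted as a mismatch for these
# rules (configurable).

DNA_BASES <- c("A", "C", "G", "T")

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' Build a 12-entry single-nucleotide mutation spectrum
#'
#' @param ts_tv_ratio Weight ratio of each transition to each transversion
#'   (default 2). There are 4 transitions and 8 transversions; weights are
#'   normalized to sum to 1.
#' @param weights Optional named numeric vector `"X>Y"` overriding the
#'   ratio-based spectrum (normalized internally).
#' @return Tibble `from`, `to`, `weight`.
#' @export
mutation_spectrum <- function(ts_tv_ratio = 2, weights = NULL) {
  sp <- crossing(from = DNA_BASES, to = DNA_BASES) |>
    filter(.data$from != .data$to) |>
    mutate(transition = (.data$from %in% c("A", "G") &
                           .data$to %in% c("A", "G")) |
             (.data$from %in% c("C", "T") & .data$to %in% c("C", "T")),
           weight = ifelse(.data$transition, ts_tv_ratio, 1))
  if (!is.null(weights)) {
    key <- paste0(sp$from, ">", sp$to)
    if (!all(names(weights) %in% key)) abort("unknown substitution in weights")
    sp$weight <- 0
    sp$weight[match(names(weights), key)] <- weights
  }
  if (any(sp$weight < 0) || sum(sp$weight) <= 0) {
    abort("spectrum weights must be nonnegative and not all zero")
  }
  sp |>
    mutate(weight = .data$weight / sum(.data$weight)) |>
    select("from", "to", "weight")
}

translate_codon <- function(codon) GENETIC_CODE_TABLE[[codon]]

# is a substitution old->new at pos synonymous in every ORF containing it?
substitution_synonymous <- function(seq_chars, pos, new_base, orf_intervals) {
  if (is.null(orf_intervals) || nrow(orf_intervals) == 0) return(TRUE)
  covering <- which(orf_intervals$start <= pos - 1L &
                      pos - 1L < orf_intervals$end)
  for (o in covering) {
    st <- orf_intervals$start[o]
    codon_i <- (pos - 1L - st) %/% 3L
    c0 <- st + codon_i * 3L + 1L
    codon <- seq_chars[c0:(c0 + 2L)]
    new_codon <- codon
    new_codon[pos - c0 + 1L] <- new_base
    if (translate_codon(paste(codon, collapse = "")) !=
          translate_codon(paste(new_codon, collapse = ""))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Propose and accept one substitution step
#'
#' A position is drawn uniformly, a replacement base is drawn with
#' probability proportional to the spectrum weights for the current base,
#' and the proposal is accepted unless it causes a non-synonymous codon
#' change in any ORF containing it (in which case position and base are
#' redrawn).
#'
#' @param seq_chars Character vector of the current sequence (DNA bases).
#' @param spectrum A [mutation_spectrum()].
#' @param orf_intervals Tibble `start`, `end` (0-based half-open; lengths
#'   divisible by 3, frame = start) or NULL.
#' @param max_redraw Bound on rejected proposals before erroring.
#' @return List `seq` (updated character vector), `pos` (1-based), `from`,
#'   `to`.
#' @export
mutate_step <- function(seq_chars, spectrum, orf_intervals = NULL,
                        max_redraw = 100000) {
  wmat <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  wmat[cbind(spectrum$from, spectrum$to)] <- spectrum$weight
  for (try in seq_len(max_redraw)) {
    pos <- sample.int(length(seq_chars), 1L)
    from <- seq_chars[pos]
    w <- wmat[from, ]
    if (sum(w) <= 0) next
    to <- sample(DNA_BASES, 1L, prob = w)
    if (substitution_synonymous(seq_chars, pos, to, orf_intervals)) {
      seq_chars[pos] <- to
      return(list(seq = seq_chars, pos = pos, from = from, to = to))
    }
  }
  abort("no acceptable substitution found (pathological input)")
}

# per-guide site map: consensus index (0-based) opposite guide position i
# is anchor + L - i for a guide of length L whose site occupies
# [anchor, anchor + L) with t1 at the highest index.
guide_site_indices <- function(anchor, guide_length) {
  anchor + guide_length - seq_len(guide_length) + 1L  # 1-based vector
}

#' Per-guide mismatch counts and competence against a sequence
#'
#' Each guide is evaluated at its fixed anchor (coordinates do not shift
#' because only substitutions are simulated).
#'
#' @param sequence Consensus sequence (DNA string or character vector).
#' @param repertoire Tibble `guide_id`, `sequence` (26-nt RNA guide,
#'   5'->3'), `anchor` (0-based start of the target site on the consensus).
#' @param sirna_length siRNA prefix length (default 21).
#' @return Tibble per guide: mismatch tallies (`mm_total`, `mm_prefix`,
#'   `mm_seed`, `mm_critical`) and flags `pirna_competent`,
#'   `sirna_competent`.
#' @export
competence_table <- function(sequence, repertoire, sirna_length = 21) {
  seq_chars <- if (length(sequence) == 1L) {
    strsplit(toupper(chartr("U", "T", sequence)), "", fixed = TRUE)[[1]]
  } else sequence
  n_g <- nrow(repertoire)
  lens <- nchar(repertoire$sequence)
  mm_total <- integer(n_g)
  mm_prefix <- integer(n_g)
  mm_seed <- integer(n_g)
  mm_crit <- integer(n_g)
  g_all <- strsplit(chartr("U", "T", toupper(repertoire$sequence)), "",
                    fixed = TRUE)
  for (gi in seq_len(n_g)) {
    L <- lens[gi]
    idx <- guide_site_indices(repertoire$anchor[gi], L)
    if (idx[L] < 1L || idx[1] > length(seq_chars)) {
      abort(sprintf("anchor of guide %s outside sequence",
                    repertoire$guide_id[gi]))
    }
    mm <- seq_chars[idx] != DNA_COMPLEMENT[g_all[[gi]]]
    mm_total[gi] <- sum(mm)
    mm_prefix[gi] <- sum(mm[seq_len(min(sirna_length, L))])
    mm_seed[gi] <- sum(mm[2:8])
    mm_crit[gi] <- sum(mm[c(9, 10, 11, 13)])
  }
  tibble(guide_id = repertoire$guide_id,
         mm_total = mm_total, mm_prefix = mm_prefix,
         mm_seed = mm_seed, mm_critical = mm_crit,
         pirna_competent = mm_total <= 6,
         sirna_competent = mm_prefix <= 5 & mm_seed <= 1 & mm_crit == 0)
}

#' Count cleavage-competent piRNA and siRNA guides
#'
#' @inheritParams competence_table
#' @return One-row tibble `n_pirna`, `n_sirna`.
#' @export
count_competent <- function(sequence, repertoire, sirna_length = 21) {
  ct <- competence_table(sequence, repertoire, sirna_length)
  tibble(n_pirna = sum(ct$pirna_competent), n_sirna = sum(ct$sirna_competent))
}

#' Simulate transposon escape lineages
#'
#' Runs `n_sims` independent lineages of `n_steps` accepted substitutions
#' each (synonymous-only inside ORFs) and records, after every step, how
#' many repertoire piRNAs and simulated siRNAs remain competent to cleave
#' the mutated sequence. Mismatch bookkeeping is updated incrementally at
#' the mutated position only.
#'
#' @param consensus Consensus sequence (DNA string).
#' @param repertoire Guide repertoire (see [competence_table()]).
#' @param orf_intervals Tibble `start`, `end` (0-based half-open) or NULL.
#' @param n_steps Accepted substitutions per lineage (default 1000).
#' @param n_sims Independent lineages (default 100).
#' @param spectrum A [mutation_spectrum()] (default ts:tv 2:1).
#' @param seed Integer seed; lineage s uses `seed + s` so trajectories are
#'   reproducible individually.
#' @param sirna_length siRNA prefix length (default 21).
#' @return A `piwikit_trajectories` tibble: `sim`, `step` (0..n_steps),
#'   `n_pirna`, `n_sirna`, with the repertoire size in attribute
#'   `n_guides`.
#' @export
simulate_escape <- function(consensus, repertoire, orf_intervals = NULL,
                            n_steps = 1000, n_sims = 100,
                            spectrum = mutation_spectrum(), seed = 1,
                            sirna_length = 21) {
  seq0 <- strsplit(toupper(chartr("U", "T", consensus)), "", fixed = TRUE)[[1]]
  if (!is.null(orf_intervals) && nrow(orf_intervals) > 0) {
    bad <- (orf_intervals$end - orf_intervals$start) %% 3 != 0 |
      orf_intervals$start < 0 | orf_intervals$end > length(seq0)
    if (any(bad)) abort("ORF intervals must lie in the sequence with length divisible by 3")
  }
  n_g <- nrow(repertoire)
  L <- nchar(repertoire$sequence)
  if (any(L < sirna_length)) abort("guides shorter than the siRNA prefix")
  # site maps and required bases
  g_chars <- strsplit(chartr("U", "T", toupper(repertoire$sequence)), "",
                      fixed = TRUE)
  site_idx <- map2(repertoire$anchor, L, guide_site_indices)
  req <- map(g_chars, function(g) unname(DNA_COMPLEMENT[g]))
  if (any(unlist(site_idx) < 1L) || any(unlist(site_idx) > length(seq0))) {
    abort("guide anchor outside the consensus sequence")
  }
  # coverage: for each consensus position, which (guide, gpos) pairs sit there
  cov_guide <- vector("list", length(seq0))
  cov_gpos <- vector("list", length(seq0))
  for (gi in seq_len(n_g)) {
    for (k in seq_along(site_idx[[gi]])) {
      p <- site_idx[[gi]][k]
      cov_guide[[p]] <- c(cov_guide[[p]], gi)
      cov_gpos[[p]] <- c(cov_gpos[[p]], k)
    }
  }
  wmat <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  wmat[cbind(spectrum$from, spectrum$to)] <- spectrum$weight

  run_one <- function(s) {
    set.seed(seed + s)
    sq <- seq0
    ct0 <- competence_table(sq, repertoire, sirna_length)
    mm_total <- ct0$mm_total
    mm_prefix <- ct0$mm_prefix
    mm_seed <- ct0$mm_seed
    mm_crit <- ct0$mm_critical
    n_pi <- integer(n_steps + 1L)
    n_si <- integer(n_steps + 1L)
    n_pi[1] <- sum(mm_total <= 6)
    n_si[1] <- sum(mm_prefix <= 5 & mm_seed <= 1 & mm_crit == 0)
    for (st in seq_len(n_steps)) {
      repeat {
        pos <- sample.int(length(sq), 1L)
        from <- sq[pos]
        to <- sample(DNA_BASES, 1L, prob = wmat[from, ])
        if (substitution_synonymous(sq, pos, to, orf_intervals)) break
      }
      affected <- cov_guide[[pos]]
      if (length(affected)) {
        gpos <- cov_gpos[[pos]]
        for (a in seq_along(affected)) {
          gi <- affected[a]; k <- gpos[a]
          was_mm <- sq[pos] != req[[gi]][k]
          is_mm <- to != req[[gi]][k]
          d <- as.integer(is_mm) - as.integer(was_mm)
          if (d != 0L) {
            mm_total[gi] <- mm_total[gi] + d
            if (k <= sirna_length) mm_prefix[gi] <- mm_prefix[gi] + d
            if (k >= 2 && k <= 8) mm_seed[gi] <- mm_seed[gi] + d
            if (k %in% c(9, 10, 11, 13)) mm_crit[gi] <- mm_crit[gi] + d
          }
        }
      }
      sq[pos] <- to
      n_pi[st + 1L] <- sum(mm_total <= 6)
      n_si[st + 1L] <- sum(mm_prefix <= 5 & mm_seed <= 1 & mm_crit == 0)
    }
    tibble(sim = s, step = 0:n_steps, n_pirna = n_pi, n_sirna = n_si)
  }
  out <- list_rbind(map(seq_len(n_sims), run_one))
  structure(out, class = c("piwikit_trajectories", class(out)),
            n_guides = n_g, seed = seed)
}

#' Guide loss rate per substitution
#'
#' Least-squares slope of the fraction of competent guides versus the
#' substitution count, expressed as percent of guides lost per
#' substitution. Reported both as the slope of the across-simulation mean
#' trajectory and as the distribution (median, IQR) of per-simulation
#' slopes.
#'
#' @param trajectories A [simulate_escape()] result (or a compatible
#'   tibble with `sim`, `step`, `n_pirna`, `n_sirna`).
#' @param n_guides Repertoire size (taken from the trajectories attribute
#'   when present).
#' @return Tibble per guide class: `loss_pct_of_means` (slope of the mean
#'   trajectory), `loss_pct_median`, `q25`, `q75` (per-simulation slopes).
#' @export
decay_rate <- function(trajectories, n_guides = attr(trajectories, "n_guides")) {
  if (is.null(n_guides)) abort("repertoire size required")
  long <- trajectories |>
    pivot_longer(cols = c("n_pirna", "n_sirna"), names_to = "class",
                 values_to = "n") |>
    mutate(class = sub("^n_", "", .data$class),
           frac = .data$n / n_guides)
  slope_pct <- function(step, frac) {
    if (length(unique(frac)) == 1L) return(0)
    -unname(coef(lm(frac ~ step))[2]) * 100
  }
  per_sim <- long |>
    group_by(.data$class, .data$sim) |>
    summarize(loss = slope_pct(.data$step, .data$frac), .groups = "drop")
  of_means <- long |>
    group_by(.data$class, .data$step) |>
    summarize(frac = mean(.data$frac), .groups = "drop") |>
    group_by(.data$class) |>
    summarize(loss_pct_of_means = slope_pct(.data$step, .data$frac),
              .groups = "drop")
  per_sim |>
    group_by(.data$class) |>
    summarize(loss_pct_median = median(.data$loss),
              q25 = quantile(.data$loss, 0.25),
              q75 = quantile(.data$loss, 0.75), .groups = "drop") |>
    left_join(of_means, by = "class")
}
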