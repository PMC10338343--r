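# Nearest-neighbour duplex free energy.
#
# Built-in Turner 2004 stacking parameters (Watson-Crick and G:U wobble
# pairs, delta-G at 37 C, kcal/mol), duplex initiation and terminal AU/GU
# penalties, plus simple fixed penalties for internal loops and bulges.
# Dangling ends and loop-sequence effects are not modelled: the predictor is
# a deterministic, self-contained stacking sum, adequate for ranking duplex
# configurations and for the monotonicity guarantees the rest of the
# package relies on.

PAIR_LEVELS <- c("CG", "GC", "GU", "UG", "AU", "UA")

# stack_raw[p1, p2c]: energy of the dinucleotide step 5'-x1 x2-3' paired to
# 3'-y1 y2-5', where p1 = x1y1 and p2c = y2x2 (the second pair read on the
# opposite strand). Layout follows the standard published table.
STACK_DG <- matrix(c(
  # p2c:  CG     GC     GU     UG     AU     UA
  -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,  # p1 = CG
  -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,  # p1 = GC
  -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,  # p1 = GU
  -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,  # p1 = UG
  -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,  # p1 = AU
  -2.10, -2.40, -1.30, -1.00, -0.90, -1.30   # p1 = UA
), nrow = 6, byrow = TRUE, dimnames = list(PAIR_LEVELS, PAIR_LEVELS))

DUPLEX_INIT_DG <- 4.10
TERMINAL_AU_DG <- 0.50  # applied per helix end closed by AU/UA/GU/UG

swap_pair <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))

#' Free-energy increment of one nearest-neighbour stack
#'
#' @param pair1,pair2 Pair codes `"XY"` = guide nucleotide then target
#'   nucleotide, for two consecutive guide positions (5'->3' on the guide).
#' @return Stacking free energy in kcal/mol.
#' @export
stack_energy <- function(pair1, pair2) {
  p2c <- swap_pair(pair2)
  if (!all(pair1 %in% PAIR_LEVELS) || !all(p2c %in% PAIR_LEVELS)) {
    abort(sprintf("unknown dinucleotide step %s/%s",
                  paste(pair1, collapse = ","), paste(pair2, collapse = ",")))
  }
  STACK_DG[cbind(pair1, p2c)]
}

internal_loop_penalty <- function(n_guide, n_target) {
  n <- n_guide + n_target
  if (n_guide == 0L || n_target == 0L) {
    3.8 + 1.1 * log(max(n, 1L))            # bulge
  } else {
    1.6 + 1.1 * log(n / 2)                 # internal loop / mismatch run
  }
}

#' Predict the standard free energy of a guide:target duplex
#'
#' Nearest-neighbour stacking sum over contiguous paired blocks
#' (Watson-Crick and G:U parameters), plus duplex initiation, terminal
#' AU/GU penalties at every helix end, and fixed penalties for the internal
#' loops and bulges separating the blocks. Unpaired flanks outside the
#' outermost paired positions contribute nothing. An empty pairing has
#' energy 0 by convention.
#'
#' @param pairing A [annotate_pairing()] result. G:U wobbles count as paired
#'   for block contiguity (the object's own wobble convention is ignored
#'   here: energy always treats wobbles as stackable pairs).
#' @return One-row tibble: `delta_g0` (kcal/mol), `model_tag`, `n_paired`,
#'   `n_blocks`.
#' @export
predict_duplex_energy <- function(pairing) {
  stopifnot(inherits(pairing, "piwikit_pairing"))
  paired <- pairing$state %in% c("wc", "gu")
  if (!any(paired)) {
    return(tibble(delta_g0 = 0, model_tag = "turner2004-stacks",
                  n_paired = 0L, n_blocks = 0L))
  }
  pr <- paste0(pairing$guide_nt, pairing$target_nt)
  r <- rle(paired)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  block_start <- starts[r$values]
  block_end <- ends[r$values]

  dg <- DUPLEX_INIT_DG
  for (b in seq_along(block_start)) {
    i0 <- block_start[b]; i1 <- block_end[b]
    if (i1 > i0) {
      dg <- dg + sum(stack_energy(pr[i0:(i1 - 1L)], pr[(i0 + 1L):i1]))
    }
    for (end_pair in pr[c(i0, i1)]) {
      if (end_pair %in% c("AU", "UA", "GU", "UG")) dg <- dg + TERMINAL_AU_DG
    }
    if (b > 1L) {
      gap <- seq(block_end[b - 1L] + 1L, block_start[b] - 1L)
      n_guide <- sum(pairing$state[gap] != "guide_bulge")
      t_hi <- pairing$target_index[block_end[b - 1L]]
      t_lo <- pairing$target_index[block_start[b]]
      n_target <- t_hi - t_lo - 1L
      dg <- dg + internal_loop_penalty(n_guide, n_target)
    }
  }
  tibble(delta_g0 = dg, model_tag = "turner2004-stacks",
         n_paired = sum(paired), n_blocks = length(block_start))
}

#' Duplex free energy directly from sequences
#'
#' Convenience wrapper: annotates the pairing and returns the scalar
#' predicted free energy.
#'
#' @inheritParams annotate_pairing
#' @return Scalar free energy (kcal/mol).
#' @export
duplex_energy <- function(guide, target, t1_index = NULL, indels = NULL) {
  predict_duplex_energy(
    annotate_pairing(guide, target, t1_index = t1_index, indels = indels)
  )$delta_g0
}
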