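# Guide:target pairing in g/t coordinates.
#
# Conventions used throughout the package:
#  * guide positions are 1-based (g1 = 5'-most guide nucleotide);
#  * transcript/target coordinates are 0-based, half-open;
#  * the target runs antiparallel to the guide, so along the target 5'->3'
#    the paired positions read tN ... t1, and the nucleotide opposite g_i
#    sits at target index c + 10 - i, where c is the index of t10;
#  * the scissile phosphodiester bond lies between t10 and t11, so the 3'
#    cleavage product (which carries the 5' monophosphate) starts at t10.

RNA_BASES <- c("A", "C", "G", "U")

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

WOBBLE_PARTNER <- c(G = "U", U = "G")

#' Normalize and validate an RNA sequence
#'
#' Uppercases, converts T to U and checks the alphabet is A/C/G/U.
#'
#' @param x Character vector of sequences.
#' @param what Label used in error messages.
#' @param min_len,max_len Optional length bounds (inclusive).
#' @return The normalized character vector.
#' @export
normalize_rna <- function(x, what = "sequence", min_len = NULL, max_len = NULL) {
  x <- chartr("tu", "TU", toupper(x))
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,U}: %s",
                  what, paste(head(x[bad], 3), collapse = ", ")))
  }
  n <- nchar(x)
  if (!is.null(min_len) && any(n < min_len)) {
    abort(sprintf("%s shorter than %d nt", what, min_len))
  }
  if (!is.null(max_len) && any(n > max_len)) {
    abort(sprintf("%s longer than %d nt", what, max_len))
  }
  x
}

#' Reverse complement of an RNA sequence
#'
#' @param x Character vector of RNA sequences (A/C/G/U).
#' @return Character vector of reverse complements.
#' @export
rna_reverse_complement <- function(x) {
  vapply(strsplit(chartr("T", "U", toupper(x)), "", fixed = TRUE), function(s) {
    paste(rev(unname(RNA_COMPLEMENT[s])), collapse = "")
  }, character(1))
}

#' Build a validated guide table
#'
#' A guide is a small-RNA sequence written 5'->3', 18-35 nt long, with an
#' optional intracellular abundance in pM.
#'
#' @param name Character vector of guide identifiers.
#' @param sequence RNA sequences (A/C/G/U, length 18-35).
#' @param abundance_pm Optional non-negative abundances (pM).
#' @return A tibble with columns `name`, `sequence`, `length`, `abundance_pm`.
#' @export
guide_table <- function(name, sequence, abundance_pm = NA_real_) {
  sequence <- normalize_rna(sequence, "guide sequence", min_len = 18, max_len = 35)
  if (any(!is.na(abundance_pm) & abundance_pm < 0)) {
    abort("guide abundance_pm must be non-negative")
  }
  tibble(name = as.character(name), sequence = sequence,
         length = nchar(sequence),
         abundance_pm = as.numeric(abundance_pm))
}

pair_state <- function(guide_nt, target_nt) {
  ifelse(RNA_COMPLEMENT[guide_nt] == target_nt, "wc",
    ifelse(!is.na(WOBBLE_PARTNER[guide_nt]) &
             WOBBLE_PARTNER[guide_nt] == target_nt, "gu", "mismatch"))
}

#' Annotate the pairing configuration of a guide:target duplex
#'
#' Classifies every guide position g1..gN against the antiparallel target as
#' Watson-Crick (`"wc"`), G:U wobble (`"gu"`), `"mismatch"`, or
#' `"guide_bulge"` (guide nucleotide with no target partner). Comparison is
#' gapless unless `indels` is supplied.
#'
#' @param guide Guide RNA sequence, 5'->3'.
#' @param target Target RNA sequence, 5'->3'.
#' @param t1_index 0-based index in `target` of the nucleotide opposite g1.
#'   Defaults to the last position of `target`, i.e. a target that ends at t1.
#' @param indels Optional tibble with columns `g` and `type`
#'   (`"guide_bulge"`: guide position `g` skips the target;
#'   `"target_bulge"`: one extra target nucleotide between `g` and `g + 1`).
#' @param wobble Either `"paired"` (default; G:U counts towards
#'   `paired_count` and contiguity) or `"mismatch"`.
#' @return A tibble of class `piwikit_pairing` with columns `g`, `guide_nt`,
#'   `target_index`, `target_nt`, `state`, carrying attributes
#'   `paired_count`, `span` (maximal contiguous paired block in g
#'   coordinates, or NULL), `t1_index`, `guide`, `target`, `wobble`,
#'   `insertions`.
#' @export
annotate_pairing <- function(guide, target, t1_index = NULL, indels = NULL,
                             wobble = c("paired", "mismatch")) {
  wobble <- match.arg(wobble)
  guide <- normalize_rna(guide, "guide")
  target <- normalize_rna(target, "target")
  n <- nchar(guide)
  if (is.null(t1_index)) t1_index <- nchar(target) - 1L
  gchars <- strsplit(guide, "", fixed = TRUE)[[1]]
  tchars <- strsplit(target, "", fixed = TRUE)[[1]]

  bulge_at <- integer(0)
  insert_after <- integer(0)
  if (!is.null(indels) && nrow(indels) > 0) {
    bulge_at <- indels$g[indels$type == "guide_bulge"]
    insert_after <- indels$g[indels$type == "target_bulge"]
  }

  if (length(bulge_at) == 0 && length(insert_after) == 0) {
    # gapless fast path: g_i opposes target index t1_index - (i - 1)
    target_index <- t1_index - (seq_len(n) - 1L)
    if (target_index[n] < 0 || t1_index >= length(tchars)) {
      abort("target too short to oppose all guide positions")
    }
    target_nt <- tchars[target_index + 1L]
    state <- unname(pair_state(gchars, target_nt))
  } else {
    target_index <- integer(n)
    state <- character(n)
    target_nt <- character(n)
    idx <- t1_index
    for (i in seq_len(n)) {
      if (i %in% bulge_at) {
        target_index[i] <- NA_integer_
        target_nt[i] <- NA_character_
        state[i] <- "guide_bulge"
        # target index does not advance: g_i is looped out of the duplex
      } else {
        if (idx < 0 || idx >= length(tchars)) {
          abort(sprintf("target too short to oppose guide position g%d", i))
        }
        target_index[i] <- idx
        target_nt[i] <- tchars[idx + 1L]
        state[i] <- pair_state(gchars[i], tchars[idx + 1L])
        idx <- idx - 1L
      }
      if (i %in% insert_after) idx <- idx - 1L  # skip the inserted target nt
    }
  }

  paired_states <- if (wobble == "paired") c("wc", "gu") else "wc"
  paired <- state %in% paired_states
  span <- NULL
  if (any(paired)) {
    r <- rle(paired)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values)
    best <- k[which.max(r$lengths[k])]
    span <- c(g_start = starts[best], g_end = ends[best])
  }

  out <- tibble(g = seq_len(n), guide_nt = gchars,
                target_index = target_index, target_nt = target_nt,
                state = state)
  structure(out,
            class = c("piwikit_pairing", class(out)),
            guide = guide, target = target, t1_index = t1_index,
            wobble = wobble, paired_count = sum(paired), span = span,
            insertions = insert_after)
}

#' Number of paired guide positions
#' @param pairing A `piwikit_pairing` object.
#' @return Integer count of paired positions under the object's wobble
#'   convention.
#' @export
paired_count <- function(pairing) attr(pairing, "paired_count")

#' Compact string serialization of a pairing configuration
#'
#' One character per guide position: `|` Watson-Crick, `:` G:U wobble,
#' `.` mismatch, `-` guide bulge (target deletion); a `+` is inserted after
#' position g for each target insertion.
#'
#' @param pairing A `piwikit_pairing` object.
#' @return A single string.
#' @export
pairing_string <- function(pairing) {
  code <- c(wc = "|", gu = ":", mismatch = ".", guide_bulge = "-")
  chars <- unname(code[pairing$state])
  for (g in sort(attr(pairing, "insertions"), decreasing = TRUE)) {
    chars <- append(chars, "+", after = g)
  }
  paste(chars, collapse = "")
}

#' Parse a compact pairing string
#'
#' Inverse of [pairing_string()] at the level of states (sequences are not
#' recoverable from the string).
#'
#' @param x A string over `{|, :, ., -, +}`.
#' @return A tibble with columns `g` and `state`; target insertions are
#'   returned in the `insertions` attribute (guide position after which the
#'   insertion occurs).
#' @export
parse_pairing_string <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("|", ":", ".", "-", "+"))) {
    abort("pairing string may only contain | : . - +")
  }
  decode <- c("|" = "wc", ":" = "gu", "." = "mismatch", "-" = "guide_bulge")
  g <- 0L
  states <- character(0)
  insertions <- integer(0)
  for (ch in chars) {
    if (ch == "+") {
      insertions <- c(insertions, g)
    } else {
      g <- g + 1L
      states <- c(states, decode[[ch]])
    }
  }
  structure(tibble(g = seq_len(g), state = states), insertions = insertions)
}

#' Cleavage-site coordinates from the position of t10
#'
#' The scissile bond joins t10 and t11; slicing leaves a 3' product whose
#' first nucleotide is t10 and which carries the 5' monophosphate.
#'
#' @param guide_length Guide length N (nt).
#' @param t10_index 0-based target index of t10.
#' @return One-row tibble: `three_prime_start` (index of the 3' product's
#'   first nucleotide, = t10), `five_prime_end` (half-open end of the 5'
#'   product), `t1_index`, `t11_index`, `paired_start`, `paired_end`
#'   (half-open span of target indices opposite g1..gN).
#' @export
cut_site_coordinates <- function(guide_length, t10_index) {
  t10_index <- as.integer(t10_index)
  tibble(three_prime_start = t10_index,
         five_prime_end = t10_index,
         t11_index = t10_index - 1L,
         t1_index = t10_index + 9L,
         paired_start = t10_index + 10L - as.integer(guide_length),
         paired_end = t10_index + 10L)
}

#' Convert a dissociation constant to a standard binding free energy
#'
#' \eqn{\Delta G^0 = R T \ln(K_d / 1\,\mathrm{M})} with
#' \eqn{R = 1.987 \times 10^{-3}} kcal/(mol K).
#'
#' @param kd_molar Dissociation constant in molar units (> 0).
#' @param temperature_k Temperature in kelvin; defaults to 306.15 K (33
#'   degrees C, the binding-assay temperature).
#' @return Binding free energy in kcal/mol (negative = favorable).
#' @export
kd_to_energy <- function(kd_molar, temperature_k = 306.15) {
  if (any(!is.finite(kd_molar)) || any(kd_molar <= 0)) {
    abort("kd_molar must be positive and finite")
  }
  GAS_CONSTANT_KCAL * temperature_k * log(kd_molar)
}

GAS_CONSTANT_KCAL <- 1.987e-3
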