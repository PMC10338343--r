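# Independent brute-force oracles, written as literal rule applications and
# kept free of the package's internal helpers.

ORACLE_WC <- c(A = "U", C = "G", G = "C", U = "A")

oracle_random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# per-position pairing classifier: character-by-character, gapless
oracle_classify <- function(guide, target, t1_index) {
  g <- strsplit(guide, "", fixed = TRUE)[[1]]
  t <- strsplit(target, "", fixed = TRUE)[[1]]
  vapply(seq_along(g), function(i) {
    tn <- t[t1_index - (i - 1) + 1]
    if (ORACLE_WC[[g[i]]] == tn) {
      "wc"
    } else if ((g[i] == "G" && tn == "U") || (g[i] == "U" && tn == "G")) {
      "gu"
    } else {
      "mismatch"
    }
  }, character(1))
}

# exhaustive sliding-window site assignment over a full-layout read.
# windows: data frame with guide-coordinate columns g_start, g_end, site.
# Flank rules: core width <= 10 -> both flanks must not be the WC partner
# of the adjacent guide position; width 11 -> only the flank beyond g_end.
oracle_assign <- function(read, guide, windows) {
  r <- strsplit(read, "", fixed = TRUE)[[1]]
  g <- strsplit(guide, "", fixed = TRUE)[[1]]
  hits <- character(0)
  for (w in seq_len(nrow(windows))) {
    a <- windows$g_start[w]; b <- windows$g_end[w]
    width <- b - a + 1
    # read-sense motif is the reverse complement of guide[a..b]
    for (s in seq_len(length(r) - width + 1)) {
      ok <- TRUE
      for (k in 0:(width - 1)) {
        # read position s+k is opposite guide position b-k
        if (r[s + k] != ORACLE_WC[[g[b - k]]]) { ok <- FALSE; break }
      }
      if (!ok) next
      if (width <= 11 && b < length(g) && s > 1 &&
            r[s - 1] == ORACLE_WC[[g[b + 1]]]) ok <- FALSE
      if (width <= 10 && a > 1 && s + width <= length(r) &&
            r[s + width] == ORACLE_WC[[g[a - 1]]]) ok <- FALSE
      if (ok) hits <- c(hits, windows$site[w])
    }
  }
  if (length(hits) == 0) "no_site" else if (length(hits) == 1) hits else "reject"
}

# positional competence checker (DNA alphabet): guide laid antiparallel at
# its anchor; mismatch wherever the consensus base is not the DNA
# complement of the guide base.
oracle_competence <- function(seq_chars, guide_rna, anchor) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  g <- strsplit(chartr("U", "T", guide_rna), "", fixed = TRUE)[[1]]
  L <- length(g)
  mm <- vapply(seq_len(L), function(i) {
    seq_chars[anchor + L - i + 1] != comp[[g[i]]]
  }, logical(1))
  list(
    pirna = sum(mm) <= 6,
    sirna = sum(mm[1:21]) <= 5 && sum(mm[2:8]) <= 1 &&
      !any(mm[c(9, 10, 11, 13)])
  )
}

# trapezoid precision-recall integration, direct loop
oracle_pr_auc <- function(scores, labels) {
  ord <- order(-scores)
  y <- labels[ord]
  pos <- sum(y)
  tp <- 0
  prev_r <- 0; prev_p <- 1
  auc <- 0
  for (k in seq_along(y)) {
    tp <- tp + y[k]
    r <- tp / pos
    p <- tp / k
    auc <- auc + (r - prev_r) * (p + prev_p) / 2
    prev_r <- r; prev_p <- p
  }
  auc
}

# step-by-step stacking-sum walk over a fully paired duplex, reading the
# published stack value for each consecutive pair of pairs directly
oracle_full_duplex_energy <- function(guide, target) {
  g <- strsplit(guide, "", fixed = TRUE)[[1]]
  t <- strsplit(target, "", fixed = TRUE)[[1]]
  n <- length(g)
  pairs <- vapply(seq_len(n), function(i) {
    paste0(g[i], t[n - i + 1])
  }, character(1))
  dg <- 4.10
  for (i in seq_len(n - 1)) {
    p1 <- pairs[i]
    p2 <- pairs[i + 1]
    p2c <- paste0(substr(p2, 2, 2), substr(p2, 1, 1))
    dg <- dg + piwikit:::STACK_DG[p1, p2c]
  }
  for (end_pair in pairs[c(1, n)]) {
    if (end_pair %in% c("AU", "UA", "GU", "UG")) dg <- dg + 0.5
  }
  dg
}
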