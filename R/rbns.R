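# Bind-n-Seq analysis: site-type assignment of random-region reads and
# maximum-likelihood estimation of per-site dissociation constants across a
# RISC concentration series.

#' The six-point RISC concentration series (nM)
#' @export
RBNS_CONCENTRATIONS_NM <- c(0.003, 0.01, 0.032, 0.1, 0.316, 1)

#' Build a non-overlapping site-type catalog for Bind-n-Seq assignment
#'
#' Each site type is a contiguous complementarity window `gX-gY` of the
#' guide. To keep site sets non-overlapping, windows of 10 nt or shorter
#' must be flanked on both sides by read nucleotides that are not
#' (Watson-Crick) complementary to the adjacent guide positions; 11-nt
#' windows require the non-complementary flank only on the guide-5' side
#' (beyond gY); windows of 12 nt or more carry no flank requirement. An
#' optional t1 requirement (e.g. the canonical 8-mer seed = g2-g8 plus t1A)
#' extends the motif by the fixed t1 nucleotide.
#'
#' @param guide Guide RNA sequence, 5'->3'.
#' @param windows Tibble with columns `g_start`, `g_end`, optional `t1`
#'   (NA or a base that must sit opposite g1) and optional `site` names.
#' @return Tibble catalog with one row per site type: `site`, `g_start`,
#'   `g_end`, `t1`, `width`, `motif` (read-sense 5'->3'), `flank5_forbidden`
#'   and `flank3_forbidden` (base that must NOT appear immediately 5' or 3'
#'   of the motif in the read; NA = unconstrained). Guide sequence kept as
#'   an attribute.
#' @export
rbns_site_catalog <- function(guide, windows) {
  guide <- normalize_rna(guide, "guide")
  g <- strsplit(guide, "", fixed = TRUE)[[1]]
  n <- length(g)
  if (!all(c("g_start", "g_end") %in% names(windows))) {
    abort("windows needs columns g_start and g_end")
  }
  windows <- as_tibble(windows)
  if (!"t1" %in% names(windows)) windows$t1 <- NA_character_
  if (!"site" %in% names(windows)) {
    windows$site <- ifelse(is.na(windows$t1),
                           sprintf("g%d-g%d", windows$g_start, windows$g_end),
                           sprintf("g%d-g%d+t1%s", windows$g_start,
                                   windows$g_end, windows$t1))
  }
  if (any(windows$g_start < 1 | windows$g_end > n |
            windows$g_start > windows$g_end)) {
    abort("window outside guide coordinates")
  }
  rows <- pmap(windows[, c("site", "g_start", "g_end", "t1")],
               function(site, g_start, g_end, t1) {
    width <- g_end - g_start + 1L
    # read-sense motif: target runs tEnd..tStart 5'->3'
    motif <- rna_reverse_complement(paste(g[g_start:g_end], collapse = ""))
    t1 <- as.character(t1)
    if (!is.na(t1)) {
      if (g_start != 2L) abort("t1-anchored sites must start at g2")
      motif <- paste0(motif, normalize_rna(t1, "t1"))
      width <- width + 1L
    }
    # flank5 in the read lies opposite g_end + 1; flank3 opposite g_start - 1
    # (or opposite g0 for t1-anchored sites, which is unconstrained).
    flank5 <- NA_character_
    flank3 <- NA_character_
    core_w <- g_end - g_start + 1L
    if (core_w <= 11L && g_end < n) flank5 <- unname(RNA_COMPLEMENT[g[g_end + 1L]])
    if (core_w <= 10L && g_start > 1L && is.na(t1)) {
      flank3 <- unname(RNA_COMPLEMENT[g[g_start - 1L]])
    }
    tibble(site = site, g_start = g_start, g_end = g_end, t1 = t1,
           width = width, motif = motif,
           flank5_forbidden = flank5, flank3_forbidden = flank3)
  })
  out <- list_rbind(rows)
  if (anyDuplicated(out$site)) abort("duplicate site names in catalog")
  structure(out, guide = guide)
}

#' Assign Bind-n-Seq reads to site types
#'
#' A read is assigned to a site type if its sequence (the 20-nt random
#' region plus the four constant nucleotides on each side) contains exactly
#' one catalog motif satisfying the flank rules. Reads with two or more
#' motif occurrences (same or different site types) are rejected; reads with
#' none are classified `"no_site"`.
#'
#' @param reads Character vector of full-layout reads
#'   (`GATC` + 20-nt random region + `TGGA`).
#' @param catalog A [rbns_site_catalog()].
#' @param check_layout Validate the constant-region layout (default TRUE).
#' @return Tibble with columns `read`, `site` (site name, `"no_site"`, or
#'   `"reject"`) and `n_hits`.
#' @export
assign_sites <- function(reads, catalog, check_layout = TRUE) {
  reads <- chartr("T", "U", toupper(reads))
  if (check_layout) {
    ok <- nchar(reads) == 28 & startsWith(reads, "GAUC") & endsWith(reads, "UGGA")
    # reads may arrive as DNA; accept either alphabet for the constant part
    ok_dna <- nchar(reads) == 28 & startsWith(chartr("U", "T", reads), "GATC") &
      endsWith(chartr("U", "T", reads), "TGGA")
    if (!all(ok | ok_dna)) {
      abort("malformed read layout: expected GATC + N20 + TGGA (28 nt)")
    }
  }
  reads <- chartr("T", "U", reads)
  n_reads <- length(reads)
  read_len <- nchar(reads)
  hits <- integer(n_reads)
  label <- rep(NA_character_, n_reads)
  for (k in seq_len(nrow(catalog))) {
    motif <- catalog$motif[k]
    w <- nchar(motif)
    # scan every start position so that overlapping occurrences of a
    # self-overlapping motif are counted separately
    for (s in seq_len(max(read_len) - w + 1L)) {
      match_here <- substring(reads, s, s + w - 1L) == motif
      if (!any(match_here)) next
      ok <- match_here
      if (!is.na(catalog$flank5_forbidden[k]) && s > 1L) {
        ok <- ok & substring(reads, s - 1L, s - 1L) !=
          catalog$flank5_forbidden[k]
      }
      if (!is.na(catalog$flank3_forbidden[k])) {
        e <- s + w - 1L
        flank3 <- substring(reads, e + 1L, e + 1L)
        ok <- ok & (e >= read_len | flank3 != catalog$flank3_forbidden[k])
      }
      hits[ok] <- hits[ok] + 1L
      label[ok] <- catalog$site[k]
    }
  }
  tibble(read = reads,
         site = case_when(hits == 0L ~ "no_site",
                          hits == 1L ~ label,
                          TRUE ~ "reject"),
         n_hits = hits)
}

#' Tabulate site assignments into a site x sample count table
#'
#' @param assignments Tibble with columns `site` and `sample` (one row per
#'   read, e.g. from [assign_sites()] with a sample column added); rejected
#'   reads are dropped.
#' @return Long tibble `site`, `sample`, `count`.
#' @export
rbns_count_table <- function(assignments) {
  assignments |>
    filter(.data$site != "reject") |>
    count(.data$site, .data$sample, name = "count") |>
    tidyr::complete(site = unique(.data$site), sample = unique(.data$sample),
                    fill = list(count = 0L))
}

# Solve free-RISC concentration from total-RISC conservation:
#   E_T = E + sum_i S_i * E / (E + Kd_i),  E in [0, E_T],
# by bisection to relative tolerance 1e-9. Vectorized over samples.
solve_free_risc <- function(e_total, s_conc, kd) {
  lo <- rep(0, length(e_total))
  hi <- e_total
  for (iter in 1:80) {
    mid <- (lo + hi) / 2
    bound <- vapply(mid, function(e) sum(s_conc * e / (e + kd)), numeric(1))
    g <- mid + bound - e_total
    hi <- ifelse(g > 0, mid, hi)
    lo <- ifelse(g > 0, lo, mid)
    if (all(hi - lo <= 1e-9 * pmax(hi, 1e-300))) break
  }
  (lo + hi) / 2
}

rbns_negll <- function(log_par, counts_mat, f_input, s_conc, rel_conc) {
  m <- length(f_input)
  kd <- exp(log_par[seq_len(m)])
  stock <- exp(log_par[m + 1L])
  e_total <- stock * rel_conc
  e_free <- solve_free_risc(e_total, s_conc, kd)
  ll <- 0
  for (j in seq_along(e_total)) {
    theta <- e_free[j] / (e_free[j] + kd)
    p <- f_input * theta
    p <- p / sum(p)
    ll <- ll + sum(counts_mat[, j] * log(pmax(p, 1e-300)))
  }
  -ll
}

# analytic gradient of rbns_negll in the log-parameters, using implicit
# differentiation of the conservation equation for E_free
rbns_negll_grad <- function(log_par, counts_mat, f_input, s_conc, rel_conc) {
  m <- length(f_input)
  kd <- exp(log_par[seq_len(m)])
  stock <- exp(log_par[m + 1L])
  e_total <- stock * rel_conc
  e_free <- solve_free_risc(e_total, s_conc, kd)
  g_kd <- numeric(m)
  g_stock <- 0
  for (j in seq_along(e_total)) {
    e <- e_free[j]
    n_j <- counts_mat[, j]
    nn <- sum(n_j)
    theta <- e / (e + kd)
    p <- f_input * theta
    p <- p / sum(p)
    res <- n_j - nn * p                  # dLL_j / dlog(theta_i)
    denom <- 1 + sum(s_conc * kd / (e + kd)^2)
    de_dkd <- s_conc * e / (e + kd)^2 / denom       # dE/dKd_i
    dlth_de <- kd / (e * (e + kd))                  # dlog(theta_r)/dE
    common <- sum(res * dlth_de)
    # dLL_j/dKd_i = -res_i/(e+kd_i) + common * de_dkd_i
    g_kd <- g_kd + (-res / (e + kd) + common * de_dkd) * kd
    g_stock <- g_stock + common * (e_total[j] / denom)
  }
  -c(g_kd, g_stock)
}

#' Maximum-likelihood dissociation constants from Bind-n-Seq counts
#'
#' Fits the equilibrium binding model: occupancy of site type i at free RISC
#' concentration E is `theta_i = E / (E + Kd_i)`; E solves total-RISC
#' conservation given the library site concentrations; the bound-sample read
#' frequencies are multinomial with probability proportional to
#' `f_input_i * theta_i`. The joint likelihood across the concentration
#' series is maximized over all site Kd values (including a `"no_site"`
#' class with its own Kd) and the stock-concentration scale. Optimization is
#' repeated from the 7 x 7 grid of initial guesses for stock concentration
#' and no-site Kd (0.1, 0.2, 0.5, 1, 2, 5, 10 nM) and the median of the 49
#' estimates is reported per site.
#'
#' @param counts Long tibble `site`, `sample`, `count` containing an
#'   `"input"` sample, a `"no_site"` site class, and one bound sample per
#'   concentration.
#' @param concentrations_nm Named numeric vector: bound-sample name ->
#'   nominal RISC concentration (nM). Defaults to the six-point series
#'   0.003-1 nM with sample names `bound_<conc>`.
#' @param lib_conc_nm Total library RNA concentration (nM) used to convert
#'   input frequencies into site concentrations.
#' @param guess_grid_nm Initial-guess grid (nM) for stock concentration and
#'   no-site Kd.
#' @param max_site_width Sites of this width (nt) or more are excluded from
#'   fitting (long sites can be sliced when cleavage is not blocked);
#'   requires a `width` column in `counts` to take effect.
#' @return A `piwikit_kd_fit` object: tibble with one row per site
#'   (`site`, `kd_pm`, `n_starts`, `n_converged`, `flagged`), with the
#'   per-start estimate matrix in attribute `starts`.
#' @export
fit_kd_mle <- function(counts,
                       concentrations_nm = setNames(
                         RBNS_CONCENTRATIONS_NM,
                         paste0("bound_", RBNS_CONCENTRATIONS_NM)),
                       lib_conc_nm = 100,
                       guess_grid_nm = c(0.1, 0.2, 0.5, 1, 2, 5, 10),
                       max_site_width = 15) {
  stopifnot(all(c("site", "sample", "count") %in% names(counts)))
  if (!"input" %in% counts$sample) abort("counts must contain an 'input' sample")
  if (!"no_site" %in% counts$site) abort("counts must contain a 'no_site' class")
  if ("width" %in% names(counts)) {
    wide_sites <- unique(counts$site[!is.na(counts$width) &
                                       counts$width >= max_site_width])
    if (length(wide_sites)) {
      warn(sprintf("excluding %d site(s) of width >= %d nt from Kd fitting: %s",
                   length(wide_sites), max_site_width,
                   paste(wide_sites, collapse = ", ")))
      counts <- filter(counts, !.data$site %in% wide_sites)
    }
  }
  wide <- counts |>
    select("site", "sample", "count") |>
    pivot_wider(names_from = "sample", values_from = "count", values_fill = 0L)
  absent <- wide$site[wide$input == 0]
  if (length(absent)) {
    warn(sprintf("site(s) absent from input excluded: %s",
                 paste(absent, collapse = ", ")))
    wide <- filter(wide, .data$input > 0)
  }
  bound_names <- names(concentrations_nm)
  if (!all(bound_names %in% names(wide))) {
    abort("bound sample columns missing from counts")
  }
  sites <- wide$site
  m <- length(sites)
  f_input <- wide$input / sum(wide$input)
  s_conc <- f_input * lib_conc_nm
  counts_mat <- as.matrix(wide[, bound_names])
  rel_conc <- unname(concentrations_nm) / max(concentrations_nm)
  i_nosite <- match("no_site", sites)

  grid <- crossing(stock0 = guess_grid_nm, kd_ns0 = guess_grid_nm)
  lower <- c(rep(log(1e-7), m), log(1e-4))
  upper <- c(rep(log(1e4), m), log(1e3))
  run_start <- function(stock0, kd_ns0) {
    kd0 <- rep(1, m)
    kd0[i_nosite] <- kd_ns0
    par0 <- c(log(kd0), log(stock0))
    fit <- tryCatch(
      optim(par0, rbns_negll, rbns_negll_grad, method = "L-BFGS-B",
            lower = lower, upper = upper,
            counts_mat = counts_mat, f_input = f_input,
            s_conc = s_conc, rel_conc = rel_conc,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) return(rep(NA_real_, m + 2L))
    pinned <- any(abs(fit$par - lower) < 1e-8) || any(abs(fit$par - upper) < 1e-8)
    c(exp(fit$par), as.numeric(fit$convergence == 0 && !pinned))
  }
  est <- t(mapply(run_start, grid$stock0, grid$kd_ns0))
  conv <- est[, m + 2L] == 1 & !is.na(est[, 1])
  kd_nm <- est[, seq_len(m), drop = FALSE]

  use <- if (any(conv)) conv else !is.na(est[, 1])
  med_kd <- apply(kd_nm[use, , drop = FALSE], 2, median)
  out <- tibble(site = sites,
                kd_pm = med_kd * 1000,
                n_starts = nrow(grid),
                n_converged = sum(conv),
                flagged = sum(conv) <= nrow(grid) / 2)
  structure(out, class = c("piwikit_kd_fit", class(out)),
            starts = kd_nm, stock_nm = est[, m + 1L], converged = conv,
            lib_conc_nm = lib_conc_nm)
}

#' Closed-form fraction bound in a double-filter binding assay
#'
#' Solution of the binding quadratic under total-concentration bookkeeping:
#' `f = ((E_T + S_T + Kd) - sqrt((E_T + S_T + Kd)^2 - 4 E_T S_T)) / (2 S_T)`.
#'
#' @param e_total Total RISC concentration(s).
#' @param s_total Total target concentration (same units).
#' @param kd Dissociation constant (same units).
#' @return Fraction of target bound, in \[0, 1\].
#' @export
filter_binding_fraction <- function(e_total, s_total, kd) {
  a <- e_total + s_total + kd
  (a - sqrt(pmax(a^2 - 4 * e_total * s_total, 0))) / (2 * s_total)
}

#' Fit a dissociation constant to double-filter binding data
#'
#' Least-squares fit of the closed-form binding quadratic
#' ([filter_binding_fraction()]) to fraction-bound measurements over a RISC
#' titration, with the total target concentration known.
#'
#' @param e_total RISC concentrations (any consistent unit).
#' @param fraction_bound Measured fraction bound, in \[0, 1\].
#' @param s_total Total target concentration (same unit as `e_total`).
#' @return One-row tibble: `kd`, `kd_se`, `converged`, `flagged`
#'   (TRUE when the data show no binding transition).
#' @export
fit_filter_binding <- function(e_total, fraction_bound, s_total) {
  stopifnot(length(e_total) == length(fraction_bound))
  if (any(fraction_bound < -0.05 | fraction_bound > 1.05)) {
    abort("fraction_bound must lie in [0, 1]")
  }
  flat <- diff(range(fraction_bound)) < 0.1
  kd0 <- {
    i <- which.min(abs(fraction_bound - 0.5))
    max(e_total[i], max(e_total) * 1e-4)
  }
  dat <- tibble(e = e_total, f = fraction_bound)
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ filter_binding_fraction(e, s_total, kd),
                      data = dat, start = list(kd = kd0),
                      lower = 0, upper = max(e_total) * 1e4,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(tibble(kd = NA_real_, kd_se = NA_real_,
                  converged = FALSE, flagged = TRUE))
  }
  sm <- summary(fit)$coefficients
  tibble(kd = unname(coef(fit)["kd"]), kd_se = sm["kd", "Std. Error"],
         converged = TRUE, flagged = flat)
}

#' Linear regression of measured against predicted binding energies
#'
#' Ordinary least-squares r-squared plus a two-tailed permutation P value
#' for the Pearson correlation (labels of one vector permuted).
#'
#' @param observed Numeric vector (e.g. Kd-derived binding energies).
#' @param predicted Numeric vector of the same length (e.g. predicted
#'   nearest-neighbour energies).
#' @param n_perm Number of permutations.
#' @return One-row tibble: `r2`, `pearson_r`, `p_perm`, `n`, `flagged`
#'   (TRUE when the correlation is undefined).
#' @export
energy_regression <- function(observed, predicted, n_perm = 10000) {
  keep <- complete.cases(observed, predicted)
  x <- predicted[keep]; y <- observed[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(r2 = NA_real_, pearson_r = NA_real_, p_perm = NA_real_,
                  n = n, flagged = TRUE))
  }
  r_obs <- cor(x, y)
  r_perm <- vapply(seq_len(n_perm), function(i) cor(x, sample(y)), numeric(1))
  p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  # for simple OLS the coefficient of determination equals r^2
  tibble(r2 = r_obs^2, pearson_r = r_obs,
         p_perm = p, n = n, flagged = FALSE)
}

#' @export
tidy.piwikit_kd_fit <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.piwikit_kd_fit <- function(x, ...) {
  tibble(n_sites = nrow(x),
         n_starts = x$n_starts[1],
         n_converged = x$n_converged[1],
         stock_nm = median(attr(x, "stock_nm")[attr(x, "converged")],
                           na.rm = TRUE),
         lib_conc_nm = attr(x, "lib_conc_nm"))
}
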