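# Cleave-n-Seq analysis: time-course depletion of a designed target-variant
# library -> per-variant pre-steady-state cleavage rates.

#' Standard CNS sampling timepoints (minutes)
#' @export
CNS_TIMEPOINTS_FAST <- c(0, 1, 2, 4, 8)

#' @rdname CNS_TIMEPOINTS_FAST
#' @export
CNS_TIMEPOINTS_SLOW <- c(0, 20, 60, 120, 240, 480, 960)

#' Depth- and decay-normalize a CNS count table
#'
#' Counts are first scaled to ppm within each sample (timepoint x trial),
#' then each ppm value is divided by the summed ppm of the normalizer
#' variants of that sample (targets with at most 7 nt complementarity to
#' the guide, which are not cleaved and so track the total library amount
#' over the reaction).
#'
#' @param counts Tibble with columns `variant_id`, `timepoint_min`, `trial`,
#'   `count`.
#' @param normalizer_ids Character vector of normalizer variant ids.
#' @return Input tibble plus columns `ppm` and `abundance` (normalizer-
#'   scaled ppm).
#' @export
normalize_library <- function(counts, normalizer_ids) {
  stopifnot(all(c("variant_id", "timepoint_min", "trial", "count")
                %in% names(counts)))
  if (length(normalizer_ids) == 0 ||
        !any(counts$variant_id %in% normalizer_ids)) {
    abort("normalizer set (<= 7 nt complementarity variants) is empty")
  }
  counts |>
    group_by(.data$timepoint_min, .data$trial) |>
    mutate(ppm = .data$count / sum(.data$count) * 1e6,
           abundance = .data$ppm /
             sum(.data$ppm[.data$variant_id %in% normalizer_ids])) |>
    ungroup()
}

#' Relative cleaved product per variant, timepoint and trial
#'
#' `P_relative = (abundance_0min - abundance_t) / abundance_0min`. Negative
#' values (sampling noise around slow rates) are retained for fitting.
#'
#' @param tc A normalized time course from [normalize_library()] (uses the
#'   `abundance` column, falling back to `ppm`).
#' @return Tibble `variant_id`, `trial`, `timepoint_min`, `p_relative`,
#'   `quantifiable` (FALSE when the time-0 abundance is zero).
#' @export
compute_p_relative <- function(tc) {
  value_col <- if ("abundance" %in% names(tc)) "abundance" else "ppm"
  tc |>
    group_by(.data$variant_id, .data$trial) |>
    mutate(.a0 = .data[[value_col]][.data$timepoint_min == 0][1]) |>
    ungroup() |>
    filter(.data$timepoint_min > 0) |>
    mutate(p_relative = ifelse(.data$.a0 > 0,
                               (.data$.a0 - .data[[value_col]]) / .data$.a0,
                               NA_real_),
           quantifiable = .data$.a0 > 0) |>
    select("variant_id", "trial", "timepoint_min", "p_relative",
           "quantifiable")
}

#' Burst-and-steady-state cleavage curve
#'
#' Relative cleaved product for the scheme E+S <-> ES -> EP -> E+P:
#' `f(t) = E_rel * ((k2/(k2+k3))^2 (1 - exp(-(k2+k3) t)) + (k2 k3/(k2+k3)) t)`.
#' The amplitude `E_rel` is applied once.
#'
#' @param t Time (minutes).
#' @param e_relative Burst amplitude (fraction of active complex), in
#'   \[0.5, 1\].
#' @param k2 Cleavage rate constant (min^-1).
#' @param k3 Product-release rate constant (min^-1).
#' @return Relative cleaved product.
#' @export
burst_fraction <- function(t, e_relative, k2, k3 = 0) {
  n <- max(length(t), length(e_relative), length(k2), length(k3))
  t <- rep_len(t, n)
  e_relative <- rep_len(e_relative, n)
  k2 <- rep_len(k2, n)
  k3 <- rep_len(k3, n)
  ks <- k2 + k3
  ks_safe <- ifelse(ks <= 0, 1, ks)
  ifelse(ks <= 0, 0,
         e_relative * ((k2 / ks_safe)^2 * (1 - exp(-ks_safe * t)) +
                         (k2 * k3 / ks_safe) * t))
}

#' Fit the burst-and-steady-state model to pooled P_relative data
#'
#' Bounded Levenberg-Marquardt least squares (at most 10,000 function
#' evaluations) with the physical constraints 0.5 <= E_relative <= 1,
#' 0 <= k2 <= 100 min^-1, 0 <= k3 <= 1e-4 min^-1 (single-turnover regime).
#' Trials are pooled as independent observations. The pre-steady-state
#' cleavage rate is reported as k = k2 + k3; parameter standard deviations
#' come from the fit covariance.
#'
#' @param time_min Timepoints (minutes), non-zero.
#' @param p_relative Relative cleaved product at those timepoints.
#' @return A `piwikit_burst_fit`: one-row tibble with `e_relative`, `k2`,
#'   `k3`, `k`, standard errors, `converged`, `flagged`, `flag_reason`,
#'   `n_obs`.
#' @export
fit_burst <- function(time_min, p_relative) {
  keep <- is.finite(time_min) & is.finite(p_relative) & time_min > 0
  t <- time_min[keep]; p <- p_relative[keep]
  res <- tibble(e_relative = NA_real_, k2 = NA_real_, k3 = NA_real_,
                k = NA_real_, e_se = NA_real_, k2_se = NA_real_,
                k3_se = NA_real_, k_se = NA_real_,
                converged = FALSE, flagged = TRUE,
                flag_reason = NA_character_, n_obs = length(p))
  if (length(unique(t)) < 4) {
    res$flag_reason <- "fewer than 4 distinct nonzero timepoints"
    return(structure(res, class = c("piwikit_burst_fit", class(res)),
                     data = tibble(time_min = t, p_relative = p)))
  }
  if (all(abs(p) < 1e-12)) {
    res$k2 <- 0; res$k3 <- 0; res$k <- 0
    res$flag_reason <- "no signal: k at lower bound, amplitude unidentifiable"
    return(structure(res, class = c("piwikit_burst_fit", class(res)),
                     data = tibble(time_min = t, p_relative = p)))
  }
  p_hi <- max(p)
  e0 <- min(max(p_hi, 0.5), 1)
  t_half <- t[which.min(abs(p - p_hi / 2))]
  k_starts <- unique(c(log(2) / max(t_half, min(t)), 10^seq(-3, 1)))
  dat <- tibble(t = t, p = p)
  best <- NULL
  for (k0 in k_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        p ~ burst_fraction(t, e_relative, k2, k3),
        data = dat,
        start = list(e_relative = e0, k2 = min(max(k0, 1e-6), 100), k3 = 1e-6),
        lower = c(0.5, 0, 0), upper = c(1, 100, 1e-4),
        control = minpack.lm::nls.lm.control(maxfev = 10000, maxiter = 1000)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    res$flag_reason <- if (diff(range(p)) < 0.05 && mean(p) > 0.45) {
      "fast phase unidentifiable: all timepoints saturated"
    } else "optimizer failed from all starts"
    return(structure(res, class = c("piwikit_burst_fit", class(res)),
                     data = tibble(time_min = t, p_relative = p)))
  }
  fit <- best$fit
  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  k <- unname(cf["k2"] + cf["k3"])
  k_var <- vc[2, 2] + vc[3, 3] + 2 * vc[2, 3]
  flag_reason <- NA_character_
  # fast phase unresolvable when even the earliest sample is saturated
  if (k > 0 && (1 - exp(-k * min(t))) > 0.99) {
    flag_reason <- "fast phase unidentifiable: all timepoints saturated"
  }
  if (abs(cf["k2"] - 100) < 1e-6) {
    flag_reason <- "k2 pinned at upper bound"
  }
  res <- tibble(e_relative = unname(cf["e_relative"]), k2 = unname(cf["k2"]),
                k3 = unname(cf["k3"]), k = k,
                e_se = sqrt(vc[1, 1]), k2_se = sqrt(vc[2, 2]),
                k3_se = sqrt(vc[3, 3]),
                k_se = sqrt(pmax(k_var, 0)),
                converged = TRUE, flagged = !is.na(flag_reason),
                flag_reason = flag_reason, n_obs = length(p))
  structure(res, class = c("piwikit_burst_fit", class(res)),
            data = tibble(time_min = t, p_relative = p))
}

#' Fit burst kinetics for every variant of a P_relative table
#'
#' @param p_rel Output of [compute_p_relative()] (or any tibble with
#'   `variant_id`, `timepoint_min`, `p_relative`).
#' @return Tibble with one row per variant: the [fit_burst()] columns.
#' @export
fit_burst_rates <- function(p_rel) {
  if ("quantifiable" %in% names(p_rel)) {
    p_rel <- filter(p_rel, .data$quantifiable)
  }
  p_rel |>
    group_by(.data$variant_id) |>
    group_modify(function(d, key) {
      as_tibble(fit_burst(d$timepoint_min, d$p_relative))
    }) |>
    ungroup()
}

#' Per-variant fold change in cleavage rate versus the perfect site
#'
#' `fold_change = k_perfect / k_variant`, where the perfect-match reference
#' is taken from the same guide/protein combination.
#'
#' @param fits Tibble of rate fits with columns `variant_id`, `k`, plus any
#'   of `match_cols`.
#' @param perfect_id `variant_id` of the perfectly paired reference.
#' @param match_cols Columns identifying the library/guide/protein run the
#'   reference must share (defaults to those of `c("guide", "protein")`
#'   present in `fits`).
#' @return `fits` plus columns `k_perfect` and `fold_change`.
#' @export
fold_changes <- function(fits, perfect_id = "perfect",
                         match_cols = intersect(c("guide", "protein"),
                                                names(fits))) {
  ref <- fits |>
    filter(.data$variant_id == perfect_id) |>
    select(all_of(match_cols), k_perfect = "k")
  if (nrow(ref) == 0) abort("missing perfect-match reference fit")
  out <- if (length(match_cols)) {
    left_join(fits, ref, by = match_cols)
  } else {
    mutate(fits, k_perfect = ref$k_perfect[1])
  }
  if (any(is.na(out$k_perfect))) {
    abort("missing perfect reference for some guide/protein combinations")
  }
  mutate(out, fold_change = .data$k_perfect / .data$k)
}

#' Median and IQR of rate fold changes over a grouping
#'
#' @param fits Rate fits (see [fold_changes()]).
#' @param ... Grouping columns (e.g. mismatch position, geometry).
#' @inheritParams fold_changes
#' @return Tibble with `median_fold`, `q25`, `q75`, `n` per group.
#' @export
fold_change_summary <- function(fits, ..., perfect_id = "perfect",
                                match_cols = intersect(c("guide", "protein"),
                                                       names(fits))) {
  fold_changes(fits, perfect_id, match_cols) |>
    filter(.data$variant_id != perfect_id) |>
    group_by(...) |>
    summarize(median_fold = median(.data$fold_change),
              q25 = quantile(.data$fold_change, 0.25),
              q75 = quantile(.data$fold_change, 0.75),
              n = dplyr::n(), .groups = "drop")
}

#' Map cleavage positions from sequenced 3' products
#'
#' Each read is matched to its library variant through the 8-nt barcode and
#' its 5' end located within the variant sequence; the offset is reported
#' relative to t10 (offset 0 = canonical scissile bond between t10 and
#' t11). Spiked synthetic 5'-monophosphorylated control oligos can be
#' included as library rows with `t10_index` equal to 0 so that intact
#' controls report offset 0 (negative offsets then flag non-templated
#' additions, positive offsets exonucleolytic trimming).
#'
#' @param product_reads Tibble with columns `read` (product sequence,
#'   5'->3') and `barcode`.
#' @param library Tibble with columns `variant_id`, `sequence`, `barcode`,
#'   `t10_index` (0-based index of t10 in `sequence`).
#' @param min_match Minimum prefix length used to locate the product
#'   (defaults to the full read, capped at 12).
#' @return Tibble `variant_id`, `offset`, `n`, `fraction` (per-variant
#'   histogram of product 5'-end offsets relative to t10); unmatched reads
#'   appear with `offset = NA`.
#' @export
map_cut_sites <- function(product_reads, library, min_match = 12) {
  if (anyDuplicated(library$barcode)) abort("barcode collision in library")
  reads <- product_reads |>
    mutate(read = chartr("T", "U", toupper(.data$read))) |>
    left_join(library |>
                mutate(sequence = chartr("T", "U", toupper(.data$sequence))) |>
                select("variant_id", "barcode", "sequence", "t10_index"),
              by = "barcode")
  if (any(is.na(reads$variant_id))) {
    warn(sprintf("%d read(s) with unknown barcode dropped",
                 sum(is.na(reads$variant_id))))
    reads <- filter(reads, !is.na(.data$variant_id))
  }
  reads <- reads |>
    mutate(query = str_sub(.data$read, 1,
                           pmin(str_length(.data$read), pmax(min_match, 12))),
           hit = mapply(function(q, s) regexpr(q, s, fixed = TRUE)[1],
                        .data$query, .data$sequence, USE.NAMES = FALSE),
           offset = ifelse(.data$hit > 0,
                           .data$hit - 1L - .data$t10_index, NA_integer_))
  reads |>
    count(.data$variant_id, .data$offset, name = "n") |>
    group_by(.data$variant_id) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
}

#' @export
tidy.piwikit_burst_fit <- function(x, ...) {
  tibble(term = c("e_relative", "k2", "k3", "k"),
         estimate = c(x$e_relative, x$k2, x$k3, x$k),
         std.error = c(x$e_se, x$k2_se, x$k3_se, x$k_se))
}

#' @export
glance.piwikit_burst_fit <- function(x, ...) {
  tibble(k = x$k, converged = x$converged, flagged = x$flagged,
         flag_reason = x$flag_reason, n_obs = x$n_obs)
}
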