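# The 35-feature logistic decision function for in vivo cleavage, its
# 16 x 5 x 5 = 400-model ensemble fitting scheme, and precision-recall
# evaluation.
#
# Objective (defined explicitly): with class-balanced observation weights
# w_i = n / (2 * n_class(y_i)) (inversely proportional to class
# frequencies, averaging 1) and ridge weight lambda, minimize
#   sum_i w_i * logloss_i  +  lambda/2 * ||beta||^2,
# the intercept unpenalized, matching the convention of the standard
# penalized-logistic implementations in which lambda = 1 is the default.
# Optimized with L-BFGS-B, at most 1,000 iterations.

LOGIT_FEATURES <- c(paste0("x", 1:35))

#' Build the 35-feature vectors for the cleavage decision function
#'
#' Features: x1-x24 = presence of pairing to g2-g25; x25 = total paired
#' nucleotides between g2 and g25 rescaled to \[0,1\]; x26 = piRNA
#' abundance rescaled to \[0,1\]; x27 = negative predicted pairing energy
#' rescaled to \[0,1\]; x28-x31 = t1 identity indicators (A, U, C, G);
#' x32-x34 = region indicators (5' UTR, ORF, 3' UTR); x35 = lncRNA
#' indicator. Inclusion filter: at least 19 paired nucleotides between g2
#' and g25, abundance at least 0.1 ppm, and no target insertions or
#' deletions in the pairing.
#'
#' @param data Tibble with one row per piRNA-site pair: `pairing` (compact
#'   pairing string over the guide, see [pairing_string()]),
#'   `abundance_ppm`, `delta_g0` (kcal/mol), `t1` (A/U/C/G), `region`
#'   (`"5utr"`, `"orf"`, `"3utr"` or `"none"`), `lncrna` (logical),
#'   `cleaved` (0/1 label).
#' @param min_paired Inclusion threshold on paired nucleotides g2-g25.
#' @param min_abundance_ppm Inclusion threshold on piRNA abundance.
#' @param rescale Min-max rescale x25-x27 on the included set (the
#'   ensemble fitter redoes this per training fold from the raw columns).
#' @return Tibble with columns `x1`..`x35`, `cleaved`, and raw columns
#'   `.paired_total`, `.abundance`, `.neg_dg` used for per-fold rescaling.
#'   Excluded rows are dropped; the reason tally is in attribute
#'   `excluded`.
#' @export
build_features <- function(data, min_paired = 19, min_abundance_ppm = 0.1,
                           rescale = TRUE) {
  req <- c("pairing", "abundance_ppm", "delta_g0", "t1", "region", "lncrna",
           "cleaved")
  stopifnot(all(req %in% names(data)))
  parsed <- map(data$pairing, parse_pairing_string)
  has_indel <- vapply(parsed, function(p) {
    any(p$state == "guide_bulge") || length(attr(p, "insertions")) > 0
  }, logical(1))
  paired_vec <- map(parsed, function(p) p$state %in% c("wc", "gu"))
  paired_g2_g25 <- vapply(paired_vec, function(v) {
    idx <- 2:min(25, length(v))
    sum(v[idx])
  }, numeric(1))
  keep <- !has_indel & paired_g2_g25 >= min_paired &
    data$abundance_ppm >= min_abundance_ppm
  excluded <- c(indel = sum(has_indel),
                under_paired = sum(!has_indel & paired_g2_g25 < min_paired),
                low_abundance = sum(!has_indel & paired_g2_g25 >= min_paired &
                                      data$abundance_ppm < min_abundance_ppm))
  data <- data[keep, , drop = FALSE]
  paired_vec <- paired_vec[keep]
  paired_g2_g25 <- paired_g2_g25[keep]

  pos <- t(vapply(paired_vec, function(v) {
    out <- numeric(24)
    idx <- 2:min(25, length(v))
    out[idx - 1L] <- as.numeric(v[idx])
    out
  }, numeric(24)))
  colnames(pos) <- paste0("x", 1:24)

  minmax <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
  }
  neg_dg <- -data$delta_g0
  out <- as_tibble(pos) |>
    mutate(x25 = if (rescale) minmax(paired_g2_g25) else paired_g2_g25,
           x26 = if (rescale) minmax(data$abundance_ppm) else data$abundance_ppm,
           x27 = if (rescale) minmax(neg_dg) else neg_dg,
           x28 = as.numeric(data$t1 == "A"),
           x29 = as.numeric(data$t1 == "U"),
           x30 = as.numeric(data$t1 == "C"),
           x31 = as.numeric(data$t1 == "G"),
           x32 = as.numeric(data$region == "5utr"),
           x33 = as.numeric(data$region == "orf"),
           x34 = as.numeric(data$region == "3utr"),
           x35 = as.numeric(data$lncrna),
           cleaved = as.numeric(data$cleaved),
           .paired_total = paired_g2_g25,
           .abundance = data$abundance_ppm,
           .neg_dg = neg_dg)
  structure(out, excluded = excluded)
}

#' Ridge-penalized, class-weighted logistic regression
#'
#' @param x Numeric feature matrix (no intercept column).
#' @param y 0/1 labels.
#' @param lambda Ridge penalty weight (default 1).
#' @param balanced Use class weights inversely proportional to class
#'   frequencies (default TRUE).
#' @param maxit Maximum L-BFGS-B iterations (default 1000).
#' @return List: `beta0`, `beta` (named by column), `converged`, `value`.
#' @export
fit_logistic <- function(x, y, lambda = 1, balanced = TRUE, maxit = 1000) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (length(unique(y)) < 2) abort("both classes must be present to fit")
  w <- if (balanced) {
    tab <- table(factor(y, levels = c(0, 1)))
    unname((n / (2 * tab))[as.character(y)])
  } else rep(1, n)
  obj <- function(par) {
    eta <- par[1] + drop(x %*% par[-1])
    # numerically stable weighted log-loss
    ll <- sum(w * (log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta))
    ll + lambda / 2 * sum(par[-1]^2)
  }
  grad <- function(par) {
    eta <- par[1] + drop(x %*% par[-1])
    pr <- 1 / (1 + exp(-eta))
    r <- w * (pr - y)
    c(sum(r), drop(crossprod(x, r)) + lambda * par[-1])
  }
  fit <- optim(rep(0, p + 1), obj, grad, method = "L-BFGS-B",
               control = list(maxit = maxit))
  list(beta0 = fit$par[1],
       beta = setNames(fit$par[-1], colnames(x)),
       converged = fit$convergence == 0,
       value = fit$value)
}

predict_logistic <- function(model, x) {
  eta <- model$beta0 + drop(as.matrix(x) %*% model$beta)
  1 / (1 + exp(-eta))
}

# stratified k-fold assignment; errors if a class has fewer members than k
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    if (length(idx) < k) abort("class smaller than the number of folds")
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# per-fold min-max scaling of x25-x27 learned on train, applied clipped
fold_scaling <- function(feat) {
  list(paired = range(feat$.paired_total),
       abundance = range(feat$.abundance),
       neg_dg = range(feat$.neg_dg))
}

apply_scaling <- function(feat, sc) {
  mm <- function(v, r) {
    if (r[1] == r[2]) rep(0, length(v))
    else pmin(pmax((v - r[1]) / (r[2] - r[1]), 0), 1)
  }
  feat$x25 <- mm(feat$.paired_total, sc$paired)
  feat$x26 <- mm(feat$.abundance, sc$abundance)
  feat$x27 <- mm(feat$.neg_dg, sc$neg_dg)
  feat
}

#' Fit the 400-model logistic ensemble
#'
#' For each of 16 replicate pairings (permutations), 5-times repeated
#' stratified 5-fold cross-validation yields 25 fits, for 16 x 25 = 400
#' models. Per fit, x25-x27 are min-max rescaled on the training portion
#' (test values clipped to \[0,1\]), the penalized weighted logistic
#' objective is optimized, and the precision-recall AUC is evaluated on
#' the held-out fold.
#'
#' @param features Output of [build_features()]; either one tibble (labels
#'   shared by all permutations) or a tibble with a `permutation` column
#'   (1..`n_permutations`) carrying per-pairing labels.
#' @param n_permutations,n_repeats,n_folds Ensemble dimensions (defaults
#'   16, 5, 5).
#' @param lambda Ridge penalty (default 1).
#' @param seed Integer seed; fold assignments are seeded per
#'   (permutation, repeat).
#' @return A `piwikit_ensemble`: tibble with one row per model
#'   (`permutation`, `rep`, `fold`, `pr_auc`, `converged`, `beta0`,
#'   `b_x1`..`b_x35`), scalings stored in attribute `scalings`.
#' @export
fit_cleavage_ensemble <- function(features, n_permutations = 16,
                                  n_repeats = 5, n_folds = 5, lambda = 1,
                                  seed = 1) {
  per_perm <- "permutation" %in% names(features)
  if (per_perm) {
    stopifnot(all(sort(unique(features$permutation)) ==
                    seq_len(n_permutations)))
  }
  rows <- list()
  scalings <- list()
  mi <- 0L
  for (perm in seq_len(n_permutations)) {
    feat <- if (per_perm) {
      filter(features, .data$permutation == perm)
    } else features
    y <- feat$cleaved
    for (rep_i in seq_len(n_repeats)) {
      set.seed(seed * 100003L + perm * 1009L + rep_i)
      fold <- stratified_folds(y, n_folds)
      for (fo in seq_len(n_folds)) {
        tr <- feat[fold != fo, , drop = FALSE]
        te <- feat[fold == fo, , drop = FALSE]
        sc <- fold_scaling(tr)
        tr <- apply_scaling(tr, sc)
        te <- apply_scaling(te, sc)
        m <- fit_logistic(as.matrix(tr[, LOGIT_FEATURES]), tr$cleaved,
                          lambda = lambda)
        auc <- if (any(te$cleaved == 1)) {
          pr_auc(predict_logistic(m, te[, LOGIT_FEATURES]), te$cleaved)
        } else NA_real_
        mi <- mi + 1L
        scalings[[mi]] <- sc
        rows[[mi]] <- tibble(permutation = perm, rep = rep_i, fold = fo,
                             pr_auc = auc, converged = m$converged,
                             beta0 = m$beta0,
                             !!!setNames(as.list(m$beta),
                                         paste0("b_", LOGIT_FEATURES)))
      }
    }
  }
  out <- list_rbind(rows)
  structure(out, class = c("piwikit_ensemble", class(out)),
            scalings = scalings, lambda = lambda, seed = seed)
}

#' Area under the precision-recall curve
#'
#' Observations are ranked by decreasing score (ties broken by stable
#' original order); from the anchor point (recall 0, precision 1) the
#' curve (recall_k, precision_k) over all ranks k is integrated by the
#' trapezoid rule.
#'
#' @param scores Predicted scores.
#' @param labels 0/1 labels; must contain at least one positive.
#' @return Scalar AUC.
#' @export
pr_auc <- function(scores, labels) {
  if (!any(labels == 1)) abort("PR-AUC undefined without positives")
  ord <- order(-scores)  # stable in R
  y <- labels[ord]
  tp <- cumsum(y)
  k <- seq_along(y)
  recall <- c(0, tp / sum(y))
  precision <- c(1, tp / k)
  sum(diff(recall) * (head(precision, -1) + tail(precision, -1)) / 2)
}

#' Evaluate an ensemble on an independent cohort
#'
#' Applies each model (with its own training scaling) to the new feature
#' set and reports per-model PR-AUC. If `features` carries a `permutation`
#' column, every model is evaluated against every permutation of the new
#' cohort (giving `n_models x n_permutations` values).
#'
#' @param ensemble A [fit_cleavage_ensemble()] result.
#' @param features New cohort features from [build_features()].
#' @return Tibble `permutation`, `rep`, `fold`, `test_permutation`,
#'   `pr_auc`.
#' @export
evaluate_pr_auc <- function(ensemble, features) {
  scalings <- attr(ensemble, "scalings")
  test_sets <- if ("permutation" %in% names(features)) {
    split(features, features$permutation)
  } else list(`1` = features)
  rows <- imap(test_sets, function(te, tp) {
    map(seq_len(nrow(ensemble)), function(i) {
      sc <- scalings[[i]]
      te2 <- apply_scaling(te, sc)
      beta <- unlist(ensemble[i, paste0("b_", LOGIT_FEATURES)])
      eta <- ensemble$beta0[i] +
        drop(as.matrix(te2[, LOGIT_FEATURES]) %*% beta)
      auc <- if (any(te2$cleaved == 1)) {
        pr_auc(1 / (1 + exp(-eta)), te2$cleaved)
      } else NA_real_
      tibble(permutation = ensemble$permutation[i], rep = ensemble$rep[i],
             fold = ensemble$fold[i],
             test_permutation = as.integer(tp), pr_auc = auc)
    }) |> list_rbind()
  })
  list_rbind(rows)
}

#' Median and IQR of ensemble coefficients per feature
#'
#' @param ensemble A [fit_cleavage_ensemble()] result.
#' @return Tibble `feature`, `median`, `q25`, `q75`.
#' @export
coefficient_summary <- function(ensemble) {
  tidy(ensemble) |>
    group_by(.data$feature) |>
    summarize(median = median(.data$estimate),
              q25 = quantile(.data$estimate, 0.25),
              q75 = quantile(.data$estimate, 0.75), .groups = "drop")
}

#' @export
tidy.piwikit_ensemble <- function(x, ...) {
  as_tibble(x) |>
    pivot_longer(cols = all_of(c("beta0", paste0("b_", LOGIT_FEATURES))),
                 names_to = "feature", values_to = "estimate") |>
    mutate(feature = sub("^b_", "", .data$feature))
}

#' @export
glance.piwikit_ensemble <- function(x, ...) {
  tibble(n_models = nrow(x),
         n_permutations = length(unique(x$permutation)),
         median_pr_auc = median(x$pr_auc, na.rm = TRUE),
         lambda = attr(x, "lambda"))
}
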