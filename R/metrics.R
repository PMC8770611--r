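#' Area under the ROC curve
#'
#' Rank-based AUROC with mid-rank handling of tied scores; equal to the
#' normalized Mann-Whitney U statistic, i.e. the probability that a
#' random presence is scored above a random absence.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric prediction scores (higher = more likely present).
#' @return Scalar in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUROC undefined: both classes must be present.")
  }
  r <- rank(scores) # mid-ranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Computed by the interpolation-free average-precision summation:
#' `sum_k (R_k - R_(k-1)) * P_k` over the distinct score thresholds in
#' decreasing order, where `R` and `P` are recall and precision. Tied
#' scores are handled as one threshold group, so a constant-score
#' classifier scores exactly the prevalence (the random-classifier
#' baseline). Trapezoidal interpolation in PR space is deliberately
#' avoided (it overestimates the area).
#'
#' @inheritParams auroc
#' @return Scalar in `(0, 1]`.
#' @export
auprc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  P <- sum(labels == 1)
  if (P == 0) abort("AUPRC undefined: no positive labels.")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  # group boundaries at distinct scores
  last <- cumsum(rle(sc)$lengths)
  tp <- cumsum(lab)[last]
  fp <- cumsum(1 - lab)[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' AUPRC relative to the prevalence baseline
#'
#' The prevalence of a species equals the AUPRC of a random classifier,
#' so this ratio says how many times better than random the model
#' predicts that species.
#'
#' @inheritParams auroc
#' @return Scalar ratio (about 1 for random scores).
#' @export
auprc_prevalence_ratio <- function(labels, scores) {
  auprc(labels, scores) / mean(labels == 1)
}

#' Moran's I with a permutation test
#'
#' Spatial autocorrelation of per-plot residuals:
#' `I = (N / W) * sum_uv(w_uv r_u r_v) / sum_u(r_u^2)` on centred
#' residuals `r`, with expected value `-1/(N-1)` under independence. The
#' p-value comes from random permutations of the residuals over the
#' plots (seeded, 999 by default), with a one-sided "greater" alternative
#' by default since the diagnostic guards against positive spatial
#' autocorrelation among nearby plots.
#'
#' @param residuals Numeric vector, one value per plot.
#' @param coordinates Two-column matrix/data frame of plot x, y (metres).
#' @param weights `"inverse_distance"` (row-standardized, zero diagonal)
#'   or `"knn"` (binary k-nearest-neighbour, row-standardized).
#' @param k Number of neighbours when `weights = "knn"`.
#' @param n_perm Number of permutations.
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`.
#' @param seed RNG seed for the permutations.
#' @return A tibble with `I`, `expected_I`, `p_value`, `weight_spec`,
#'   `n_perm`, `seed`.
#' @export
morans_i <- function(residuals, coordinates,
                     weights = c("inverse_distance", "knn"), k = 8,
                     n_perm = 999,
                     alternative = c("greater", "less", "two.sided"),
                     seed = 1L) {
  weights <- match.arg(weights)
  alternative <- match.arg(alternative)
  coordinates <- as.matrix(coordinates)
  N <- length(residuals)
  if (N < 3) abort("Moran's I needs at least 3 plots.")
  stopifnot(nrow(coordinates) == N, ncol(coordinates) == 2)
  if (stats::sd(residuals) == 0) {
    abort("Moran's I undefined: residuals have zero variance.")
  }
  d <- as.matrix(stats::dist(coordinates))
  if (any(d[upper.tri(d)] == 0)) {
    abort("Plots with identical coordinates; weights undefined.")
  }
  W <- switch(weights,
    inverse_distance = 1 / d,
    knn = {
      Wk <- matrix(0, N, N)
      for (i in seq_len(N)) {
        di <- d[i, ]
        di[i] <- Inf
        Wk[i, order(di)[seq_len(k)]] <- 1
      }
      Wk
    }
  )
  diag(W) <- 0
  W <- W / rowSums(W)

  stat <- function(r) {
    r <- r - mean(r)
    N / sum(W) * sum(W * tcrossprod(r)) / sum(r^2)
  }
  I <- stat(residuals)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat(sample(residuals)), numeric(1))
  })
  p_gr <- (1 + sum(perm >= I)) / (n_perm + 1)
  p_ls <- (1 + sum(perm <= I)) / (n_perm + 1)
  p <- switch(alternative,
    greater = p_gr, less = p_ls, two.sided = min(1, 2 * min(p_gr, p_ls))
  )
  tibble(
    I = I, expected_I = -1 / (N - 1), p_value = p,
    weight_spec = paste0(weights, if (weights == "knn") paste0("(k=", k, ")"),
                         ", row-standardized, zero diagonal"),
    n_perm = n_perm, seed = as.integer(seed)
  )
}

#' Per-plot residuals of a fitted occurrence model
#'
#' Mean Pearson residual across species at each plot, using
#' population-level (fixed-effects-only) predictions by default, the
#' input to the Moran's I spatial diagnostic.
#'
#' @param fit A `te_fit` object.
#' @param type `"pearson"` or `"deviance"`.
#' @param include_random Use conditional (random-effect) predictions
#'   instead of population-level ones?
#' @return Numeric vector, one value per fitted plot.
#' @export
plot_residuals <- function(fit, type = c("pearson", "deviance"),
                           include_random = FALSE) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "te_fit"))
  p <- predict_probability(fit, include_random = include_random)
  Y <- fit$Y
  r <- switch(type,
    pearson = (Y - p) / sqrt(p * (1 - p)),
    deviance = sign(Y - p) *
      sqrt(-2 * (Y * log(p) + (1 - Y) * log(1 - p)))
  )
  rowMeans(r)
}

#' Evaluate a fitted occurrence model
#'
#' Per-species prevalence, AUROC, AUPRC and AUPRC/prevalence on the
#' fitted data (in-sample, conditional predictions by default), plus the
#' pooled AUROC over all plot x species cells and the mean of per-species
#' AUROC. The pooled and averaged variants are both reported because
#' "AUROC across all species" can mean either; pooled is the default
#' headline value.
#'
#' @param fit A `te_fit` object.
#' @param include_random Evaluate conditional (random effects included)
#'   predictions (default) or population-level ones?
#' @return A list of class `te_metrics` with `per_species` (tibble),
#'   `pooled_auroc`, `mean_auroc`, and `ratio_summary` (mean and range of
#'   AUPRC/prevalence over evaluable species).
#' @export
evaluate_fit <- function(fit, include_random = TRUE) {
  stopifnot(inherits(fit, "te_fit"))
  p <- predict_probability(fit, include_random = include_random)
  Y <- fit$Y
  m <- ncol(Y)
  per <- purrr::map(seq_len(m), function(j) {
    y <- Y[, j]; s <- p[, j]
    prev <- mean(y)
    evaluable <- prev > 0 && prev < 1
    tibble(
      species_id = colnames(Y)[j],
      prevalence = prev,
      auroc = if (evaluable) auroc(y, s) else NA_real_,
      auprc = if (prev > 0) auprc(y, s) else NA_real_,
      auprc_prevalence = if (prev > 0) auprc(y, s) / prev else NA_real_
    )
  }) %>% purrr::list_rbind()
  ok <- !is.na(per$auprc_prevalence)
  structure(
    list(
      per_species = per,
      pooled_auroc = auroc(as.vector(Y), as.vector(p)),
      mean_auroc = mean(per$auroc, na.rm = TRUE),
      ratio_summary = tibble(
        mean = mean(per$auprc_prevalence[ok]),
        min = min(per$auprc_prevalence[ok]),
        max = max(per$auprc_prevalence[ok])
      )
    ),
    class = "te_metrics"
  )
}

#' @export
print.te_metrics <- function(x, ...) {
  cat("<te_metrics>\n")
  cat(sprintf("  pooled AUROC %.3f (per-species mean %.3f)\n",
              x$pooled_auroc, x$mean_auroc))
  cat(sprintf("  AUPRC/prevalence %.2f (range %.2f-%.2f)\n",
              x$ratio_summary$mean, x$ratio_summary$min, x$ratio_summary$max))
  print(x$per_species)
  invisible(x)
}

#' Aggregate fixed effects across replicate fits
#'
#' Per-coefficient mean and min-max range over replicate grid-sample
#' fits, formatted like a "10 fit ranges" column (`min/max` to 2
#' decimals).
#'
#' @param fits A list of `te_fit` objects sharing one design structure.
#' @return A tibble with `term`, `mean`, `min`, `max`, `range`.
#' @export
aggregate_fits <- function(fits) {
  stopifnot(length(fits) >= 1, all(purrr::map_lgl(fits, inherits, "te_fit")))
  terms <- fits[[1]]$fixed$term
  same <- purrr::map_lgl(fits, ~ identical(.x$fixed$term, terms))
  if (!all(same)) abort("Fits have mismatched coefficient sets.")
  est <- purrr::map(fits, ~ .x$fixed$estimate)
  M <- do.call(cbind, est)
  tibble(
    term = terms,
    mean = rowMeans(M),
    min = apply(M, 1, min),
    max = apply(M, 1, max)
  ) %>%
    mutate(range = sprintf("%.2f/%.2f", .data$min, .data$max))
}
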