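#' Separation and reliability of a set of measures
#'
#' Classical Rasch separation statistics. With observed (sample) variance
#' `SD^2` of the measures and mean squared standard error `MSE`, the "true"
#' variance is `T = max(SD^2 - MSE, 0)`, reliability is `R = T / SD^2` and
#' the separation index is `G = sqrt(T) / sqrt(MSE)`; the two are tied by
#' `R = G^2 / (1 + G^2)`. Item separation indicates how distinctly the item
#' difficulties are spread relative to their estimation error; person
#' separation the same for abilities.
#'
#' @param measures Numeric vector of logit measures (non-extreme entities).
#' @param ses Matching vector of standard errors.
#' @return A list with `reliability` and `separation`.
#' @export
separation_reliability <- function(measures, ses) {
  stopifnot(length(measures) == length(ses), length(measures) >= 2L)
  sd2 <- var(measures)
  mse <- mean(ses^2)
  if (sd2 == 0 && mse > 0) {
    return(list(reliability = 0, separation = 0))
  }
  if (mse == 0) {
    warn("all standard errors are zero; reliability capped at 1")
    return(list(reliability = 1, separation = Inf))
  }
  tv <- max(sd2 - mse, 0)
  list(reliability = tv / sd2, separation = sqrt(tv) / sqrt(mse))
}

#' Cronbach's alpha of a response matrix
#'
#' The definitional internal-consistency coefficient
#' `k/(k-1) * (1 - sum of item variances / variance of total scores)`,
#' computed on listwise-complete persons.
#'
#' @param data A [response_matrix] or a wide data frame (first column person
#'   id).
#' @return Alpha, a scalar in `(-Inf, 1]`.
#' @export
cronbach_alpha <- function(data) {
  if (!inherits(data, "response_matrix")) {
    x <- as.matrix(data[, -1L, drop = FALSE])
  } else {
    x <- data$values
  }
  x <- x[stats::complete.cases(x), , drop = FALSE]
  k <- ncol(x)
  if (nrow(x) < 2L || k < 2L) abort("need at least 2 complete persons and 2 items")
  total_var <- var(rowSums(x))
  if (total_var == 0) abort("zero total-score variance; alpha undefined")
  item_var <- sum(apply(x, 2L, var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' Infit and outfit mean-square fit statistics
#'
#' Standard Rasch quality-control residual statistics. For an item, outfit is
#' the mean over persons of the squared standardised residual
#' `z^2 = (x - E)^2 / W`, and infit the information-weighted version
#' `sum (x - E)^2 / sum W`; both are approximately 1 when the data fit the
#' model, and inflate for noisy (mis-fitting) entities. Person statistics are
#' the transposed analogues. Missing cells are skipped.
#'
#' @param fit A `rasch_fit`.
#' @return A tibble with columns `entity`, `id`, `infit`, `outfit`.
#' @export
fit_statistics <- function(fit) {
  stopifnot(inherits(fit, "rasch_fit"))
  x <- fit$data$values
  e <- fit$expected; w <- fit$score_var
  sq <- (x - e)^2
  z2 <- sq / w
  item_stats <- tibble(
    entity = "item", id = colnames(x),
    infit = colSums(sq, na.rm = TRUE) / colSums(w, na.rm = TRUE),
    outfit = colMeans(z2, na.rm = TRUE)
  )
  person_stats <- tibble(
    entity = "person", id = rownames(x),
    infit = rowSums(sq, na.rm = TRUE) / rowSums(w, na.rm = TRUE),
    outfit = rowMeans(z2, na.rm = TRUE)
  )
  bind_rows(person_stats, item_stats)
}

#' Variance explained by the Rasch measures and residual first contrast
#'
#' A unidimensionality panel. The modelled cell values `E` carry the variance
#' explained by the person and item measures; the model score variances `W`
#' are the unexplained (stochastic) part:
#' `raw_variance_explained = 100 * Var(E) / (Var(E) + mean(W))`. The first
#' contrast is the largest eigenvalue of the item-by-item correlation matrix
#' of standardised residuals; under model fit it stays near 1 (noise), and
#' the share of unexplained variance it carries is
#' `100 * (lambda1 / I) * mean(W) / (Var(E) + mean(W))`. A raw variance above
#' roughly 40% is conventionally read as an excellently unidimensional
#' instrument.
#'
#' @param fit A `rasch_fit` (converged).
#' @return A list with `raw_variance_explained` (percent),
#'   `first_contrast_eigenvalue`, and `unexplained_first_contrast` (percent;
#'   `NA` with fewer than 3 items).
#' @export
variance_explained <- function(fit) {
  stopifnot(inherits(fit, "rasch_fit"))
  e <- fit$expected[!is.na(fit$expected)]
  w <- fit$score_var[!is.na(fit$score_var)]
  v_expl <- var(e) * (length(e) - 1) / length(e)
  v_unexpl <- mean(w)
  raw_pct <- 100 * v_expl / (v_expl + v_unexpl)
  i_n <- ncol(fit$std_resid)
  if (i_n < 3L) {
    return(list(raw_variance_explained = raw_pct,
                first_contrast_eigenvalue = NA_real_,
                unexplained_first_contrast = NA_real_))
  }
  cmat <- suppressWarnings(cor(fit$std_resid, use = "pairwise.complete.obs"))
  cmat[!is.finite(cmat)] <- 0
  diag(cmat) <- 1
  lambda1 <- max(eigen(cmat, symmetric = TRUE, only.values = TRUE)$values)
  list(
    raw_variance_explained = raw_pct,
    first_contrast_eigenvalue = lambda1,
    unexplained_first_contrast = 100 * (lambda1 / i_n) * v_unexpl / (v_expl + v_unexpl)
  )
}

#' Psychometric attribute panel
#'
#' One-row summary of instrument quality for a calibrated occasion: variance
#' explained by the measures, residual first contrast, Cronbach's alpha, and
#' person/item reliability and separation (non-extreme entities only).
#'
#' @param fit A `rasch_fit`.
#' @return A one-row tibble with columns `raw_variance_explained`,
#'   `unexplained_first_contrast`, `first_contrast_eigenvalue`,
#'   `cronbach_alpha`, `person_reliability`, `person_separation`,
#'   `item_reliability`, `item_separation`.
#' @export
psychometric_panel <- function(fit) {
  stopifnot(inherits(fit, "rasch_fit"))
  ve <- variance_explained(fit)
  pers <- fit$persons[!fit$persons$extreme, ]
  items <- fit$items[!fit$items$extreme, ]
  pr <- separation_reliability(pers$theta, pers$se)
  ir <- separation_reliability(items$delta, items$se)
  alpha <- tryCatch(cronbach_alpha(fit$data), error = function(e) NA_real_)
  tibble(
    raw_variance_explained = ve$raw_variance_explained,
    unexplained_first_contrast = ve$unexplained_first_contrast,
    first_contrast_eigenvalue = ve$first_contrast_eigenvalue,
    cronbach_alpha = alpha,
    person_reliability = pr$reliability,
    person_separation = pr$separation,
    item_reliability = ir$reliability,
    item_separation = ir$separation
  )
}
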