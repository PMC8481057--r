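#' Calibration settings
#'
#' Controls for the joint maximum likelihood (JMLE) engine. Defaults are
#' tighter than two printed decimals of any logit measure.
#'
#' @param max_iter Maximum number of Newton sweeps.
#' @param score_tol Convergence ceiling on the largest absolute score
#'   residual `|observed raw score - expected raw score|` over persons and
#'   items.
#' @param change_tol Convergence ceiling on the largest absolute logit change
#'   applied in a sweep.
#' @param extreme_adjust Fractional score adjustment (score points) used to
#'   give zero and perfect raw scores finite measures: a raw score of 0 is
#'   treated as `extreme_adjust`, a perfect score as `max - extreme_adjust`.
#' @param bias_correct If `TRUE`, rescale item difficulties by `(I-1)/I`
#'   (a classical JMLE bias correction). Off by default; switching it on
#'   shifts every printed-scale comparison.
#' @param max_step Per-sweep cap on any single parameter update (logits);
#'   damping that keeps alternating Newton stable on small matrices.
#' @return A list of class `calibration_config`.
#' @export
calibration_config <- function(max_iter = 100L, score_tol = 0.01,
                               change_tol = 0.001, extreme_adjust = 0.3,
                               bias_correct = FALSE, max_step = 1.0) {
  stopifnot(score_tol > 0, change_tol > 0,
            extreme_adjust > 0, extreme_adjust < 1, max_step > 0)
  structure(
    list(max_iter = as.integer(max_iter), score_tol = score_tol,
         change_tol = change_tol, extreme_adjust = extreme_adjust,
         bias_correct = isTRUE(bias_correct), max_step = max_step),
    class = "calibration_config"
  )
}

#' PROX initialisation
#'
#' Normal-approximation starting values from the raw-score margins: person
#' logits are the log-odds of the raw score against its maximum,
#' item logits the negated log-odds of the item score (then centred to mean
#' 0), and thresholds the log-ratios of adjacent overall category counts
#' (then centred to sum 0).
#'
#' @param data A [response_matrix].
#' @param extreme_adjust Score adjustment applied to zero/perfect margins so
#'   their log-odds stay finite.
#' @return A list with numeric vectors `theta`, `delta`, `tau`.
#' @export
prox_initialize <- function(data, extreme_adjust = 0.3) {
  stopifnot(inherits(data, "response_matrix"))
  x <- data$values
  m <- data$max_category
  obs <- !is.na(x)
  if (any(rowSums(obs) == 0L)) abort("person with no observed responses")
  if (any(colSums(obs) == 0L)) abort("item with no observed responses")
  cat_counts <- tabulate(x[obs] + 1L, nbins = m + 1L)
  if (any(cat_counts == 0L)) {
    abort(paste0(
      "category with zero observed count: ",
      paste(which(cat_counts == 0L) - 1L, collapse = ", "),
      "; collapse the scale first (see collapse_categories())"
    ))
  }
  r <- rowSums(x * obs, na.rm = TRUE); r_max <- m * rowSums(obs)
  s <- colSums(x * obs, na.rm = TRUE); s_max <- m * colSums(obs)
  r_adj <- pmin(pmax(r, extreme_adjust), r_max - extreme_adjust)
  s_adj <- pmin(pmax(s, extreme_adjust), s_max - extreme_adjust)
  theta <- log(r_adj / (r_max - r_adj))
  delta <- -log(s_adj / (s_max - s_adj))
  delta <- delta - mean(delta)
  tau <- log(cat_counts[1:m] / cat_counts[2:(m + 1L)])
  tau <- tau - mean(tau)
  list(theta = unname(theta), delta = unname(delta), tau = unname(tau))
}

#' Calibrate a response matrix with the rating scale model
#'
#' Joint maximum likelihood (JMLE) estimation of person abilities, item
#' difficulties and shared category thresholds. Each sweep applies damped
#' Newton updates in a fixed order — persons, then items, then thresholds —
#' re-anchoring `mean(delta) = 0` (non-extreme items) and `sum(tau) = 0`
#' after every sweep. Zero and perfect raw scores (persons or items) are
#' excluded from the joint fit, then given finite measures by solving their
#' adjusted-score estimating equation against the fixed co-parameters, and
#' flagged `extreme`. Standard errors are model-based Fisher information,
#' `1 / sqrt(sum of score variances)`.
#'
#' Non-convergence within `max_iter` sweeps returns a result with
#' `converged = FALSE` and a warning, never silently.
#'
#' @param data A [response_matrix] (or a data frame accepted by
#'   [response_matrix()], in which case `max_category` must be supplied).
#' @param config A [calibration_config()].
#' @param max_category Scale maximum, only used when `data` is a bare data
#'   frame.
#' @return An object of class `rasch_fit` with components `persons` and
#'   `items` (tibbles of measures, standard errors, raw scores and extreme
#'   flags), `tau`, `anchoring`, `converged`, `n_iter`, `max_residual`,
#'   `trace` (one row per sweep), and matrices `expected`, `score_var`,
#'   `std_resid` aligned with the input data (missing where data are
#'   missing). Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' sim <- simulate_prepost(sim_design(n_persons = 25, n_items = 6, seed = 1))
#' fit <- rasch_rsm(sim$pre)
#' glance(fit)
#' tidy(fit)
#' @export
rasch_rsm <- function(data, config = calibration_config(), max_category = NULL) {
  if (!inherits(data, "response_matrix")) {
    if (is.null(max_category)) abort("supply max_category when data is a data frame")
    data <- response_matrix(data, max_category)
  }
  stopifnot(inherits(config, "calibration_config"))
  x <- data$values
  m <- data$max_category
  obs <- !is.na(x)
  if (any(rowSums(obs) == 0L)) abort("person with no observed responses")
  if (any(colSums(obs) == 0L)) abort("item with no observed responses")

  # iteratively flag extreme persons/items relative to the core submatrix
  keep_p <- rep(TRUE, nrow(x)); keep_i <- rep(TRUE, ncol(x))
  repeat {
    sub <- x[keep_p, keep_i, drop = FALSE]
    sobs <- obs[keep_p, keep_i, drop = FALSE]
    r <- rowSums(sub * sobs, na.rm = TRUE); rmx <- m * rowSums(sobs)
    s <- colSums(sub * sobs, na.rm = TRUE); smx <- m * colSums(sobs)
    new_p <- keep_p; new_p[keep_p] <- !(r == 0 | r == rmx)
    new_i <- keep_i; new_i[keep_i] <- !(s == 0 | s == smx)
    if (identical(new_p, keep_p) && identical(new_i, keep_i)) break
    keep_p <- new_p; keep_i <- new_i
    if (sum(keep_p) < 2L || sum(keep_i) < 2L) {
      abort("all (or nearly all) persons or items have extreme scores; nothing to calibrate")
    }
  }

  core <- new_response_matrix(x[keep_p, keep_i, drop = FALSE], m, data$occasion)
  fit_core <- jmle_core(core, config)
  theta_c <- fit_core$theta; delta_c <- fit_core$delta; tau <- fit_core$tau

  # full parameter vectors: extremes estimated against fixed co-parameters
  theta <- numeric(nrow(x)); se_t <- numeric(nrow(x))
  delta <- numeric(ncol(x)); se_d <- numeric(ncol(x))
  theta[keep_p] <- theta_c; se_t[keep_p] <- fit_core$se_theta
  delta[keep_i] <- delta_c; se_d[keep_i] <- fit_core$se_delta
  adj <- config$extreme_adjust

  for (n in which(!keep_p)) {
    use <- obs[n, ] & keep_i
    r_n <- sum(x[n, use]); r_max <- m * sum(use)
    r_adj <- if (r_n <= 0) adj else r_max - adj
    est <- solve_measure(r_adj, delta[use], tau, person = TRUE)
    theta[n] <- est$measure; se_t[n] <- est$se
  }
  for (i in which(!keep_i)) {
    use <- obs[, i] & keep_p
    s_i <- sum(x[use, i]); s_max <- m * sum(use)
    s_adj <- if (s_i <= 0) adj else s_max - adj
    est <- solve_measure(s_adj, theta[use], tau, person = FALSE)
    delta[i] <- est$measure; se_d[i] <- est$se
  }

  if (config$bias_correct) {
    i_n <- sum(keep_i)
    delta <- delta * (i_n - 1) / i_n
  }

  # residual matrices over the full data
  p_all <- rsm_prob_array(theta, delta, tau)
  mom <- rsm_moments(p_all)
  e_mat <- mom$E; w_mat <- mom$W
  e_mat[!obs] <- NA_real_; w_mat[!obs] <- NA_real_
  z_mat <- (x - e_mat) / sqrt(w_mat)
  dimnames(e_mat) <- dimnames(w_mat) <- dimnames(z_mat) <- dimnames(x)

  r_all <- rowSums(x * obs, na.rm = TRUE)
  s_all <- colSums(x * obs, na.rm = TRUE)

  fit <- structure(list(
    persons = tibble(
      person_id = rownames(x), theta = theta, se = se_t,
      raw_score = r_all, max_score = m * rowSums(obs), extreme = !keep_p
    ),
    items = tibble(
      item_id = colnames(x), delta = delta, se = se_d,
      raw_score = s_all, max_score = m * colSums(obs), extreme = !keep_i
    ),
    tau = tau,
    anchoring = list(
      item_mean = "mean(delta) = 0 over non-extreme items",
      threshold_sum = "sum(tau) = 0",
      bias_correct = config$bias_correct
    ),
    converged = fit_core$converged,
    n_iter = fit_core$n_iter,
    max_residual = fit_core$max_residual,
    trace = fit_core$trace,
    expected = e_mat, score_var = w_mat, std_resid = z_mat,
    data = data, config = config
  ), class = "rasch_fit")
  if (!fit$converged) {
    warn(sprintf(
      "calibration did not converge in %d sweeps (max score residual %.4g)",
      fit$n_iter, fit$max_residual
    ))
  }
  fit
}

# JMLE on a matrix with no extreme persons/items.
jmle_core <- function(data, config) {
  x <- data$values
  m <- data$max_category
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0L
  r <- rowSums(x0); s <- colSums(x0)
  ge_obs <- vapply(seq_len(m), function(j) sum(x0[obs] >= j), numeric(1))

  init <- prox_initialize(data, config$extreme_adjust)
  theta <- init$theta; delta <- init$delta; tau <- init$tau
  cap <- function(d) pmin(pmax(d, -config$max_step), config$max_step)

  trace <- vector("list", config$max_iter)
  converged <- FALSE
  max_res <- Inf
  iter <- 0L
  for (iter in seq_len(config$max_iter)) {
    max_change <- 0

    mom <- masked_moments(theta, delta, tau, obs)
    dth <- cap((r - rowSums(mom$E)) / rowSums(mom$W))
    theta <- theta + dth
    max_change <- max(max_change, abs(dth))

    mom <- masked_moments(theta, delta, tau, obs)
    ddl <- cap((s - colSums(mom$E)) / colSums(mom$W))
    delta <- delta - ddl
    max_change <- max(max_change, abs(ddl))
    ctr <- mean(delta)
    delta <- delta - ctr; theta <- theta - ctr

    if (m > 1L) {
      p <- rsm_prob_array(theta, delta, tau)
      for (j in seq_len(m)) {
        p_ge <- matrix(0, nrow(x), ncol(x))
        for (k in j:m) p_ge <- p_ge + p[, , k + 1L]
        p_ge[!obs] <- 0
        g <- sum(p_ge) - ge_obs[j]
        info <- sum(p_ge * (1 - p_ge))
        dtj <- cap(g / info)
        tau[j] <- tau[j] + dtj
        max_change <- max(max_change, abs(dtj))
      }
      ctr_t <- mean(tau)
      tau <- tau - ctr_t; theta <- theta - ctr_t
    }

    mom <- masked_moments(theta, delta, tau, obs)
    max_res <- max(abs(r - rowSums(mom$E)), abs(s - colSums(mom$E)))
    trace[[iter]] <- tibble(iteration = iter, max_score_residual = max_res,
                            max_logit_change = max_change)
    if (max_res <= config$score_tol && max_change <= config$change_tol) {
      converged <- TRUE
      break
    }
  }

  mom <- masked_moments(theta, delta, tau, obs)
  list(
    theta = theta, delta = delta, tau = tau,
    se_theta = 1 / sqrt(rowSums(mom$W)),
    se_delta = 1 / sqrt(colSums(mom$W)),
    converged = converged, n_iter = iter, max_residual = max_res,
    trace = dplyr::bind_rows(trace[seq_len(iter)])
  )
}

# moments with missing cells zeroed out of all sums
masked_moments <- function(theta, delta, tau, obs) {
  mom <- rsm_moments(rsm_prob_array(theta, delta, tau))
  mom$E[!obs] <- 0
  mom$W[!obs] <- 0
  mom
}

# Solve sum_i E(theta, delta_i, tau) = target for one person's measure
# (or the item analogue, decreasing in delta) by root finding; used for
# extreme-score entities. Returns the measure and its information SE.
solve_measure <- function(target, others, tau, person = TRUE) {
  expected_sum <- function(v) {
    if (person) {
      mom <- rsm_moments(rsm_prob_array(v, others, tau))
    } else {
      mom <- rsm_moments(rsm_prob_array(others, v, tau))
    }
    sum(mom$E)
  }
  f <- function(v) expected_sum(v) - target
  lo <- -50; hi <- 50
  root <- uniroot(f, lower = lo, upper = hi, tol = 1e-8)$root
  if (person) {
    w <- sum(rsm_moments(rsm_prob_array(root, others, tau))$W)
  } else {
    w <- sum(rsm_moments(rsm_prob_array(others, root, tau))$W)
  }
  list(measure = root, se = 1 / sqrt(w))
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat(sprintf(
    "<rasch_fit> rating scale model: %d persons, %d items, categories 0..%d\n",
    nrow(x$persons), nrow(x$items), length(x$tau)
  ))
  cat(sprintf("  converged: %s after %d sweeps (max score residual %.4g)\n",
              x$converged, x$n_iter, x$max_residual))
  cat(sprintf("  extreme: %d persons, %d items\n",
              sum(x$persons$extreme), sum(x$items$extreme)))
  cat(sprintf("  thresholds: %s\n", paste(sprintf("%.3f", x$tau), collapse = ", ")))
  invisible(x)
}

#' Tidy a rating scale calibration
#'
#' One row per estimated parameter, broom-style: persons, items and
#' thresholds in a single tibble with an `entity` column.
#'
#' @param x A `rasch_fit`.
#' @param ... Unused.
#' @return A tibble with columns `entity` (`"person"`, `"item"`,
#'   `"threshold"`), `id`, `measure` (logits), `std_error`, `raw_score`,
#'   `max_score`, `extreme`.
#' @method tidy rasch_fit
#' @export
tidy.rasch_fit <- function(x, ...) {
  bind_rows(
    tibble(entity = "person", id = x$persons$person_id,
           measure = x$persons$theta, std_error = x$persons$se,
           raw_score = x$persons$raw_score, max_score = x$persons$max_score,
           extreme = x$persons$extreme),
    tibble(entity = "item", id = x$items$item_id,
           measure = x$items$delta, std_error = x$items$se,
           raw_score = x$items$raw_score, max_score = x$items$max_score,
           extreme = x$items$extreme),
    tibble(entity = "threshold", id = paste0("tau", seq_along(x$tau)),
           measure = x$tau, std_error = NA_real_,
           raw_score = NA_real_, max_score = NA_real_, extreme = FALSE)
  )
}

#' Glance at a rating scale calibration
#'
#' @param x A `rasch_fit`.
#' @param ... Unused.
#' @return A one-row tibble: counts, convergence state, final score
#'   residual, and the joint log-likelihood.
#' @method glance rasch_fit
#' @export
glance.rasch_fit <- function(x, ...) {
  tibble(
    n_persons = nrow(x$persons), n_items = nrow(x$items),
    n_extreme_persons = sum(x$persons$extreme),
    n_extreme_items = sum(x$items$extreme),
    converged = x$converged, n_iter = x$n_iter,
    max_score_residual = x$max_residual,
    logLik = rsm_loglik(x$data, x$persons$theta, x$items$delta, x$tau)
  )
}

#' Write calibrated parameters to JSON
#'
#' Persons, items, thresholds, standard errors, extreme flags and the
#' anchoring record, as a single JSON document.
#'
#' @param fit A `rasch_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters_json <- function(fit, path) {
  stopifnot(inherits(fit, "rasch_fit"))
  jsonlite::write_json(list(
    persons = fit$persons, items = fit$items,
    thresholds = fit$tau, anchoring = fit$anchoring,
    converged = fit$converged, n_iter = fit$n_iter
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write calibrated parameters as tidy CSV
#'
#' Long format, one row per parameter: `entity,id,measure,se,extreme`.
#'
#' @inheritParams write_parameters_json
#' @return `path`, invisibly.
#' @export
write_parameters_csv <- function(fit, path) {
  stopifnot(inherits(fit, "rasch_fit"))
  out <- tidy(fit) %>%
    select("entity", "id", measure = "measure", se = "std_error", "extreme")
  readr::write_csv(out, path, na = "")
  invisible(path)
}
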