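#' Rating scale model category probabilities
#'
#' Closed-form probabilities of the Andrich rating scale model (RSM), the
#' polytomous Rasch model in which all items share one set of category
#' thresholds. For a person of ability `theta` meeting an item of difficulty
#' `delta` on an `m+1`-category scale with thresholds `tau`,
#' \deqn{P(X = k) \propto \exp\!\Big(\sum_{j=1}^{k} (\theta - \delta - \tau_j)\Big),}
#' with the empty sum equal to 0 for `k = 0`. Computation is done in
#' log-space with max-subtraction so that `|theta - delta|` far beyond 30
#' logits stays finite.
#'
#' @param theta Person ability (logits), finite scalar.
#' @param delta Item difficulty (logits), finite scalar.
#' @param tau Numeric vector of `m` category thresholds (logits); `m >= 1`.
#' @return Numeric vector of length `m + 1`: probabilities of categories
#'   `0..m`, summing to 1.
#' @examples
#' rsm_category_probs(0, 0, c(0, 0))      # (1/3, 1/3, 1/3)
#' rsm_category_probs(1, 0, c(-0.5, 0.5)) # weights (1, e^1.5, e^2), normalised
#' @export
rsm_category_probs <- function(theta, delta, tau) {
  check_rsm_args(theta, delta, tau)
  logw <- rsm_log_weights(theta - delta, tau)
  w <- exp(logw - max(logw))
  w / sum(w)
}

# unnormalised log category weights for a single theta - delta
rsm_log_weights <- function(d, tau) {
  k <- 0:length(tau)
  k * d - c(0, cumsum(tau))
}

check_rsm_args <- function(theta, delta, tau) {
  if (length(theta) != 1L || length(delta) != 1L ||
      !is.finite(theta) || !is.finite(delta) || !all(is.finite(tau))) {
    abort("theta and delta must be finite scalars and tau a finite vector")
  }
  if (length(tau) < 1L) abort("tau must have at least one threshold")
  invisible(TRUE)
}

#' Expected score under the rating scale model
#'
#' The model-expected category value \eqn{E = \sum_k k \, P(X = k)}, a
#' strictly increasing function of ability used by the joint maximum
#' likelihood estimating equations.
#'
#' @inheritParams rsm_category_probs
#' @return Expected category value in `[0, m]`.
#' @export
rsm_expected_score <- function(theta, delta, tau) {
  p <- rsm_category_probs(theta, delta, tau)
  sum((0:length(tau)) * p)
}

#' Score variance under the rating scale model
#'
#' The model variance \eqn{\sum_k k^2 P(X = k) - E^2} of the category value;
#' the information weight behind Newton steps, standard errors and fit
#' statistics.
#'
#' @inheritParams rsm_category_probs
#' @return Variance of the category value; strictly positive for finite
#'   arguments.
#' @export
rsm_score_variance <- function(theta, delta, tau) {
  p <- rsm_category_probs(theta, delta, tau)
  k <- 0:length(tau)
  sum(k^2 * p) - sum(k * p)^2
}

#' Joint log-likelihood of a response matrix
#'
#' Sum over all non-missing cells of the log RSM probability of the observed
#' category. Adding a constant to every `theta` and every `delta` leaves the
#' value unchanged (translation invariance), which is why calibration
#' anchors `mean(delta) = 0` and `sum(tau) = 0`.
#'
#' @param data A [response_matrix].
#' @param theta Numeric vector of person abilities, one per row of `data`.
#' @param delta Numeric vector of item difficulties, one per column.
#' @param tau Numeric vector of `max_category` thresholds.
#' @return The joint log-likelihood (a non-positive number).
#' @export
rsm_loglik <- function(data, theta, delta, tau) {
  stopifnot(inherits(data, "response_matrix"))
  x <- data$values
  if (length(theta) != nrow(x) || length(delta) != ncol(x) ||
      length(tau) != data$max_category) {
    abort("parameter dimensions do not match the response matrix")
  }
  p <- rsm_prob_array(theta, delta, tau)
  n <- nrow(x); i_n <- ncol(x)
  ll <- 0
  idx <- which(!is.na(x))
  if (length(idx) == 0L) return(0)
  rows <- ((idx - 1L) %% n) + 1L
  cols <- ((idx - 1L) %/% n) + 1L
  cats <- x[idx] + 1L
  sum(log(p[cbind(rows, cols, cats)]))
}

# Vectorised probability array: persons x items x categories (0..m),
# log-space with max-subtraction per cell.
rsm_prob_array <- function(theta, delta, tau) {
  n <- length(theta); i_n <- length(delta); m <- length(tau)
  d <- outer(theta, delta, "-")                       # n x I
  ctau <- c(0, cumsum(tau))                           # length m+1
  logw <- array(0, dim = c(n, i_n, m + 1L))
  for (k in 0:m) logw[, , k + 1L] <- k * d - ctau[k + 1L]
  mx <- apply(logw, c(1L, 2L), max)
  w <- exp(logw - as.vector(mx))                      # recycles over k
  tot <- rowSums(w, dims = 2L)
  w / as.vector(tot)
}

# Expected score and score variance matrices from a probability array.
rsm_moments <- function(p) {
  m <- dim(p)[3L] - 1L
  k <- 0:m
  e <- matrix(0, dim(p)[1L], dim(p)[2L])
  e2 <- e
  for (kk in seq_len(m)) {
    e <- e + kk * p[, , kk + 1L]
    e2 <- e2 + kk^2 * p[, , kk + 1L]
  }
  list(E = e, W = e2 - e^2)
}
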