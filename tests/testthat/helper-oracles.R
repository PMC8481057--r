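# Independent oracles and fixture builders for the test suite.
# Everything here is deliberately written from first principles (plain
# exponentials, loops, enumeration), not via the package's computational path.

# build a response_matrix from a bare matrix of ratings
make_rm <- function(values, m, occasion = "test") {
  if (is.null(rownames(values))) rownames(values) <- sprintf("p%02d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("i%02d", seq_len(ncol(values)))
  df <- data.frame(person_id = rownames(values), values, check.names = FALSE)
  response_matrix(df, max_category = m, occasion = occasion)
}

# category probabilities by direct evaluation of the exponential sums
oracle_probs <- function(theta, delta, tau) {
  k <- 0:length(tau)
  w <- exp(k * (theta - delta) - c(0, cumsum(tau)))
  w / sum(w)
}

oracle_loglik <- function(values, m, theta, delta, tau) {
  ll <- 0
  for (n in seq_len(nrow(values))) {
    for (i in seq_len(ncol(values))) {
      x <- values[n, i]
      if (!is.na(x)) ll <- ll + log(oracle_probs(theta[n], delta[i], tau)[x + 1])
    }
  }
  ll
}

# Joint MLE by cyclic coordinate ascent on a fixed grid, under the same
# anchoring as the calibration engine (mean delta = 0, sum tau = 0, imposed
# by expressing the last difficulty/threshold through the others). The RSM
# joint log-likelihood is concave, so coordinate ascent on a grid reaches
# the grid-resolution global maximum.
grid_coordinate_mle <- function(values, m, grid = seq(-6, 6, by = 0.01),
                                max_sweeps = 60) {
  n <- nrow(values); i_n <- ncol(values)
  theta <- rep(0, n)
  delta <- rep(0, i_n)
  tau <- rep(0, m)

  row_ll <- function(p, th) {
    s <- 0
    for (i in seq_len(i_n)) {
      x <- values[p, i]
      if (!is.na(x)) s <- s + log(oracle_probs(th, delta[i], tau)[x + 1])
    }
    s
  }
  col_ll <- function(i, dl) {
    s <- 0
    for (p in seq_len(n)) {
      x <- values[p, i]
      if (!is.na(x)) s <- s + log(oracle_probs(theta[p], dl, tau)[x + 1])
    }
    s
  }

  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (p in seq_len(n)) {
      lls <- vapply(grid, function(g) row_ll(p, g), numeric(1))
      best <- grid[which.max(lls)]
      if (best != theta[p]) moved <- TRUE
      theta[p] <- best
    }
    # last difficulty is determined by the anchoring constraint
    for (i in seq_len(i_n - 1L)) {
      lls <- vapply(grid, function(g) {
        old_i <- delta[i]; old_last <- delta[i_n]
        delta[i] <<- g
        delta[i_n] <<- -sum(delta[-i_n])
        v <- col_ll(i, g) + col_ll(i_n, delta[i_n])
        delta[i] <<- old_i; delta[i_n] <<- old_last
        v
      }, numeric(1))
      best <- grid[which.max(lls)]
      if (best != delta[i]) moved <- TRUE
      delta[i] <- best
      delta[i_n] <- -sum(delta[-i_n])
    }
    if (m > 1L) {
      for (j in seq_len(m - 1L)) {
        lls <- vapply(grid, function(g) {
          ta <- tau; ta[j] <- g; ta[m] <- -sum(ta[-m])
          oracle_loglik(values, m, theta, delta, ta)
        }, numeric(1))
        best <- grid[which.max(lls)]
        if (best != tau[j]) moved <- TRUE
        tau[j] <- best
        tau[m] <- -sum(tau[-m])
      }
    }
    if (!moved) break
  }
  list(theta = theta, delta = delta, tau = tau,
       loglik = oracle_loglik(values, m, theta, delta, tau))
}

# exact two-sided signed-rank p by direct enumeration over sign vectors,
# written independently of the package's convolution shortcut
enumerate_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  p_lo <- mean(w_all <= w_obs + 1e-9)
  p_hi <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# two deterministic small fixtures with no extreme margins (used by the
# grid-oracle equivalence checks)
fixture_5x4 <- function() {
  make_rm(matrix(c(
    0, 1, 1, 2,
    1, 2, 0, 2,
    0, 1, 2, 1,
    2, 2, 1, 0,
    1, 0, 2, 1
  ), nrow = 5, byrow = TRUE), m = 2)
}

fixture_6x5 <- function() {
  make_rm(matrix(c(
    0, 1, 0, 2, 1,
    1, 2, 1, 2, 0,
    2, 1, 0, 1, 1,
    0, 0, 1, 2, 2,
    1, 2, 2, 0, 1,
    2, 1, 1, 1, 0
  ), nrow = 6, byrow = TRUE), m = 2)
}

new_rm_from_vals <- function(values, m) make_rm(values, m)
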