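test_that("PROX initialisation maps margins to log-odds", {
  # person at exactly half the maximum score starts at 0 logits
  vals <- rbind(rep(1L, 11), c(rep(2L, 5), rep(0L, 5), 1L))
  rownames(vals) <- c("half", "other"); colnames(vals) <- sprintf("i%02d", 1:11)
  init <- prox_initialize(make_rm(vals, 2))
  expect_equal(init$theta[1], 0)
  expect_equal(init$theta[2], 0)  # same raw score 11 of 22

  # identical item columns get identical starting difficulties
  vals2 <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L, 2L, 1L, 0L), nrow = 3)
  colnames(vals2) <- c("a", "b", "c"); rownames(vals2) <- paste0("p", 1:3)
  init2 <- prox_initialize(make_rm(vals2, 2))
  expect_equal(init2$delta[1], init2$delta[2])

  # category counts (10, 20, 10) -> tau = (-log 2, +log 2), centred
  vals3 <- matrix(c(rep(0L, 10), rep(1L, 20), rep(2L, 10)), nrow = 10)
  rownames(vals3) <- paste0("p", 1:10); colnames(vals3) <- paste0("i", 1:4)
  init3 <- prox_initialize(make_rm(vals3, 2))
  expect_equal(init3$tau, c(-log(2), log(2)), tolerance = 1e-12)
  expect_equal(sum(init3$tau), 0)
})

test_that("a never-observed category aborts with advice to collapse", {
  vals <- matrix(c(0L, 2L, 0L,
                   2L, 0L, 2L,
                   0L, 2L, 2L,
                   2L, 0L, 0L), nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("p", 1:4), c("a", "b", "c")))
  rm <- make_rm(vals, 2)
  expect_error(prox_initialize(rm), "collapse")
  expect_error(rasch_rsm(rm), "collapse")
  expect_silent(fitc <- rasch_rsm(collapse_categories(rm)))
})

test_that("raw scores are sufficient: equal scores give equal measures, higher scores higher measures", {
  sim <- simulate_prepost(sim_design(n_persons = 60, n_items = 9, seed = 5))
  fit <- rasch_rsm(sim$pre)
  pers <- fit$persons[!fit$persons$extreme, ]
  for (r in unique(pers$raw_score)) {
    th <- pers$theta[pers$raw_score == r]
    expect_lt(diff(range(th)), 2 * fit$config$change_tol)
  }
  ord <- pers[order(pers$raw_score), ]
  agg <- tapply(ord$theta, ord$raw_score, mean)
  expect_true(all(diff(agg) > 0))
})

test_that("converged fits reproduce the raw score margins and honour the anchoring", {
  for (seed in c(21, 22)) {
    sim <- simulate_prepost(sim_design(n_persons = 35, n_items = 12, seed = seed,
                                       missing_rate = if (seed == 22) 0.05 else 0))
    fit <- rasch_rsm(sim$pre)
    expect_true(fit$converged)
    core_p <- !fit$persons$extreme; core_i <- !fit$items$extreme
    e <- fit$expected[core_p, core_i]
    x <- sim$pre$values[core_p, core_i]
    obs <- !is.na(x)
    r_res <- abs(rowSums(x * obs, na.rm = TRUE) - rowSums(e * obs, na.rm = TRUE))
    expect_true(all(r_res <= fit$config$score_tol * rowSums(obs)))
    expect_equal(mean(fit$items$delta[core_i]), 0, tolerance = 1e-9)
    expect_equal(sum(fit$tau), 0, tolerance = 1e-9)
    expect_true(all(fit$persons$se > 0))
    expect_true(all(fit$items$se > 0))
  }
})

test_that("extreme scores get finite flagged measures beyond the core range", {
  sim <- simulate_prepost(sim_design(n_persons = 30, n_items = 8, seed = 6))
  vals <- sim$pre$values
  vals[1, ] <- 2L  # perfect score
  vals[2, ] <- 0L  # zero score
  fit <- rasch_rsm(make_rm(vals, 2))
  expect_true(fit$persons$extreme[1])
  expect_true(fit$persons$extreme[2])
  expect_true(is.finite(fit$persons$theta[1]))
  core <- fit$persons$theta[!fit$persons$extreme]
  expect_gt(fit$persons$theta[1], max(core))
  expect_lt(fit$persons$theta[2], min(core))
  # extremes are excluded from the anchoring mean
  expect_equal(mean(fit$items$delta[!fit$items$extreme]), 0, tolerance = 1e-9)
  # and the adjusted-score estimating equation is satisfied
  adj <- fit$config$extreme_adjust
  e_sum <- sum(vapply(seq_len(8), function(i) {
    rsm_expected_score(fit$persons$theta[1], fit$items$delta[i], fit$tau)
  }, numeric(1)))
  expect_equal(e_sum, 16 - adj, tolerance = 1e-6)
})

test_that("non-convergence warns and is reported, never silent", {
  sim <- simulate_prepost(sim_design(n_persons = 25, n_items = 7, seed = 8))
  expect_warning(
    fit <- rasch_rsm(sim$pre, calibration_config(max_iter = 2)),
    "did not converge"
  )
  expect_false(fit$converged)
  expect_equal(fit$n_iter, 2L)
})

test_that("an all-extreme matrix cannot be calibrated", {
  vals <- matrix(c(2L, 2L, 0L, 0L, 2L, 2L, 0L, 0L), nrow = 4,
                 dimnames = list(paste0("p", 1:4), c("a", "b")))
  expect_error(rasch_rsm(make_rm(vals, 2)), "extreme")
})

test_that("item difficulties are recovered from moderate simulated data", {
  sim <- simulate_prepost(sim_design(n_persons = 150, n_items = 9, seed = 13))
  fit <- rasch_rsm(sim$pre)
  ok <- !fit$items$extreme
  expect_gt(cor(fit$items$delta[ok], sim$truth$delta[ok]), 0.9)
})

test_that("tidy and glance expose the full parameter set", {
  sim <- simulate_prepost(sim_design(n_persons = 20, n_items = 6, seed = 9))
  fit <- rasch_rsm(sim$pre)
  td <- tidy(fit)
  expect_equal(sum(td$entity == "person"), 20L)
  expect_equal(sum(td$entity == "item"), 6L)
  expect_equal(sum(td$entity == "threshold"), 2L)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_lte(gl$logLik, 0)

  # parameter files round-trip through JSON and tidy CSV
  jpath <- withr::local_tempfile(fileext = ".json")
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_parameters_json(fit, jpath)
  parsed <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(parsed$persons$theta, fit$persons$theta, tolerance = 1e-12)
  write_parameters_csv(fit, cpath)
  back <- readr::read_csv(cpath, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(td))
})
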