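test_that("exact signed-rank p equals full sign enumeration, with and without ties", {
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "all differences are zero")

  r <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(r$statistic, 6)
  expect_equal(r$p_value, 0.25)
  expect_equal(r$method, "exact")

  r2 <- wilcoxon_signed_rank(c(-1, -2, -3))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 0.25)

  # zeros are dropped before ranking
  r3 <- wilcoxon_signed_rank(c(0, 1, 2, 0, 3))
  expect_equal(r3$n_nonzero, 3L)
  expect_equal(r3$p_value, 0.25)

  # every sign pattern at n = 3..8, including tied magnitudes
  for (n in 3:8) {
    mags <- c(seq_len(n - 1), n - 1)[seq_len(n)]  # one tie
    for (pattern in 0:(2^n - 1)) {
      signs <- ifelse(bitwAnd(pattern, 2^(0:(n - 1))) > 0, 1, -1)
      d <- signs * mags
      expect_equal(wilcoxon_signed_rank(d)$p_value, enumerate_wilcoxon_p(d),
                   tolerance = 1e-12)
    }
  }
})

test_that("exact p agrees with stats::wilcox.test when there are no ties or zeros", {
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    d <- sample(1:50, n) * sample(c(-1, 1), n, replace = TRUE)
    ours <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the normal approximation controls type-I error near the nominal level", {
  set.seed(42)
  rej <- mean(replicate(2000, {
    wilcoxon_signed_rank(rnorm(20))$p_value < 0.05
  }))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("label symmetry: swapping pre and post negates differences, p unchanged", {
  set.seed(43)
  for (rep in 1:20) {
    d <- round(rnorm(sample(5:15, 1)), 2)
    d <- d[d != 0]
    a <- wilcoxon_signed_rank(d)
    b <- wilcoxon_signed_rank(-d)
    n <- a$n_nonzero
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_equal(abs(a$statistic - n * (n + 1) / 4),
                 abs(b$statistic - n * (n + 1) / 4), tolerance = 1e-9)
  }

  sim <- simulate_prepost(preset_design("infant"), seed = 44)
  fwd <- rasch_stack(align_prepost(sim$pre, sim$post))
  rev <- rasch_stack(align_prepost(sim$post, sim$pre))
  expect_equal(tidy(fwd)$difference, -tidy(rev)$difference, tolerance = 1e-6)
  expect_equal(glance(fwd)$p_value, glance(rev)$p_value, tolerance = 1e-9)
})

test_that("stacking shares item difficulties and doubles the person rows", {
  sim <- simulate_prepost(preset_design("infant"), seed = 45)
  design <- align_prepost(sim$pre, sim$post)
  st <- rasch_stack(design)
  expect_equal(nrow(st$fit$persons), 82L)   # every person twice
  expect_equal(nrow(st$fit$items), 11L)     # one shared difficulty per item
  expect_setequal(substr(st$fit$persons$person_id, 1, 1), c("P", "0"))
  expect_equal(nrow(tidy(st)), 41L)
  # summary arithmetic invariant
  expect_equal(st$mean_difference, st$mean_post - st$mean_pre, tolerance = 1e-9)
  expect_equal(tidy(st)$difference,
               tidy(st)$measure_post - tidy(st)$measure_pre, tolerance = 1e-12)
})

test_that("racking shares person abilities and doubles the item columns", {
  sim <- simulate_prepost(preset_design("toddler"), seed = 46)
  design <- align_prepost(sim$pre, sim$post)
  rk <- rasch_rack(design)
  expect_equal(nrow(rk$fit$persons), 41L)   # one shared ability per person
  expect_equal(nrow(rk$fit$items), 26L)     # every item twice
  expect_setequal(substr(rk$fit$items$item_id, 1, 1), c("i", "o"))
  expect_equal(nrow(tidy(rk)), 13L)
  # the strong training effect shows as a drop in difficulty (negative diff)
  expect_lt(rk$mean_difference, 0)
  expect_lt(glance(rk)$p_value, 0.01)
})

test_that("identical occasions give zero differences and a degenerate test", {
  sim <- simulate_prepost(sim_design(n_persons = 20, n_items = 6, seed = 47))
  design <- align_prepost(sim$pre, sim$pre)
  rk <- rasch_rack(design)
  expect_true(all(abs(tidy(rk)$difference) < 1e-6))
  expect_true(is.na(glance(rk)$p_value))
  st <- rasch_stack(design)
  expect_true(all(abs(tidy(st)$difference) < 1e-6))
})

test_that("a null training effect yields approximately uniform stacking p-values", {
  null_design <- sim_design(n_persons = 41, n_items = 11, effect = 0,
                            effect_sd = 0, seed = 1)
  pvals <- vapply(1:200, function(s) {
    sim <- simulate_prepost(null_design, seed = 5000 + s)
    glance(rasch_stack(align_prepost(sim$pre, sim$post)))$p_value
  }, numeric(1))
  expect_gt(mean(pvals > 0.05), 0.85)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("stacking recovers an injected uniform training effect", {
  sim <- simulate_prepost(preset_design("infant"), seed = 48)
  st <- rasch_stack(align_prepost(sim$pre, sim$post))
  expect_gt(st$mean_difference, 2)
  expect_lt(st$mean_difference, 4)
  expect_lt(glance(st)$p_value, 0.01)
})

test_that("racking orders item-specific effects and the cross-plot flags small drops", {
  # distinct item-specific effects: estimated drops must track their ranking
  shifts <- seq(-0.5, 2.0, length.out = 13)
  sim <- simulate_prepost(sim_design(n_persons = 200, n_items = 13, effect = 1,
                                     item_shifts = shifts, seed = 49))
  rk <- rasch_rack(align_prepost(sim$pre, sim$post))
  expect_gt(cor(tidy(rk)$difference, -shifts, method = "spearman"), 0.9)

  # a hard minority block (much smaller extra effect) is flagged above the
  # identity line; the majority straddles it by construction
  blocky <- c(rep(1.5, 9), rep(-0.5, 4))
  sim2 <- simulate_prepost(sim_design(n_persons = 200, n_items = 13, effect = 1,
                                      item_shifts = blocky, seed = 50))
  rk2 <- rasch_rack(align_prepost(sim2$pre, sim2$post))
  cp <- difficulty_crossplot(rk2)
  expect_true(all(cp$above_line[10:13]))
  expect_lte(sum(cp$above_line[1:9]), 5)
})

test_that("cross-plot classification against the identity line is definitional", {
  res <- tibble::tibble(
    id = c("a", "b", "c"),
    measure_pre = c(-1, 0, 1), measure_post = c(-1, 0, 1) - 2,
    difference = c(-2, -2, -2),
    se_pre = 0.3, se_post = 0.3, extreme_pre = FALSE, extreme_post = FALSE
  )
  s <- rackstack:::new_effect_summary("item", res,
                                      wilcoxon_signed_rank(res$difference), NULL)
  cp <- difficulty_crossplot(s)
  expect_false(any(cp$above_line))  # uniform drop: everything on the line

  res2 <- res
  res2$measure_post[3] <- 3  # one item stays hard
  s2 <- rackstack:::new_effect_summary("item", res2,
                                       wilcoxon_signed_rank(res2$difference), NULL)
  expect_true(difficulty_crossplot(s2)$above_line[3])
  expect_error(difficulty_crossplot(rackstack:::new_effect_summary(
    "person", res, wilcoxon_signed_rank(res$difference), NULL)), "item-kind")
})

test_that("effect_from_means performs the published-summary arithmetic", {
  out <- effect_from_means(0.36, 3.04)
  expect_equal(out$difference, 2.68)
  out2 <- effect_from_means(1.01, -2.06)
  expect_equal(out2$difference, -3.07)
  expect_equal(out2$magnitude, 3.07)
})
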