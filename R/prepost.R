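#' Wilcoxon signed-rank test
#'
#' Paired one-sample signed-rank test on a vector of differences. Zeros are
#' dropped; absolute differences are ranked with midranks for ties;
#' `W+` is the sum of ranks of the positive differences. For
#' `n_nonzero <= exact_limit` the two-sided p-value is exact, from full
#' enumeration of the `2^n` sign assignments of the (mid)ranks — so ties are
#' handled by the permuted midrank distribution, which `stats::wilcox.test`
#' cannot do exactly. Beyond the limit a normal approximation is used with
#' the tie-corrected variance `sum(ranks^2) / 4` and a 0.5 continuity
#' correction.
#'
#' @param differences Numeric vector of paired differences.
#' @param exact_limit Largest `n_nonzero` for which the exact enumeration is
#'   used (default 12; 4096 sign assignments).
#' @return A list of class `wilcoxon_result`: `n_nonzero`, `statistic`
#'   (`W+`), `p_value` (two-sided), `method` (`"exact"` or
#'   `"normal-approximation"`).
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))   # W+ = 6, exact p = 0.25
#' @export
wilcoxon_signed_rank <- function(differences, exact_limit = 12L) {
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) abort("all differences are zero; signed-rank test undefined")
  rk <- rank(abs(d))
  w_plus <- sum(rk[d > 0])
  if (n <= exact_limit) {
    # full sign-flip enumeration of the midrank distribution
    w_all <- sign_flip_sums(rk)
    p_lo <- mean(w_all <= w_plus + 1e-9)
    p_hi <- mean(w_all >= w_plus - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- sum(rk) / 2
    sigma <- sqrt(sum(rk^2) / 4)
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sigma
    p <- 2 * pnorm(-abs(z))
    method <- "normal-approximation"
  }
  structure(list(n_nonzero = n, statistic = w_plus, p_value = p,
                 method = method),
            class = "wilcoxon_result")
}

# all 2^n sums of subsets of r (rank sums of "positive" sets), by iterative
# convolution of the sign assignments
sign_flip_sums <- function(r) {
  sums <- 0
  for (ri in r) sums <- c(sums, sums + ri)
  sums
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): W+ = %g, n = %d, two-sided p = %.4g\n",
              x$method, x$statistic, x$n_nonzero, x$p_value))
  invisible(x)
}

# ---- effect summaries ------------------------------------------------------

new_effect_summary <- function(entity, results, test, fit) {
  stopifnot(entity %in% c("person", "item"))
  if (is.null(test)) {
    # degenerate paired design: every difference is exactly zero
    test <- structure(list(n_nonzero = 0L, statistic = NA_real_,
                           p_value = NA_real_, method = "none (all differences zero)"),
                      class = "wilcoxon_result")
  }
  structure(list(
    entity = entity,
    results = results,
    mean_pre = mean(results$measure_pre),
    mean_post = mean(results$measure_post),
    range_pre = range(results$measure_pre),
    range_post = range(results$measure_post),
    mean_difference = mean(results$measure_post) - mean(results$measure_pre),
    test = test,
    fit = fit
  ), class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  kind <- if (x$entity == "person") "stacking (person ability, LVP)" else "racking (item difficulty, LVI)"
  cat(sprintf("<effect_summary> %s, n = %d\n", kind, nrow(x$results)))
  cat(sprintf("  pre  mean %+.2f (range %+.2f to %+.2f)\n",
              x$mean_pre, x$range_pre[1], x$range_pre[2]))
  cat(sprintf("  post mean %+.2f (range %+.2f to %+.2f)\n",
              x$mean_post, x$range_post[1], x$range_post[2]))
  cat(sprintf("  mean difference (post - pre) %+.2f logits (magnitude %.2f)\n",
              x$mean_difference, abs(x$mean_difference)))
  print(x$test)
  invisible(x)
}

#' Tidy an effect summary
#'
#' @param x An `effect_summary` from [rasch_stack()] or [rasch_rack()].
#' @param ... Unused.
#' @return A tibble with one row per person (stacking) or item (racking):
#'   `id`, `measure_pre`, `measure_post`, `difference` (post minus pre),
#'   standard errors and extreme flags per occasion.
#' @method tidy effect_summary
#' @export
tidy.effect_summary <- function(x, ...) x$results

#' Glance at an effect summary
#'
#' @param x An `effect_summary`.
#' @param ... Unused.
#' @return A one-row tibble mirroring a pre/post summary table row: group
#'   means and ranges per occasion, mean difference (and its magnitude), and
#'   the Wilcoxon signed-rank result.
#' @method glance effect_summary
#' @export
glance.effect_summary <- function(x, ...) {
  tibble(
    entity = x$entity, n = nrow(x$results),
    mean_pre = x$mean_pre, mean_post = x$mean_post,
    min_pre = x$range_pre[1], max_pre = x$range_pre[2],
    min_post = x$range_post[1], max_post = x$range_post[2],
    mean_difference = x$mean_difference,
    abs_difference = abs(x$mean_difference),
    w_statistic = x$test$statistic,
    p_value = x$test$p_value,
    test_method = x$test$method
  )
}

#' Summary arithmetic from occasion means
#'
#' The arithmetic behind a pre/post summary row: given the group mean logit
#' at each occasion, the change is `mean_post - mean_pre` and its magnitude
#' the absolute value (item-difficulty drops are often quoted as positive
#' magnitudes).
#'
#' @param mean_pre,mean_post Group mean logit values.
#' @return A one-row tibble: `mean_pre`, `mean_post`, `difference`,
#'   `magnitude`.
#' @export
effect_from_means <- function(mean_pre, mean_post) {
  tibble(mean_pre = mean_pre, mean_post = mean_post,
         difference = mean_post - mean_pre,
         magnitude = abs(mean_post - mean_pre))
}

#' Stacking analysis: person-ability change
#'
#' Row-concatenates the aligned pre and post matrices into one
#' `(2N x I)` dataset in which every person appears twice — the pretest copy
#' with identifier prefix `"P"`, the posttest copy with prefix `"0"` — and
#' runs a single joint calibration, so the items share one set of
#' difficulties across occasions and each person gets an occasion-specific
#' ability (LVP, logit value person). The per-person posttest-minus-pretest
#' ability differences are then summarised and tested with the Wilcoxon
#' signed-rank test.
#'
#' @param design A `prepost_design` from [align_prepost()].
#' @param config A [calibration_config()].
#' @return An `effect_summary` (entity `"person"`); see
#'   [tidy.effect_summary()] and [glance.effect_summary()]. The underlying
#'   joint `rasch_fit` is carried in `$fit`.
#' @export
rasch_stack <- function(design, config = calibration_config()) {
  stopifnot(inherits(design, "prepost_design"))
  pre <- design$pre; post <- design$post
  pids <- person_ids(pre)
  if (length(pids) < 5L) {
    warn("fewer than 5 paired persons; the exact signed-rank test has little power")
  }
  values <- rbind(pre$values, post$values)
  rownames(values) <- c(paste0("P", pids), paste0("0", pids))
  stacked <- new_response_matrix(values, pre$max_category, "stacked")
  fit <- rasch_rsm(stacked, config)
  th <- setNames(fit$persons$theta, fit$persons$person_id)
  se <- setNames(fit$persons$se, fit$persons$person_id)
  ex <- setNames(fit$persons$extreme, fit$persons$person_id)
  pre_ids <- paste0("P", pids); post_ids <- paste0("0", pids)
  results <- tibble(
    id = pids,
    measure_pre = unname(th[pre_ids]),
    measure_post = unname(th[post_ids]),
    difference = unname(th[post_ids] - th[pre_ids]),
    se_pre = unname(se[pre_ids]), se_post = unname(se[post_ids]),
    extreme_pre = unname(ex[pre_ids]), extreme_post = unname(ex[post_ids])
  )
  test <- if (all(results$difference == 0)) NULL else wilcoxon_signed_rank(results$difference)
  new_effect_summary("person", results, test, fit)
}

#' Racking analysis: item-difficulty change
#'
#' Column-concatenates the aligned pre and post matrices into one
#' `(N x 2I)` dataset in which every item appears twice — the pretest copy
#' with identifier prefix `"i"`, the posttest copy with prefix `"o"` — and
#' runs a single joint calibration, so the persons keep one shared ability
#' across occasions and each item gets an occasion-specific difficulty (LVI,
#' logit value item). Differences are reported as `post - pre`, so a
#' negative difference means the item became easier after training; the
#' summary also quotes the absolute magnitude.
#'
#' @inheritParams rasch_stack
#' @return An `effect_summary` (entity `"item"`).
#' @export
rasch_rack <- function(design, config = calibration_config()) {
  stopifnot(inherits(design, "prepost_design"))
  pre <- design$pre; post <- design$post
  iids <- item_ids(pre)
  values <- cbind(pre$values, post$values)
  colnames(values) <- c(paste0("i", iids), paste0("o", iids))
  racked <- new_response_matrix(values, pre$max_category, "racked")
  fit <- rasch_rsm(racked, config)
  dl <- setNames(fit$items$delta, fit$items$item_id)
  se <- setNames(fit$items$se, fit$items$item_id)
  ex <- setNames(fit$items$extreme, fit$items$item_id)
  pre_ids <- paste0("i", iids); post_ids <- paste0("o", iids)
  results <- tibble(
    id = iids,
    measure_pre = unname(dl[pre_ids]),
    measure_post = unname(dl[post_ids]),
    difference = unname(dl[post_ids] - dl[pre_ids]),
    se_pre = unname(se[pre_ids]), se_post = unname(se[post_ids]),
    extreme_pre = unname(ex[pre_ids]), extreme_post = unname(ex[post_ids])
  )
  test <- if (all(results$difference == 0)) NULL else wilcoxon_signed_rank(results$difference)
  new_effect_summary("item", results, test, fit)
}

#' Item difficulty cross-plot table
#'
#' The plotting table behind a pre/post item-difficulty scatter: both axes
#' are median-centred and each item is classified against the identity line.
#' Items *above* the line (`above_line = TRUE`) stayed relatively difficult
#' at posttest — their difficulty dropped less than is typical — and are the
#' candidates for targeted follow-up training.
#'
#' @param summary An item-kind `effect_summary` from [rasch_rack()].
#' @return A tibble: `item_id`, `pre`, `post`, `pre_centered`,
#'   `post_centered`, `above_line`.
#' @export
difficulty_crossplot <- function(summary) {
  stopifnot(inherits(summary, "effect_summary"))
  if (summary$entity != "item") abort("difficulty_crossplot needs an item-kind (racking) summary")
  res <- summary$results
  pre_c <- res$measure_pre - median(res$measure_pre)
  post_c <- res$measure_post - median(res$measure_post)
  tibble(
    item_id = res$id, pre = res$measure_pre, post = res$measure_post,
    pre_centered = pre_c, post_centered = post_c,
    above_line = post_c > pre_c + 1e-12
  )
}
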