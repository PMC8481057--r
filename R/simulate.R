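#' Design of a synthetic pre/post assessment dataset
#'
#' Describes the generating conditions for a paired pre/post checklist
#' assessment under the rating scale model: person abilities are drawn from
#' `Normal(ability_mean, ability_sd)`; pretest responses come from
#' `RSM(theta_n, delta_i, tau)`; training shifts person `n`'s ability by
#' `effect + eta_n` with `eta_n ~ Normal(0, effect_sd)`, and item `i`'s
#' posttest difficulty by `-item_shifts[i]` (so a positive shift is an
#' item-specific extra training effect: the item gets easier). Defaults
#' emulate a cohort of 41 trainees rated 0/1/2 on an 11-item instrument with
#' a large, fairly uniform training effect.
#'
#' @param n_persons Number of persons (default 41).
#' @param n_items Number of items (default 11); ignored when
#'   `item_difficulties` is supplied.
#' @param item_difficulties Vector of generating difficulties (logits);
#'   default equally spaced over `[-2, 2]`.
#' @param thresholds Shared category thresholds (default `c(-1, 1)`, a 0/1/2
#'   scale).
#' @param ability_mean,ability_sd Pretest ability distribution (defaults 0.3
#'   and 1.0 logits).
#' @param effect Uniform training effect on ability, logits (default 2.7).
#' @param effect_sd Person-level SD of the training effect (default 0.5).
#' @param item_shifts Item-specific posttest difficulty drops, logits
#'   (scalar or vector; default 0).
#' @param missing_rate Independent cell missingness probability (default 0).
#' @param seed Integer seed; the single random stream is consumed in a fixed
#'   order (abilities, effect noise, pre cells row-major, post cells
#'   row-major, missingness masks).
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_persons = 41L, n_items = 11L,
                       item_difficulties = NULL, thresholds = c(-1, 1),
                       ability_mean = 0.3, ability_sd = 1.0,
                       effect = 2.7, effect_sd = 0.5,
                       item_shifts = 0, missing_rate = 0, seed = 1L) {
  if (is.null(item_difficulties)) {
    item_difficulties <- seq(-2, 2, length.out = n_items)
  }
  n_items <- length(item_difficulties)
  item_shifts <- rep_len(item_shifts, n_items)
  stopifnot(n_persons >= 2L, n_items >= 2L, ability_sd > 0, effect_sd >= 0,
            length(thresholds) >= 1L, missing_rate >= 0, missing_rate < 1)
  if (any(abs(item_shifts) >= 10)) abort("item_shifts must be smaller than 10 logits")
  structure(list(
    n_persons = as.integer(n_persons), n_items = n_items,
    item_difficulties = item_difficulties, thresholds = thresholds,
    ability_mean = ability_mean, ability_sd = ability_sd,
    effect = effect, effect_sd = effect_sd, item_shifts = item_shifts,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_design")
}

#' Preset simulation designs
#'
#' Two ready-made instrument shapes: `"infant"` (11 items, training effect
#' 2.7 logits) and `"toddler"` (13 items, training effect 3.3 logits), both
#' with 41 persons on a 0/1/2 rubric.
#'
#' @param preset `"infant"` or `"toddler"`.
#' @param ... Overrides passed to [sim_design()].
#' @return A `sim_design`.
#' @export
preset_design <- function(preset = c("infant", "toddler"), ...) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    infant = list(n_items = 11L, effect = 2.7),
    toddler = list(n_items = 13L, effect = 3.3)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_design, args)
}

#' Simulate a paired pre/post response dataset
#'
#' Draws a pretest and a posttest [response_matrix] from the rating scale
#' model under a [sim_design()], together with the generating truth, so that
#' calibration and stacking/racking recovery can be scored. Identical seeds
#' give identical output.
#'
#' @param design A [sim_design()].
#' @param seed Optional seed overriding `design$seed`.
#' @return A list with `pre`, `post` ([response_matrix] objects with person
#'   ids `"01".."N"` and item ids `"01".."I"`) and `truth` (list of `theta`,
#'   `effect_noise`, `delta`, `tau`, `effect`, `item_shifts`).
#' @examples
#' sim <- simulate_prepost(preset_design("infant"), seed = 7)
#' sim$pre
#' @export
simulate_prepost <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(if (is.null(seed)) design$seed else seed)
  n <- design$n_persons; i_n <- design$n_items
  m <- length(design$thresholds)
  pid <- sprintf("%02d", seq_len(n))
  iid <- sprintf("%02d", seq_len(i_n))

  theta <- rnorm(n, design$ability_mean, design$ability_sd)
  eta <- rnorm(n, 0, design$effect_sd)

  draw <- function(th, dl) {
    p <- rsm_prob_array(th, dl, design$thresholds)
    # row-major uniforms so the stream order is person-by-person
    u <- matrix(runif(n * i_n), n, i_n, byrow = TRUE)
    x <- matrix(0L, n, i_n, dimnames = list(pid, iid))
    cdf <- p[, , 1L]
    for (k in seq_len(m)) {
      x <- x + (u > cdf)
      if (k < m) cdf <- cdf + p[, , k + 1L]
    }
    storage.mode(x) <- "integer"
    x
  }
  x_pre <- draw(theta, design$item_difficulties)
  x_post <- draw(theta + design$effect + eta,
                 design$item_difficulties - design$item_shifts)
  if (design$missing_rate > 0) {
    x_pre[matrix(runif(n * i_n), n, i_n, byrow = TRUE) < design$missing_rate] <- NA_integer_
    x_post[matrix(runif(n * i_n), n, i_n, byrow = TRUE) < design$missing_rate] <- NA_integer_
  }
  list(
    pre = new_response_matrix(x_pre, m, "pre"),
    post = new_response_matrix(x_post, m, "post"),
    truth = list(theta = theta, effect_noise = eta,
                 delta = design$item_difficulties, tau = design$thresholds,
                 effect = design$effect, item_shifts = design$item_shifts)
  )
}

#' Fraction of persons at the maximum raw score
#'
#' The ceiling rate of an occasion: the share of persons whose raw score
#' equals the maximum attainable over their observed items. A posttest with
#' a strong training effect typically has a positive ceiling rate, which is
#' why calibration must give extreme scores finite adjusted measures.
#'
#' @param x A [response_matrix].
#' @return A fraction in `[0, 1]`.
#' @export
ceiling_rate <- function(x) {
  stopifnot(inherits(x, "response_matrix"))
  obs <- !is.na(x$values)
  r <- rowSums(x$values * obs, na.rm = TRUE)
  mean(r == x$max_category * rowSums(obs))
}
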