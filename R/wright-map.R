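#' Wright person-item map (text rendering)
#'
#' A monospace variable map: one vertical logit axis with persons on the left
#' and items on the right, binned at `bin_width`. Every person and every item
#' appears exactly once, as its identifier, in the bin containing its
#' measure; ties within a bin are ordered lexicographically. Landmarks `M`
#' (mean), `S` (1 SD) and `T` (2 SD) are marked beside each side's axis
#' column. For stacked or racked fits the occasion is already encoded in the
#' identifier prefixes (`P`/`0` for persons, `i`/`o` for items), so the map
#' shows both occasions on the common scale.
#'
#' @param x A `rasch_fit` or an `effect_summary` (whose joint fit is used).
#' @param bin_width Bin width in logits (default 0.5).
#' @return A character vector of lines, classed `wright_map` (printed
#'   verbatim).
#' @examples
#' sim <- simulate_prepost(sim_design(n_persons = 15, n_items = 6, seed = 2))
#' fit <- rasch_rsm(sim$pre)
#' wright_map(fit)
#' @export
wright_map <- function(x, bin_width = 0.5) {
  if (inherits(x, "effect_summary")) x <- x$fit
  stopifnot(inherits(x, "rasch_fit"), bin_width > 0)
  persons <- tibble(id = x$persons$person_id, measure = x$persons$theta)
  items <- tibble(id = x$items$item_id, measure = x$items$delta)
  if (nrow(persons) == 0L || nrow(items) == 0L) abort("empty calibration")

  all_m <- c(persons$measure, items$measure)
  origin <- floor(min(all_m) / bin_width) * bin_width
  n_bins <- floor((max(all_m) - origin) / bin_width) + 1L
  bin_of <- function(v) pmin(floor((v - origin) / bin_width) + 1L, n_bins)
  centers <- origin + (seq_len(n_bins) - 0.5) * bin_width

  collect <- function(df) {
    b <- bin_of(df$measure)
    vapply(seq_len(n_bins), function(i) {
      paste(sort(df$id[b == i]), collapse = " ")
    }, character(1))
  }
  p_lab <- collect(persons)
  i_lab <- collect(items)

  landmark <- function(v) {
    mu <- mean(v); s <- sd(v)
    marks <- rep("", n_bins)
    put <- function(val, ch) {
      b <- bin_of(val)
      if (b >= 1L && b <= n_bins && marks[b] == "") marks[b] <<- ch
    }
    put(mu, "M")
    put(mu - s, "S"); put(mu + s, "S")
    put(mu - 2 * s, "T"); put(mu + 2 * s, "T")
    marks
  }
  p_mark <- landmark(persons$measure)
  i_mark <- landmark(items$measure)

  wp <- max(nchar(p_lab), nchar("PERSONS"))
  header <- sprintf("%*s %1s %7s %1s %s", wp, "PERSONS", " ", "LOGIT", " ", "ITEMS")
  lines <- vapply(rev(seq_len(n_bins)), function(i) {
    sprintf("%*s %1s|%6.2f|%1s %s", wp, p_lab[i],
            substr(paste0(p_mark[i], " "), 1, 1), centers[i],
            substr(paste0(i_mark[i], " "), 1, 1), i_lab[i])
  }, character(1))
  structure(c(header, lines), class = "wright_map",
            bin_width = bin_width, origin = origin)
}

#' @export
print.wright_map <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}

#' Parse a rendered Wright map back to bins
#'
#' Recovers, from the text rendering, each entity's identifier, side and bin
#' centre — the inverse of [wright_map()] at bin resolution. Mainly useful
#' for checking that a rendering is lossless.
#'
#' @param map A `wright_map` (or its character lines).
#' @return A tibble: `id`, `side` (`"person"`/`"item"`), `bin_center`.
#' @export
parse_wright_map <- function(map) {
  lines <- unclass(map)[-1L]
  out <- purrr::map_dfr(lines, function(ln) {
    parts <- strsplit(ln, "|", fixed = TRUE)[[1L]]
    center <- as.numeric(parts[2L])
    strip_mark <- function(s) sub("[MST ]$", "", s)
    pids <- strsplit(trimws(strip_mark(parts[1L])), "\\s+")[[1L]]
    iids <- strsplit(trimws(sub("^[MST ] ?", "", parts[3L])), "\\s+")[[1L]]
    bind_rows(
      tibble(id = pids[nzchar(pids)], side = "person", bin_center = center),
      tibble(id = iids[nzchar(iids)], side = "item", bin_center = center)
    )
  })
  out
}

#' Write a Wright map to a text file
#'
#' @param map A `wright_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wright_map <- function(map, path) {
  writeLines(unclass(map), path)
  invisible(path)
}

#' Plot method for a calibration: graphical Wright map
#'
#' Persons (left) and items (right) on a shared vertical logit axis.
#'
#' @param object A `rasch_fit`.
#' @param bin_width Histogram bin width in logits.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rasch_fit
#' @export
autoplot.rasch_fit <- function(object, bin_width = 0.5, ...) {
  df <- bind_rows(
    tibble(id = object$persons$person_id, measure = object$persons$theta,
           side = "persons"),
    tibble(id = object$items$item_id, measure = object$items$delta,
           side = "items")
  )
  df$side <- factor(df$side, levels = c("persons", "items"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measure)) +
    ggplot2::geom_dotplot(binwidth = bin_width, method = "histodot") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(x = "Measure (logits)", y = NULL,
                  title = "Wright person-item map") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot method for an effect summary
#'
#' For a racking (item) summary: the pre/post difficulty cross-plot with the
#' median-centred identity line; items above the line stayed relatively
#' difficult. For a stacking (person) summary: paired pre/post abilities
#' joined per person.
#'
#' @param object An `effect_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot effect_summary
#' @export
autoplot.effect_summary <- function(object, ...) {
  res <- object$results
  if (object$entity == "item") {
    cp <- difficulty_crossplot(object)
    shift <- median(res$measure_post) - median(res$measure_pre)
    ggplot2::ggplot(cp, ggplot2::aes(x = .data$pre, y = .data$post,
                                     colour = .data$above_line)) +
      ggplot2::geom_abline(intercept = shift, slope = 1, linetype = "dotted") +
      ggplot2::geom_point() +
      ggplot2::geom_text(ggplot2::aes(label = .data$item_id),
                         vjust = -0.7, size = 3, show.legend = FALSE) +
      ggplot2::labs(x = "Pretest difficulty (logits)",
                    y = "Posttest difficulty (logits)",
                    colour = "Above line",
                    title = "Item difficulty, pre vs post") +
      ggplot2::theme_minimal()
  } else {
    long <- tidyr::pivot_longer(res, c("measure_pre", "measure_post"),
                                names_to = "occasion", values_to = "measure")
    long$occasion <- factor(long$occasion, levels = c("measure_pre", "measure_post"),
                            labels = c("pre", "post"))
    ggplot2::ggplot(long, ggplot2::aes(x = .data$occasion, y = .data$measure,
                                       group = .data$id)) +
      ggplot2::geom_line(alpha = 0.4) +
      ggplot2::geom_point() +
      ggplot2::labs(x = NULL, y = "Person ability (logits)",
                    title = "Person ability, pre vs post (stacked calibration)") +
      ggplot2::theme_minimal()
  }
}
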