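#' Ordinal person-by-item response matrix
#'
#' The unit of all analysis: a rectangular table of ordinal observer ratings,
#' one row per person (e.g. a trainee assessed on a skill checklist) and one
#' column per item. Ratings are consecutive integers `0..max_category`
#' (e.g. 0 = cannot perform, 1 = performs imperfectly, 2 = performs
#' perfectly); cells may be missing.
#'
#' `max_category` is the *declared* scale maximum, not the observed maximum:
#' an occasion where nobody ever scores 2 still has `max_category = 2`.
#'
#' @param data A data frame whose first column holds unique person
#'   identifiers and whose remaining columns hold integer ratings, one column
#'   per item.
#' @param max_category Integer scale maximum `m >= 1`; valid ratings are
#'   `0..m`.
#' @param occasion Free-text occasion label (`"pre"`, `"post"`, ...).
#' @return An object of class `response_matrix`: a list with elements
#'   `values` (integer matrix, persons x items, `NA` for missing),
#'   `max_category`, and `occasion`. Person and item identifiers are carried
#'   as the matrix dimnames.
#' @examples
#' df <- data.frame(person_id = c("a", "b", "c"),
#'                  i1 = c(0L, 1L, 2L), i2 = c(1L, 1L, 2L))
#' rm <- response_matrix(df, max_category = 2, occasion = "pre")
#' rm
#' @export
response_matrix <- function(data, max_category, occasion = "unspecified") {
  stopifnot(is.data.frame(data))
  if (ncol(data) < 3L) {
    abort("need a person-identifier column plus at least 2 item columns")
  }
  person_ids <- as.character(data[[1L]])
  item_ids <- colnames(data)[-1L]
  values <- as.matrix(data[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  if (any(!is.na(values) & values != round(values))) {
    abort("non-integer rating found; ratings must be integers 0..max_category")
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(person_ids, item_ids)
  new_response_matrix(values, max_category, occasion)
}

# low-level constructor + validator used by all internal builders
new_response_matrix <- function(values, max_category, occasion = "unspecified") {
  stopifnot(is.matrix(values))
  storage.mode(values) <- "integer"
  m <- as.integer(max_category)
  if (length(m) != 1L || is.na(m) || m < 1L) {
    abort("max_category must be a single integer >= 1")
  }
  person_ids <- rownames(values)
  item_ids <- colnames(values)
  if (is.null(person_ids) || is.null(item_ids)) {
    abort("values matrix must carry person and item identifiers as dimnames")
  }
  if (anyDuplicated(person_ids)) {
    dup <- unique(person_ids[duplicated(person_ids)])
    abort(paste0("duplicate person id(s): ", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(item_ids)) {
    dup <- unique(item_ids[duplicated(item_ids)])
    abort(paste0("duplicate item id(s): ", paste(dup, collapse = ", ")))
  }
  if (nrow(values) < 2L || ncol(values) < 2L) {
    abort("need at least 2 persons and 2 items")
  }
  bad <- which(!is.na(values) & (values < 0L | values > m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "rating out of range 0..%d at person '%s', item '%s' (value %d)",
      m, person_ids[bad[1L, 1L]], item_ids[bad[1L, 2L]],
      values[bad[1L, 1L], bad[1L, 2L]]
    ))
  }
  structure(
    list(values = values, max_category = m, occasion = as.character(occasion)),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf(
    "<response_matrix> %d persons x %d items, categories 0..%d, occasion \"%s\"\n",
    nrow(x$values), ncol(x$values), x$max_category, x$occasion
  ))
  n_miss <- sum(is.na(x$values))
  if (n_miss > 0L) cat(sprintf("  %d missing cells\n", n_miss))
  print(utils::head(x$values, 6L))
  if (nrow(x$values) > 6L) cat(sprintf("  ... %d more persons\n", nrow(x$values) - 6L))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' @method as_tibble response_matrix
#' @export
as_tibble.response_matrix <- function(x, ...) {
  tibble::as_tibble(cbind(
    tibble(person_id = rownames(x$values)),
    tibble::as_tibble(x$values)
  ))
}

#' @rdname response_matrix
#' @param x A `response_matrix`.
#' @param ... Unused.
#' @method tidy response_matrix
#' @export
tidy.response_matrix <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(-"person_id", names_to = "item_id", values_to = "rating") %>%
    mutate(occasion = x$occasion)
}

person_ids <- function(x) rownames(x$values)
item_ids <- function(x) colnames(x$values)

#' Read a wide response CSV
#'
#' Expects a UTF-8 CSV with a header row; the first column is the person
#' identifier, each remaining column one checklist item. Cells matching one
#' of `missing_codes` become missing.
#'
#' @param path Path to the CSV file.
#' @param max_category Integer scale maximum (`2` for a 0/1/2 rubric).
#' @param missing_codes Character strings treated as missing.
#' @inheritParams response_matrix
#' @return A validated [response_matrix].
#' @export
read_response_csv <- function(path, max_category,
                              missing_codes = c("", "NA", "."),
                              occasion = "unspecified") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  if (ncol(raw) < 3L) abort("need a person-identifier column plus at least 2 item columns")
  ids <- raw[[1L]]
  items <- colnames(raw)[-1L]
  values <- matrix(NA_integer_, nrow(raw), length(items),
                   dimnames = list(ids, items))
  for (j in seq_along(items)) {
    cell <- raw[[j + 1L]]
    is_miss <- cell %in% missing_codes | is.na(cell)
    parsed <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_miss & (is.na(parsed) | parsed != round(parsed)))
    if (length(bad) > 0L) {
      abort(sprintf("cannot parse '%s' as an integer rating at row %d, column '%s'",
                    cell[bad[1L]], bad[1L], items[j]))
    }
    values[!is_miss, j] <- as.integer(parsed[!is_miss])
  }
  new_response_matrix(values, max_category, occasion)
}

#' Write a response matrix as wide CSV
#'
#' Inverse of [read_response_csv()]: the first column is `person_id`,
#' remaining columns are the items; missing cells are written empty.
#'
#' @param x A [response_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_response_csv <- function(x, path) {
  stopifnot(inherits(x, "response_matrix"))
  readr::write_csv(as_tibble(x), path, na = "")
  invisible(path)
}

#' Align a pre/post pair of response matrices
#'
#' Restricts both occasions to the persons and items they share (exact,
#' case-sensitive identifier matching), in the pre matrix's order, so that
#' stacking and racking operate on a strictly paired design.
#'
#' @param pre,post [response_matrix] objects for the two occasions; they must
#'   share `max_category`.
#' @return A `prepost_design`: list with aligned `pre` and `post` matrices
#'   and `dropped` (counts and identifiers of persons/items present on only
#'   one occasion).
#' @export
align_prepost <- function(pre, post) {
  stopifnot(inherits(pre, "response_matrix"), inherits(post, "response_matrix"))
  if (pre$max_category != post$max_category) {
    abort("pre and post must share max_category")
  }
  common_p <- intersect(person_ids(pre), person_ids(post))
  common_i <- intersect(item_ids(pre), item_ids(post))
  if (length(common_p) == 0L) abort("no persons in common between occasions")
  if (length(common_i) < 2L) abort("fewer than 2 items in common between occasions")
  if (length(common_p) < 2L) abort("fewer than 2 persons in common between occasions")
  # keep pre's ordering
  common_p <- person_ids(pre)[person_ids(pre) %in% common_p]
  common_i <- item_ids(pre)[item_ids(pre) %in% common_i]
  dropped <- list(
    persons_pre = setdiff(person_ids(pre), common_p),
    persons_post = setdiff(person_ids(post), common_p),
    items_pre = setdiff(item_ids(pre), common_i),
    items_post = setdiff(item_ids(post), common_i)
  )
  design <- structure(
    list(
      pre = new_response_matrix(pre$values[common_p, common_i, drop = FALSE],
                                pre$max_category, pre$occasion),
      post = new_response_matrix(post$values[common_p, common_i, drop = FALSE],
                                 post$max_category, post$occasion),
      dropped = dropped
    ),
    class = "prepost_design"
  )
  n_drop <- sum(lengths(dropped))
  if (n_drop > 0L) {
    inform(sprintf(
      "align_prepost: dropped %d person(s) and %d item(s) not present on both occasions",
      length(dropped$persons_pre) + length(dropped$persons_post),
      length(dropped$items_pre) + length(dropped$items_post)
    ))
  }
  design
}

#' @export
print.prepost_design <- function(x, ...) {
  cat(sprintf(
    "<prepost_design> %d persons x %d items per occasion, categories 0..%d\n",
    nrow(x$pre$values), ncol(x$pre$values), x$pre$max_category
  ))
  invisible(x)
}

#' Collapse rating categories to consecutive observed codes
#'
#' Renumbers the categories actually observed to `0..k-1` (e.g. observed
#' codes 0 and 2 become 0 and 1) and lowers `max_category` accordingly.
#' Needed before calibration when a category has zero observed count, since
#' the rating-scale thresholds of never-used categories are not estimable.
#'
#' @param x A [response_matrix].
#' @return A [response_matrix] with consecutively recoded categories.
#' @export
collapse_categories <- function(x) {
  stopifnot(inherits(x, "response_matrix"))
  obs <- sort(unique(x$values[!is.na(x$values)]))
  if (length(obs) < 2L) abort("fewer than 2 observed categories; nothing to scale")
  values <- matrix(match(x$values, obs) - 1L, nrow(x$values),
                   dimnames = dimnames(x$values))
  new_response_matrix(values, length(obs) - 1L, x$occasion)
}
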