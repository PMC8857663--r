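#' Build a blinded contour-review session
#'
#' Implements the blinded subjective-review protocol: per vertebral level a
#' fixed number of human-drawn and automatically generated contour slices
#' (default 3 + 3) are drawn from the supplied pools and presented in a
#' seeded random order. The blinding map (item -> source) is kept apart
#' from the presented item list and only rejoined at analysis time.
#'
#' @param human_pool,auto_pool Tibbles with columns `level_name` and
#'   `image_ref` (an opaque slice identifier/path), one pool per source.
#' @param per_level_human,per_level_auto Items per level per source.
#' @param levels Level names covered (default all of T1..L5).
#' @param seed Integer seed for sampling and presentation order.
#' @return A `review_session`: list with `items` (tibble `position`,
#'   `item_id`, `level_name`, `image_ref` — the blinded presentation) and
#'   `key` (tibble `item_id`, `source`).
#' @examples
#' pool <- tidyr::expand_grid(level_name = vertebra_levels()$name, rep = 1:3)
#' pool$image_ref <- paste0(pool$level_name, "_", pool$rep)
#' s <- build_review_session(pool, pool, seed = 1)
#' nrow(s$items)  # 17 levels x 6 slices = 102
#' @export
build_review_session <- function(human_pool, auto_pool, per_level_human = 3,
                                 per_level_auto = 3,
                                 levels = vertebra_levels()$name, seed = 1) {
  for (nm in c("level_name", "image_ref")) {
    if (!nm %in% names(human_pool) || !nm %in% names(auto_pool)) {
      stop("Pools need columns `level_name` and `image_ref`")
    }
  }
  withr::with_seed(as.integer(seed), {
    picks <- lapply(levels, function(lv) {
      h <- human_pool[human_pool$level_name == lv, , drop = FALSE]
      a <- auto_pool[auto_pool$level_name == lv, , drop = FALSE]
      if (nrow(h) < per_level_human || nrow(a) < per_level_auto) {
        stop("Insufficient pool at level ", lv, ": need ", per_level_human,
             " human and ", per_level_auto, " automatic slices")
      }
      dplyr::bind_rows(
        tibble::tibble(level_name = lv, source = "human",
                       image_ref = sample(h$image_ref, per_level_human)),
        tibble::tibble(level_name = lv, source = "automatic",
                       image_ref = sample(a$image_ref, per_level_auto))
      )
    })
    all <- dplyr::bind_rows(picks)
    all$item_id <- seq_len(nrow(all))
    ord <- sample.int(nrow(all))
    items <- all[ord, c("item_id", "level_name", "image_ref")]
    items$position <- seq_len(nrow(items))
    structure(list(
      items = items[, c("position", "item_id", "level_name", "image_ref")],
      key = all[, c("item_id", "source")],
      seed = as.integer(seed)
    ), class = "review_session")
  })
}

#' @export
print.review_session <- function(x, ...) {
  cat("<review_session> ", nrow(x$items), " blinded items (seed ", x$seed,
      ")\n", sep = "")
  invisible(x)
}

#' Write a review session to disk
#'
#' The presented item list and the blinding key go to two separate JSON
#' files so the session can be administered without revealing sources.
#'
#' @param session A `review_session`.
#' @param items_path,key_path Output JSON paths.
#' @export
write_review_session <- function(session, items_path, key_path) {
  stopifnot(inherits(session, "review_session"))
  jsonlite::write_json(session$items, items_path, dataframe = "rows")
  jsonlite::write_json(session$key, key_path, dataframe = "rows")
  invisible(c(items_path, key_path))
}

#' Analyze a completed review session
#'
#' Joins responses to the blinding key and summarizes: how often raters
#' identified the true source; the rating distribution per source on the
#' 4-point scale (1 = large obvious errors, 2 = minor errors needing
#' correction for high-precision radiotherapy, 3 = minor clinically
#' non-significant errors, 4 = precise); clinical acceptability (rating 3
#' or 4) per source; and chi-squared tests on the source-by-guess (2x2,
#' continuity-corrected by default) and source-by-rating tables. Degenerate
#' tables (a zero margin) are flagged instead of tested.
#'
#' @param session A `review_session`.
#' @param responses Tibble with `item_id` (or `position`), `guess`
#'   ("human"/"automatic") and `rating` (1..4), one row per item.
#' @param correct Continuity correction for the 2x2 guess table.
#' @return A `review_analysis` list: `identification` (one-row tibble),
#'   `ratings` (per source x rating counts), `acceptability` (per source),
#'   and `tests` (tibble of chi-squared results).
#' @export
analyze_review <- function(session, responses, correct = TRUE) {
  stopifnot(inherits(session, "review_session"))
  if (!"item_id" %in% names(responses)) {
    if (!"position" %in% names(responses)) {
      stop("Responses need `item_id` or `position`")
    }
    responses <- dplyr::left_join(responses,
                                  session$items[, c("position", "item_id")],
                                  by = "position")
  }
  if (!all(session$key$item_id %in% responses$item_id)) {
    stop("Unanswered items: every session item needs a response")
  }
  if (!all(responses$rating %in% 1:4)) stop("Ratings must be in 1..4")
  if (!all(responses$guess %in% c("human", "automatic"))) {
    stop('Guesses must be "human" or "automatic"')
  }
  df <- dplyr::inner_join(session$key, responses, by = "item_id")

  ident <- tibble::tibble(
    n = nrow(df),
    n_correct = sum(df$guess == df$source),
    accuracy = mean(df$guess == df$source)
  )
  ratings <- dplyr::count(df, .data$source,
                          rating = factor(.data$rating, levels = 1:4),
                          .drop = FALSE)
  accept <- dplyr::summarise(
    dplyr::group_by(df, .data$source),
    n = dplyr::n(),
    acceptable = mean(.data$rating >= 3),
    precise = mean(.data$rating == 4),
    obvious_errors = mean(.data$rating == 1),
    .groups = "drop"
  )

  guess_tab <- table(df$source, df$guess)
  rating_tab <- table(df$source, factor(df$rating, levels = 1:4))
  tests <- dplyr::bind_rows(
    chisq_row("source_vs_guess", guess_tab, correct = correct),
    chisq_row("source_vs_rating", rating_tab[, colSums(rating_tab) > 0,
                                             drop = FALSE], correct = FALSE)
  )
  structure(list(identification = ident, ratings = ratings,
                 acceptability = accept, tests = tests),
            class = "review_analysis")
}

chisq_row <- function(name, tab, correct) {
  degenerate <- any(dim(tab) < 2L) || any(rowSums(tab) == 0) ||
    any(colSums(tab) == 0)
  if (degenerate) {
    return(tibble::tibble(comparison = name, statistic = NA_real_,
                          df = NA_real_, p_value = NA_real_,
                          degenerate = TRUE))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  tibble::tibble(comparison = name, statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 degenerate = FALSE)
}

#' @export
print.review_analysis <- function(x, ...) {
  cat("<review_analysis>\n  identification accuracy: ",
      sprintf("%.3f", x$identification$accuracy), " (n = ",
      x$identification$n, ")\n", sep = "")
  print(x$acceptability)
  invisible(x)
}
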