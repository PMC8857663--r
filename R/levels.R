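#' Vertebral-level code table
#'
#' The thoracolumbar levels handled by the package form a fixed total order
#' T1 < T2 < ... < T12 < L1 < ... < L5, coded 1..17 in labelmaps
#' (0 is background). These helpers convert between integer codes and
#' anatomical names.
#'
#' @return `vertebra_levels()` returns a tibble with columns `code` (1..17)
#'   and `name` ("T1".."T12", "L1".."L5").
#' @examples
#' vertebra_levels()
#' level_code("L1")
#' level_name(13)
#' @export
vertebra_levels <- function() {
  tibble::tibble(
    code = 1:17,
    name = c(paste0("T", 1:12), paste0("L", 1:5))
  )
}

#' @rdname vertebra_levels
#' @param name Character vector of level names ("T1".."T12", "L1".."L5").
#' @export
level_code <- function(name) {
  tab <- vertebra_levels()
  idx <- match(toupper(name), tab$name)
  if (anyNA(idx)) {
    stop("Unknown vertebral level name(s): ",
         paste(name[is.na(idx)], collapse = ", "))
  }
  tab$code[idx]
}

#' @rdname vertebra_levels
#' @param code Integer vector of level codes (1..17).
#' @export
level_name <- function(code) {
  if (any(!is.finite(code)) || any(code < 1L | code > 17L)) {
    stop("Vertebral level codes must lie in 1..17")
  }
  vertebra_levels()$name[as.integer(code)]
}

n_levels_from <- function(first_code) 17L - as.integer(first_code) + 1L
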