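#' Match predicted instances to ground truth and score each vertebra
#'
#' Each ground-truth vertebra (excluding edge-contacting, partially visible
#' ones when `exclude_partial`) is matched to the predicted instance of
#' maximal voxel overlap (ties broken by centroid distance). Per vertebra
#' the table records Dice and Hausdorff distance against the matched
#' instance, whether the assigned level is correct, and — when a contiguous
#' run of at least two consecutive vertebrae is off by the same signed
#' level count next to a merge or a missing match — the `offset_attributed`
#' flag: those vertebrae are scored geometrically as if their labels were
#' correct, while the vertebrae causing the offset (the merged/missing
#' ones) are not offset-eligible. Unmatched vertebrae score Dice 0 with the
#' Hausdorff distance flagged missing.
#'
#' @param pred A `labeled_instance_seg` (from [sequential_approach()] or
#'   [combined_approach()]).
#' @param gt Instance-coded ground-truth [labelmap3d()].
#' @param gt_levels Ground-truth instance-to-level tibble
#'   (see [generate_phantom()]).
#' @param exclude_partial Drop edge-contacting ground-truth vertebrae from
#'   scoring (they are excluded from quantitative evaluation).
#' @return A `metrics_tbl` tibble, one row per scored vertebra: true and
#'   predicted level, `label_correct`, `offset`, `offset_attributed`,
#'   `merge_involved`, `dsc`, `hd_mm`, `hd_missing`, voxel counts.
#' @export
match_and_score <- function(pred, gt, gt_levels, exclude_partial = TRUE) {
  stopifnot(inherits(pred, "labeled_instance_seg"),
            inherits(gt, "labelmap3d"), gt$semantics == "instance")
  if (!identical(dim(pred$labels), dim(gt$values))) {
    stop("Grids are misaligned: shapes differ")
  }
  sp <- gt$spacing
  keep <- gt_levels
  if (exclude_partial) keep <- keep[!keep$edge_contact, , drop = FALSE]
  if (!nrow(keep)) stop("No fully visible ground-truth vertebrae to score")

  pred_tab <- pred$table
  rows <- lapply(seq_len(nrow(keep)), function(r) {
    gid <- keep$instance_id[r]
    gmask <- gt$values == gid
    over <- pred$labels[gmask]
    over <- over[over > 0L]
    if (!length(over)) {
      return(tibble::tibble(
        gt_instance_id = gid, matched_pred_id = NA_integer_,
        true_level_code = keep$level_code[r], pred_level_code = NA_integer_,
        n_voxels_gt = sum(gmask), n_voxels_pred = 0L,
        dsc = 0, hd_mm = NA_real_, hd_missing = TRUE
      ))
    }
    counts <- table(over)
    best <- as.integer(names(counts)[counts == max(counts)])
    if (length(best) > 1L) {
      gctr <- colMeans(arrayInd(which(gmask), dim(gmask))) * sp
      cdist <- vapply(best, function(bid) {
        pr <- pred_tab[pred_tab$instance_id == bid, ]
        sqrt(sum((c(pr$centroid_x_mm, pr$centroid_y_mm, pr$centroid_z_mm) -
                    gctr)^2))
      }, numeric(1))
      best <- best[order(cdist, best)][1]
    }
    pmask <- pred$labels == best
    tibble::tibble(
      gt_instance_id = gid, matched_pred_id = best,
      true_level_code = keep$level_code[r],
      pred_level_code = pred_tab$level_code[pred_tab$instance_id == best],
      n_voxels_gt = sum(gmask), n_voxels_pred = sum(pmask),
      dsc = dice(gmask, pmask),
      hd_mm = hausdorff(gmask, pmask, sp), hd_missing = FALSE
    )
  })
  m <- dplyr::bind_rows(rows)
  m <- m[order(m$true_level_code), ]

  # merge bookkeeping: a predicted instance claimed by >= 2 gt vertebrae
  shared <- table(m$matched_pred_id[!is.na(m$matched_pred_id)])
  m$merge_involved <- !is.na(m$matched_pred_id) &
    m$matched_pred_id %in% as.integer(names(shared)[shared >= 2L])
  m$offset <- m$pred_level_code - m$true_level_code
  m$label_correct <- !is.na(m$offset) & m$offset == 0L
  m$offset_attributed <- detect_offset_runs(m)

  m$true_level <- level_name(m$true_level_code)
  m$pred_level <- NA_character_
  ok <- !is.na(m$pred_level_code) & m$pred_level_code >= 1L &
    m$pred_level_code <= 17L
  m$pred_level[ok] <- level_name(m$pred_level_code[ok])
  m <- m[, c("gt_instance_id", "matched_pred_id", "true_level_code",
             "true_level", "pred_level_code", "pred_level", "label_correct",
             "offset", "offset_attributed", "merge_involved", "dsc", "hd_mm",
             "hd_missing", "n_voxels_gt", "n_voxels_pred")]
  class(m) <- c("metrics_tbl", class(m))
  attr(m, "spacing") <- sp
  m
}

# Maximal runs (in craniocaudal/true-level order) of >= 2 rows sharing one
# signed nonzero offset, adjacent to a merge or missing-match discrepancy.
# Rows inside the causal merge are not offset-eligible.
detect_offset_runs <- function(m) {
  n <- nrow(m)
  out <- rep(FALSE, n)
  eligible <- !is.na(m$offset) & m$offset != 0L & !m$merge_involved
  causal <- m$merge_involved | is.na(m$matched_pred_id)
  i <- 1L
  while (i <= n) {
    if (!eligible[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && eligible[j + 1L] && m$offset[j + 1L] == m$offset[i]) {
      j <- j + 1L
    }
    if (j - i + 1L >= 2L) {
      touches_cause <- (i > 1L && causal[i - 1L]) || (j < n && causal[j + 1L])
      if (touches_cause) out[i:j] <- TRUE
    }
    i <- j + 1L
  }
  out
}

#' Proportion of correctly labeled vertebrae
#'
#' Labeling accuracy with a Wilson score confidence interval.
#'
#' @param m A `metrics_tbl` from [match_and_score()].
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `n`, `n_correct`, `accuracy`, `ci_low`,
#'   `ci_high`, `ci_method`.
#' @export
labeling_accuracy <- function(m, conf_level = 0.95) {
  if (!nrow(m)) stop("Empty metrics table")
  n <- nrow(m)
  k <- sum(m$label_correct)
  p <- k / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(n = n, n_correct = k, accuracy = p,
                 ci_low = max(0, center - half),
                 ci_high = min(1, center + half),
                 ci_method = "wilson")
}

#' Paired comparison of per-vertebra metrics
#'
#' Two-sided Wilcoxon signed-rank test on paired per-vertebra values (e.g.
#' Dice of two approaches on the same vertebrae). Zero differences are
#' handled by the Pratt method by default (zeros enter the ranking of
#' absolute differences, their signed ranks are discarded; normal
#' approximation with tie and zero corrections). `zero_policy = "wilcoxon"`
#' drops zeros first and defers to [stats::wilcox.test()] (exact for small
#' tie-free samples). If all differences are zero the p-value is reported
#' as 1 with `all_zero = TRUE`.
#'
#' @param metric_a,metric_b Equal-length paired numeric vectors.
#' @param zero_policy "pratt" or "wilcoxon".
#' @return One-row tibble: `statistic` (V, sum of positive signed ranks),
#'   `p_value`, `n`, `n_zero`, `method`, `all_zero`.
#' @export
compare_paired <- function(metric_a, metric_b,
                           zero_policy = c("pratt", "wilcoxon")) {
  zero_policy <- match.arg(zero_policy)
  if (length(metric_a) != length(metric_b)) {
    stop("Paired samples must have equal length")
  }
  d <- metric_a - metric_b
  d <- d[!is.na(d)]
  n <- length(d)
  if (!n) stop("No complete pairs")
  if (all(d == 0)) {
    return(tibble::tibble(statistic = NA_real_, p_value = 1, n = n,
                          n_zero = n, method = paste0("signed-rank/", zero_policy),
                          all_zero = TRUE))
  }
  if (zero_policy == "wilcoxon") {
    dz <- d[d != 0]
    ht <- suppressWarnings(stats::wilcox.test(dz, mu = 0))
    return(tibble::tibble(statistic = unname(ht$statistic),
                          p_value = ht$p.value, n = n, n_zero = sum(d == 0),
                          method = "signed-rank/wilcoxon (zeros dropped)",
                          all_zero = FALSE))
  }
  # Pratt: rank |d| including zeros, discard zero ranks from the statistic
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  n0 <- sum(d == 0)
  e_v <- n * (n + 1) / 4 - n0 * (n0 + 1) / 4
  ties <- table(abs(d)[d != 0])
  var_v <- n * (n + 1) * (2 * n + 1) / 24 -
    n0 * (n0 + 1) * (2 * n0 + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- (v - e_v) / sqrt(var_v)
  tibble::tibble(statistic = v, p_value = 2 * stats::pnorm(-abs(z)), n = n,
                 n_zero = n0, method = "signed-rank/pratt (normal approx.)",
                 all_zero = FALSE)
}
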