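# Independent brute-force oracles (plain R, no package internals).

# Connected components by BFS flood fill.
brute_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  lab <- array(0L, d)
  nxt <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ind <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        p <- ind + as.integer(offs[r, ])
        if (any(p < 1L) || any(p > d)) next
        q <- p[1] + d[1] * ((p[2] - 1) + d[2] * (p[3] - 1))
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Surface voxels: foreground with a background 6-neighbor (or grid edge).
brute_surface <- function(mask) {
  d <- dim(mask)
  w <- which(mask, arr.ind = TRUE)
  is_surf <- vapply(seq_len(nrow(w)), function(r) {
    p <- w[r, ]
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      q <- p
      q[ax] <- q[ax] + s
      if (any(q < 1L) || any(q > d)) return(TRUE)
      if (!mask[q[1], q[2], q[3]]) return(TRUE)
    }
    FALSE
  }, logical(1))
  w[is_surf, , drop = FALSE]
}

# All-pairs maximum Hausdorff distance over surface voxels.
brute_hausdorff <- function(a, b, spacing = c(1, 1, 1)) {
  sa <- brute_surface(a)
  sb <- brute_surface(b)
  d2 <- outer(sa[, 1] * spacing[1], sb[, 1] * spacing[1], `-`)^2 +
    outer(sa[, 2] * spacing[2], sb[, 2] * spacing[2], `-`)^2 +
    outer(sa[, 3] * spacing[3], sb[, 3] * spacing[3], `-`)^2
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

brute_dice <- function(a, b) {
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

random_mask <- function(d, density, seed) {
  withr::with_seed(seed, {
    m <- array(stats::runif(prod(d)) < density, d)
    if (!any(m)) m[sample(length(m), 1)] <- TRUE
    m
  })
}

# One cube instance at 2 mm spacing (8000 mm^3, passes candidate filtering)
# whose level prediction is split n_major/(1000 - n_major) between T7 and T8.
cube_inputs <- function(n_major) {
  bin <- array(0L, c(14, 14, 14))
  bin[3:12, 3:12, 3:12] <- 1L  # 1000 voxels
  lv <- array(0L, c(14, 14, 14))
  w <- which(bin == 1L)
  lv[w[seq_len(n_major)]] <- 7L
  lv[w[(n_major + 1):1000]] <- 8L
  list(binary = labelmap3d(bin, spacing = c(2, 2, 2), semantics = "binary"),
       level = labelmap3d(lv, spacing = c(2, 2, 2), semantics = "level"))
}

# A review pool with `per_level` slices per vertebral level.
make_pool <- function(per_level = 4, prefix = "img") {
  pool <- tidyr::expand_grid(level_name = vertebra_levels()$name,
                             rep = seq_len(per_level))
  pool$image_ref <- paste0(prefix, "_", pool$level_name, "_", pool$rep)
  pool
}
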