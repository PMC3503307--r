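# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each quantity by the most literal method
# available and share no code with the package internals.

# Build an airspace_map from a plain label matrix.
make_map <- function(lab, pixel_size_um = 1) {
  lungmorph:::relabel_map(matrix(as.integer(lab), nrow = nrow(lab)),
                          pixel_size_um)
}

# Rosin corner rule by exhaustive evaluation over every bin.
oracle_unimodal_threshold <- function(h) {
  peak <- which.max(h)
  nz <- which(h > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  tail_end <- if (peak - lo >= hi - peak) lo else hi
  if (tail_end == peak) return(peak - 1L)
  x1 <- peak; y1 <- h[peak]; x2 <- tail_end; y2 <- h[tail_end]
  best <- peak; best_d <- -1
  rng <- if (tail_end < peak) tail_end:peak else peak:tail_end
  for (i in rng) {
    d <- abs((x2 - x1) * (y1 - h[i]) - (x1 - i) * (y2 - y1)) /
      sqrt((x2 - x1)^2 + (y2 - y1)^2)
    if (d > best_d + 1e-12 ||
        (abs(d - best_d) <= 1e-12 && abs(i - peak) < abs(best - peak))) {
      best_d <- d; best <- i
    }
  }
  best - 1L
}

# Erosion by literal neighborhood sweep.
oracle_erode_square <- function(m, se_size) {
  r <- (se_size - 1) / 2
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (!m[i, j]) next
      ok <- TRUE
      for (di in -r:r) {
        for (dj in -r:r) {
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > nrow(m) || jj < 1 || jj > ncol(m) ||
              !m[ii, jj]) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      out[i, j] <- ok
    }
  }
  out
}

# Winding-number point-in-polygon (angle summation); boundary handled by
# an explicit on-segment test.
oracle_point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  on_seg <- function(p, a, b) {
    cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (abs(cross) > 1e-9) return(FALSE)
    dot <- (p[1] - a[1]) * (b[1] - a[1]) + (p[2] - a[2]) * (b[2] - a[2])
    len2 <- sum((b - a)^2)
    if (len2 == 0) return(all(abs(p - a) < 1e-9))
    dot >= -1e-9 && dot <= len2 + 1e-9
  }
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (on_seg(pt, poly[i, ], poly[j, ])) return(TRUE)
  }
  if (n < 3) return(FALSE)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(poly[i, 1] - pt[1], poly[i, 2] - pt[2])
    a2 <- atan2(poly[j, 1] - pt[1], poly[j, 2] - pt[2])
    da <- a2 - a1
    while (da > pi) da <- da - 2 * pi
    while (da < -pi) da <- da + 2 * pi
    total <- total + da
  }
  abs(total) > pi
}

# Two-sided Mann-Whitney p by enumeration of all pooled-data splits.
oracle_mw_permutation <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  u_of <- function(x, y) sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  u_obs <- u_of(a, b)
  splits <- utils::combn(n, n1)
  us <- apply(splits, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Probabilistic AUC: P(score_pos > score_neg) + 0.5 P(tie).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  (sum(outer(pos, neg, `>`)) + 0.5 * sum(outer(pos, neg, `==`))) /
    (length(pos) * length(neg))
}

# Match segmented regions to ground-truth labels by majority overlap.
match_regions <- function(map, truth_label_map) {
  vapply(seq_len(nrow(map$regions)), function(i) {
    tl <- truth_label_map[map$label_map == map$regions$label[i]]
    tl <- tl[tl > 0]
    if (!length(tl)) return(NA_integer_)
    as.integer(names(sort(table(tl), decreasing = TRUE))[1])
  }, integer(1))
}

# 4-neighbour boundary pixel count of each labeled truth region.
region_perimeters <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- lab
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  boundary <- (pad[1:nr, 2:(nc + 1)] != core) |
    (pad[3:(nr + 2), 2:(nc + 1)] != core) |
    (pad[2:(nr + 1), 1:nc] != core) |
    (pad[2:(nr + 1), 3:(nc + 2)] != core)
  k <- max(lab)
  vapply(seq_len(k), function(i) sum(boundary & core == i), numeric(1))
}
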