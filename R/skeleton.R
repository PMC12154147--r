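# Morphological thinning and skeleton-path utilities.
# No installed package provides 2-D skeletonization, so the classic
# Zhang-Suen iterative thinning is implemented here, vectorized over the
# whole image per iteration.

shift_mat <- function(M, dr, dc) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- M[rs - dr, cs - dc]
  out
}

#' Thin a binary mask to a one-pixel skeleton (Zhang-Suen)
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same size; the medial skeleton.
#' @export
thin_mask <- function(mask) {
  M <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P2 <- shift_mat(M, 1, 0); P3 <- shift_mat(M, 1, -1)
      P4 <- shift_mat(M, 0, -1); P5 <- shift_mat(M, -1, -1)
      P6 <- shift_mat(M, -1, 0); P7 <- shift_mat(M, -1, 1)
      P8 <- shift_mat(M, 0, 1); P9 <- shift_mat(M, 1, 1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (step == 1) {
        cond <- M == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- M == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) {
        M[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  M == 1L
}

# Order skeleton pixels into a path: start from an endpoint (a pixel with a
# single 8-neighbor) and walk to the nearest unvisited neighbor, preferring
# the straightest continuation. Adequate for the near-tubular components
# this package segments; branching skeletons yield the longest greedy walk.
order_skeleton <- function(coords) {
  n <- nrow(coords)
  if (n <= 2L) return(coords)
  key <- paste(coords[, 1], coords[, 2])
  idx <- stats::setNames(seq_len(n), key)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  nbrs <- function(i) {
    k <- paste(coords[i, 1] + offs$dr, coords[i, 2] + offs$dc)
    unname(idx[k[k %in% key]])
  }
  deg <- vapply(seq_len(n), function(i) length(nbrs(i)), integer(1))
  start <- if (any(deg == 1)) which(deg == 1)[1] else 1L
  visited <- rep(FALSE, n)
  path <- integer(0)
  cur <- start
  prev_dir <- c(0, 0)
  while (!is.na(cur)) {
    visited[cur] <- TRUE
    path <- c(path, cur)
    cand <- nbrs(cur)
    cand <- cand[!visited[cand]]
    if (length(cand) == 0) break
    if (length(cand) > 1 && any(prev_dir != 0)) {
      dirs <- cbind(coords[cand, 1] - coords[cur, 1], coords[cand, 2] - coords[cur, 2])
      score <- dirs %*% prev_dir
      cand <- cand[order(-score)]
    }
    nxt <- cand[1]
    prev_dir <- c(coords[nxt, 1] - coords[cur, 1], coords[nxt, 2] - coords[cur, 2])
    cur <- nxt
  }
  coords[path, , drop = FALSE]
}

# Bilinear interpolation of a matrix at fractional (row, col) positions;
# out-of-range queries clamp to the border.
bilinear <- function(M, r, c) {
  nr <- nrow(M); nc <- ncol(M)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  M[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    M[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    M[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    M[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# Moving-average smoothing of a path (n x 2 matrix), window must be odd.
smooth_path <- function(p, window = 9L) {
  n <- nrow(p)
  if (n < window) return(p)
  half <- window %/% 2
  sm <- p
  for (j in 1:2) {
    cs <- cumsum(c(0, p[, j]))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    sm[, j] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  sm
}

# Resample a polyline (n x 2) at equal arclength steps.
resample_path <- function(p, step) {
  seglen <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  if (total <= step) return(p[c(1, nrow(p)), , drop = FALSE])
  ss <- seq(0, total, by = step)
  out <- matrix(0, length(ss), 2)
  j <- 1L
  for (i in seq_along(ss)) {
    while (j < length(s) - 1L && s[j + 1] < ss[i]) j <- j + 1L
    f <- if (s[j + 1] > s[j]) (ss[i] - s[j]) / (s[j + 1] - s[j]) else 0
    out[i, ] <- p[j, ] + f * (p[j + 1, ] - p[j, ])
  }
  out
}
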