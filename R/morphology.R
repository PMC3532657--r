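# Small image-processing primitives shared by segmentation, classification and
# the resection loop. Pure R; frames in this package are small enough that
# vectorized passes and a stack-based flood fill are adequate.

#' Label connected components of a binary mask
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 4 or 8 (default 8, the convention used throughout).
#' @return Integer matrix of the same shape: 0 for background, 1..k for the
#'   components, with a `"sizes"` attribute giving pixel counts per label.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (!any(mask)) { attr(lab, "sizes") <- integer(0); return(lab) }
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else if (connectivity == 4L) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else stopf("connectivity must be 4 or 8")
  todo <- which(mask)
  sizes <- integer(0)
  k <- 0L
  stack <- integer(length(todo))
  for (s in todo) {
    if (lab[s] != 0L) next
    k <- k + 1L
    top <- 1L; stack[1L] <- s; lab[s] <- k
    size <- 0L
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      size <- size + 1L
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (j in seq_along(dr)) {
        r2 <- r + dr[j]; c2 <- cc + dc[j]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          q <- r2 + (c2 - 1L) * nr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- k
            top <- top + 1L; stack[top] <- q
          }
        }
      }
    }
    sizes[k] <- size
  }
  attr(lab, "sizes") <- sizes
  lab
}

#' Binary dilation by a Chebyshev (square) structuring element
#'
#' @param mask logical matrix.
#' @param radius dilation radius in pixels; 0 returns the mask unchanged.
#' @return Logical matrix.
#' @export
dilate_mask <- function(mask, radius = 1L) {
  mask <- mask != 0
  if (radius < 1) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (dr in -radius:radius) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rt <- max(1, 1 - dr):min(nr, nr - dr)
    for (dc in -radius:radius) {
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      ct <- max(1, 1 - dc):min(nc, nc - dc)
      out[rs, cs] <- out[rs, cs] | mask[rt, ct]
    }
  }
  out
}

# 3x3 median filter with replicated edges; rejects isolated hot/dead pixels
# ahead of minimum statistics.
median_filter3 <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  idx_r <- function(d) pmin(pmax(seq_len(nr) + d, 1L), nr)
  idx_c <- function(d) pmin(pmax(seq_len(nc) + d, 1L), nc)
  stack <- matrix(0, nr * nc, 9L)
  j <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    j <- j + 1L
    stack[, j] <- mat[idx_r(dr), idx_c(dc)]
  }
  out <- apply(stack, 1L, stats::median)
  matrix(out, nr, nc)
}

# Otsu's between-class-variance threshold on a numeric vector
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) stopf("degenerate (constant) image: no threshold exists")
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  mids[which.max(sigma_b)]
}

# pixel-center rasterization of a disc: pixel (r, c) is inside iff its center
# ((r-0.5)p, (c-0.5)p) lies within diameter/2 of (cy, cx) in um. A disc whose
# interior captures no pixel centre still claims the pixel containing its
# centre, so every object at least a pitch wide has >= 1 truth pixel.
disc_mask <- function(frame_shape, center_um, diameter_um, pixel_pitch) {
  nr <- frame_shape[1]; nc <- frame_shape[2]
  yc <- (seq_len(nr) - 0.5) * pixel_pitch
  xc <- (seq_len(nc) - 0.5) * pixel_pitch
  m <- outer((yc - center_um[1])^2, (xc - center_um[2])^2, "+") <= (diameter_um / 2)^2
  if (!any(m) && diameter_um > 0) {
    r <- min(max(ceiling(center_um[1] / pixel_pitch), 1L), nr)
    cc <- min(max(ceiling(center_um[2] / pixel_pitch), 1L), nc)
    m[r, cc] <- TRUE
  }
  m
}
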