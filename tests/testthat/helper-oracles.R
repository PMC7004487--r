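# Independent brute-force oracles used to pin down the image operations.
# These deliberately re-derive every definition with naive loops rather than
# calling any package code path they are checking.

# grey-scale opening with a non-flat ball SE: b(d) = sqrt(r^2-|d|^2) - r
oracle_ball_opening <- function(img, radius) {
  ny <- nrow(img); nx <- ncol(img)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  h <- sqrt(radius^2 - offs$dy^2 - offs$dx^2) - radius
  ero <- matrix(NA_real_, ny, nx)
  for (y in 1:ny) for (x in 1:nx) {
    yy <- y + offs$dy; xx <- x + offs$dx
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    ero[y, x] <- min(img[cbind(yy[ok], xx[ok])] - h[ok])
  }
  dil <- matrix(NA_real_, ny, nx)
  for (y in 1:ny) for (x in 1:nx) {
    yy <- y + offs$dy; xx <- x + offs$dx
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    dil[y, x] <- max(ero[cbind(yy[ok], xx[ok])] + h[ok])
  }
  dil
}

# disk median with half-sample symmetric reflection at the edges
oracle_median_disk <- function(img, radius) {
  ny <- nrow(img); nx <- ncol(img)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i <- ifelse(i < 1, 1 - i, i)
      i <- ifelse(i > n, 2 * n + 1 - i, i)
    }
    i
  }
  out <- matrix(NA_real_, ny, nx)
  for (y in 1:ny) for (x in 1:nx) {
    yy <- refl(y + offs$dy, ny); xx <- refl(x + offs$dx, nx)
    out[y, x] <- median(img[cbind(yy, xx)])
  }
  out
}

# exhaustive Otsu on an integer-valued 8-bit stack: for every candidate
# threshold t, split values into {<= t} and {> t} and compute the
# between-class variance directly; return the smallest maximizer.
oracle_otsu_8bit <- function(values) {
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 0:254) {
    lo <- values[values <= t]; hi <- values[values > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(values)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-9) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# small random 8-bit test stack wrapped as an image_stack
random_stack <- function(dims, values, name = "ch") {
  arr <- array(values, dim = dims)
  image_stack(setNames(list(arr), name), bit_depth = 8)
}

# expected per-plane profile count from simulator ground truth: marker-type
# cells whose rasterized nucleus intersects the plane
expected_profile_count <- function(truth, bud, z) {
  cells <- truth$cells[truth$cells$type == "type3" & truth$cells$bud == bud, ]
  sum(cells$nuc_zmin <= z & cells$nuc_zmax >= z, na.rm = TRUE)
}
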