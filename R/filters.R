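# Internal 3-D image filtering primitives. Volumes are (z, y, x) arrays.

# 1-D Gaussian kernel, radius 3*sigma, normalized
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# convolution along one axis via a banded matrix with replicate padding
conv_axis <- function(vol, kernel, axis) {
  d <- dim(vol)
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  # build n x n operator with replicate (clamp-to-edge) boundary
  M <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    M[cbind(seq_len(n), idx)] <- M[cbind(seq_len(n), idx)] + kernel[j]
  }
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  v <- aperm(vol, perm)
  dv <- dim(v)
  v <- M %*% matrix(v, dv[1], dv[2] * dv[3])
  dim(v) <- dv
  aperm(v, order(perm))
}

# separable Gaussian blur with per-axis sigmas in voxels (z, y, x order)
gauss_blur3 <- function(vol, sigma_vox) {
  out <- vol
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) out <- conv_axis(out, gauss_kernel(sigma_vox[ax]), ax)
  }
  out
}

# shift a 3-D array by (dz, dy, dx), padding with `fill`
shift3 <- function(vol, dz, dy, dx, fill = -Inf) {
  d <- dim(vol)
  out <- array(fill, d)
  src <- function(n, s) {
    if (s >= 0) list(from = seq_len(n - s), to = seq_len(n - s) + s)
    else list(from = seq_len(n + s) - s, to = seq_len(n + s))
  }
  sz <- src(d[1], dz); sy <- src(d[2], dy); sx <- src(d[3], dx)
  if (length(sz$from) && length(sy$from) && length(sx$from)) {
    out[sz$to, sy$to, sx$to] <- vol[sz$from, sy$from, sx$from]
  }
  out
}

# scale-normalized negative Laplacian of the Gaussian-blurred volume;
# positive at bright blobs of scale ~ sigma_vox
log_response <- function(vol, sigma_vox) {
  sm <- gauss_blur3(vol, sigma_vox)
  resp <- array(0, dim(vol))
  offs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (ax in 1:3) {
    o <- offs[[ax]]
    second <- shift3(sm, o[1], o[2], o[3], fill = NA) +
      shift3(sm, -o[1], -o[2], -o[3], fill = NA) - 2 * sm
    second[is.na(second)] <- 0
    resp <- resp - sigma_vox[ax]^2 * second
  }
  resp
}

# strict-ish 26-neighbourhood local maxima above `threshold`
local_maxima3 <- function(vol, threshold) {
  is_max <- vol >= threshold
  if (!any(is_max)) return(matrix(integer(), 0, 3))
  for (a in -1:1) for (b in -1:1) for (c in -1:1) {
    if (a == 0 && b == 0 && c == 0) next
    if (!any(is_max)) break
    is_max <- is_max & (vol >= shift3(vol, a, b, c, fill = -Inf))
  }
  which(is_max, arr.ind = TRUE)  # columns iz, iy, ix
}

# Otsu threshold from a 256-bin histogram (maximizes between-class variance);
# no installed package offers an n-D Otsu on plain arrays, so it is inlined.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) <= 0) return(NA_real_)
  h <- tabulate(pmin(pmax(
    findInterval(x, seq(rng[1], rng[2], length.out = n_bins + 1L),
                 all.inside = TRUE), 1L), n_bins), nbins = n_bins)
  p <- h / sum(h)
  mids <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (mids[-1] + mids[-length(mids)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# 26-connected components of a logical 3-D mask -> integer label array
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- .label_components_3d(as.logical(mask), as.integer(d),
                              as.integer(connectivity))
  array(lab, d)
}

# anisotropic distance-to-background (um) inside a 3-D mask
mask_distance <- function(mask, voxel_size) {
  d <- dim(mask)
  array(.chamfer_distance_3d(as.logical(mask), as.integer(d),
                             as.numeric(voxel_size)), d)
}
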