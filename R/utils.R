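# Shared numerical helpers: FFT Gaussian smoothing, finite differences,
# connected components, binary morphology. All operate on bare 3D arrays.

# Circular (periodic) separable Gaussian smoothing via FFT. Periodic
# wrap-around is acceptable here because smoothed fields are only used as
# random warps; the kernel is normalized to unit sum so the field variance
# is controlled.
smooth_gaussian3 <- function(a, sigma_vox) {
  d <- dim(a)
  f <- stats::fft(a)
  for (ax in 1:3) {
    n <- d[ax]
    x <- ((seq_len(n) - 1 + n %/% 2) %% n) - n %/% 2
    k <- exp(-x^2 / (2 * sigma_vox^2))
    k <- k / sum(k)
    fk <- Re(stats::fft(k))
    rep_each <- prod(d[seq_len(ax - 1)])
    f <- f * rep(fk, each = rep_each)
  }
  Re(stats::fft(f, inverse = TRUE)) / prod(d)
}

# Finite-difference derivative of a 3D array along one axis in physical
# units: central differences on interior planes, one-sided at the two
# boundary planes.
fd_derivative <- function(a, axis, h) {
  d <- dim(a)
  n <- d[axis]
  if (n < 3L) stop("grid must have at least 3 voxels along each axis")
  take <- function(i) {
    idx <- rep(list(quote(expr = )), 3L)
    idx[[axis]] <- i
    out <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    out
  }
  g <- array(0, d)
  assign_slab <- function(g, i, val) {
    idx <- rep(list(quote(expr = )), 3L)
    idx[[axis]] <- i
    do.call(`[<-`, c(list(g), idx, list(val)))
  }
  g <- assign_slab(g, 2:(n - 1), (take(3:n) - take(1:(n - 2))) / (2 * h))
  g <- assign_slab(g, 1L, (take(2L) - take(1L)) / h)
  g <- assign_slab(g, n, (take(n) - take(n - 1L)) / h)
  g
}

# Neighbour offset table for 6/18/26 3D connectivity.
neighbor_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  s <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = s == 1, "18" = s >= 1 & s <= 2, "26" = s >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

# Connected-component labelling of a logical 3D array by breadth-first
# search over an explicit frontier. Returns an integer array of labels
# (0 = background).
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- neighbor_offsets(connectivity)
  lab <- array(0L, d)
  seeds <- which(mask)
  n1 <- d[1]; n12 <- d[1] * d[2]
  cur <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier) > 0) {
      co <- arrayInd(frontier, d)
      nb <- matrix(0L, nrow(co) * nrow(offs), 3)
      for (j in 1:3)
        nb[, j] <- rep(co[, j], each = nrow(offs)) + rep(offs[, j], nrow(co))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + (nb[, 2] - 1L) * n1 + (nb[, 3] - 1L) * n12)
      lin <- lin[mask[lin] & lab[lin] == 0L]
      lab[lin] <- cur
      frontier <- lin
    }
  }
  lab
}

# Shift a 3D array by k voxels along an axis, padding with `fill`.
shift_array <- function(a, axis, k, fill = FALSE) {
  d <- dim(a)
  n <- d[axis]
  if (k == 0) return(a)
  out <- array(fill, d)
  src <- if (k > 0) 1:(n - k) else (1 - k):n
  dst <- if (k > 0) (1 + k):n else 1:(n + k)
  if (length(src) <= 0) return(out)
  idx_src <- rep(list(quote(expr = )), 3L); idx_src[[axis]] <- src
  idx_dst <- rep(list(quote(expr = )), 3L); idx_dst[[axis]] <- dst
  do.call(`[<-`, c(list(out), idx_dst,
                   list(do.call(`[`, c(list(a), idx_src, list(drop = FALSE))))))
}

# Chebyshev (cube) binary dilation with radius r, as a separable running OR.
dilate_cube <- function(mask, r) {
  if (r == 0) return(mask)
  out <- mask
  for (ax in 1:3) {
    acc <- out
    for (k in seq_len(r)) {
      acc <- acc | shift_array(out, ax, k) | shift_array(out, ax, -k)
    }
    out <- acc
  }
  out
}
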