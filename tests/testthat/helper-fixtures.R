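# Shared fixtures: a small atlas for fast tests and independent oracle
# implementations used to cross-check the vectorized pipeline code.

small_atlas_spec <- function() {
  shape <- c(32L, 40L, 24L)
  mid <- (shape[1] - 1) / 2
  atlas_spec(
    shape = shape, spacing = c(2, 2, 2),
    divisions = data.frame(
      name = c("Pallium", "TeO_L", "TeO_R", "LCeP_L", "LCeP_R", "Medulla"),
      cx = c(mid, 7, 2 * mid - 7, 8, 2 * mid - 8, mid),
      cy = c(7, 18, 18, 29, 29, 36),
      cz = c(12, 14, 14, 11, 11, 9),
      rx = c(6, 5, 5, 4, 4, 4),
      ry = c(5, 4, 4, 4, 4, 3),
      rz = c(6, 4, 4, 4, 4, 3)),
    envelope = list(center = (shape - 1) / 2, radii = c(14, 19, 11)))
}

small_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_atlas(small_atlas_spec())
    cache
  }
})

small_cohort_spec <- function(...) {
  cohort_spec(n_per_group = c(control = 4L, crispant = 4L), ...)
}

# Independent Jacobian oracle: per-voxel determinant of I + grad(u), with
# the gradient assembled voxel by voxel from explicitly indexed finite
# differences and the determinant evaluated by base::det on a 3x3 matrix.
# Deliberately loop-based and separate from the package's vectorized path.
jacobian_oracle <- function(field, voxels) {
  sp <- attr(field, "spacing")
  d <- dim(field)[1:3]
  u <- array(as.vector(field), dim(field))
  vapply(seq_len(nrow(voxels)), function(r) {
    v <- voxels[r, ]
    G <- matrix(0, 3, 3)
    for (i in 1:3) {
      for (j in 1:3) {
        lo <- v; hi <- v
        if (v[j] > 1 && v[j] < d[j]) {
          lo[j] <- v[j] - 1; hi[j] <- v[j] + 1
          h <- 2 * sp[j]
        } else if (v[j] == 1) {
          hi[j] <- v[j] + 1; h <- sp[j]
        } else {
          lo[j] <- v[j] - 1; h <- sp[j]
        }
        G[i, j] <- (u[hi[1], hi[2], hi[3], i] - u[lo[1], lo[2], lo[3], i]) / h
      }
    }
    det(diag(3) + G)
  }, numeric(1))
}

# Vectorized but independently coded central-difference Jacobian over the
# full interior, using cofactor expansion along the THIRD row (the
# package expands along the first) and gradient slabs built with apply().
jacobian_oracle_dense <- function(field) {
  sp <- attr(field, "spacing")
  d <- dim(field)[1:3]
  grad <- function(comp, axis) {
    a <- array(as.vector(field), dim(field))[, , , comp]
    dim(a) <- d
    n <- d[axis]
    idx <- function(i) {
      ix <- list(1:d[1], 1:d[2], 1:d[3]); ix[[axis]] <- i
      a[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    }
    g <- array(NA_real_, d)
    ix <- list(1:d[1], 1:d[2], 1:d[3]); ix[[axis]] <- 2:(n - 1)
    g[ix[[1]], ix[[2]], ix[[3]]] <- (idx(3:n) - idx(1:(n - 2))) / (2 * sp[axis])
    g
  }
  G <- array(0, c(d, 3, 3))
  for (i in 1:3) for (j in 1:3) {
    G[, , , i, j] <- grad(i, j) + as.numeric(i == j)
  }
  # cofactor expansion along the third row
  G[, , , 3, 1] * (G[, , , 1, 2] * G[, , , 2, 3] -
                   G[, , , 1, 3] * G[, , , 2, 2]) -
  G[, , , 3, 2] * (G[, , , 1, 1] * G[, , , 2, 3] -
                   G[, , , 1, 3] * G[, , , 2, 1]) +
  G[, , , 3, 3] * (G[, , , 1, 1] * G[, , , 2, 2] -
                   G[, , , 1, 2] * G[, , , 2, 1])
}

# Independent step-up BH oracle (direct definition, no cummin trick in
# the same shape as p.adjust).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- p[o][i:m] * m / (i:m)
    adj[o[i]] <- min(1, min(cand))
  }
  adj
}

# Flood-fill component oracle by iterative dilation from each unvisited
# seed (algorithmically distinct from the package's BFS labelling).
components_oracle <- function(mask, connectivity) {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  s <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = s == 1, "18" = s >= 1 & s <= 2, s >= 1), ]
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  repeat {
    seed <- which(mask & lab == 0L)
    if (length(seed) == 0) break
    cur <- cur + 1L
    comp <- array(FALSE, d)
    comp[seed[1]] <- TRUE
    repeat {
      grown <- comp
      cc <- which(comp)
      co <- arrayInd(cc, d)
      for (r in seq_len(nrow(offs))) {
        nb <- sweep(co, 2, as.numeric(offs[r, ]), `+`)
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
              nb[, 2] >= 1 & nb[, 2] <= d[2] &
              nb[, 3] >= 1 & nb[, 3] <= d[3]
        nb <- nb[ok, , drop = FALSE]
        lin <- nb[, 1] + (nb[, 2] - 1) * d[1] + (nb[, 3] - 1) * d[1] * d[2]
        grown[lin[mask[lin]]] <- TRUE
      }
      if (identical(grown, comp)) break
      comp <- grown
    }
    lab[comp] <- cur
  }
  lab
}

# Brute-force symmetry-filter oracle: for every set voxel, scan the full
# cube window around its mirrored index.
bilateral_oracle <- function(mask, axis, tol) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (v in which(mask)) {
    co <- arrayInd(v, d)
    mc <- co
    mc[axis] <- d[axis] + 1 - co[axis]
    hit <- FALSE
    for (dx in -tol:tol) for (dy in -tol:tol) for (dz in -tol:tol) {
      q <- mc + c(dx, dy, dz)
      if (all(q >= 1) && all(q <= d) && mask[q[1], q[2], q[3]]) {
        hit <- TRUE; break
      }
    }
    out[v] <- hit
  }
  out
}

zero_field <- function(shape, spacing = c(2, 2, 2)) {
  cm_volume(array(0, c(shape, 3L)), spacing, "displacement")
}
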