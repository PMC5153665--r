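# Independent pure-R oracles and small fixture builders. The BFS labeller
# below shares no code with the package's C++ implementation.

# brute-force BFS connected-component labelling; numbering follows the
# first voxel of each object in linear (z-fastest, column-major) order
bfs_label_oracle <- function(mask, connectivity) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  labels <- array(0L, dims)
  k <- 0L
  for (lin in seq_along(mask)) {
    if (!mask[lin] || labels[lin] != 0L) next
    k <- k + 1L
    queue <- matrix(arrayInd(lin, dims), ncol = 3)
    labels[lin] <- k
    while (nrow(queue) > 0L) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (j in seq_len(nrow(offs))) {
        nb <- cur + offs[j, ]
        if (any(nb < 1L) || any(nb > dims)) next
        if (mask[nb[1], nb[2], nb[3]] &&
            labels[nb[1], nb[2], nb[3]] == 0L) {
          labels[nb[1], nb[2], nb[3]] <- k
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  attr(labels, "n_objects") <- k
  labels
}

# small isotropic test volume from explicit values
tiny_volume <- function(values, voxel_size = c(10, 10, 10), bit_depth = 8L) {
  volume_grid(values, voxel_size = voxel_size, bit_depth = bit_depth)
}

# mask with foreground at the given (z, y, x) index rows
mask_at <- function(dims, idx) {
  m <- array(FALSE, dims)
  for (i in seq_len(nrow(idx))) m[idx[i, 1], idx[i, 2], idx[i, 3]] <- TRUE
  m
}

# small fibsem-preset mitochondria phantom used across tests
small_mito_phantom <- function(seed = 1, n_objects = 5, n_speckle = 10,
                               n_fragments = 3, grid = c(64, 64, 64)) {
  spec <- phantom_preset("fibsem", grid_shape = grid, rng_seed = seed)
  list(spec = spec,
       phantom = make_mitochondria_phantom(
         spec, n_objects = n_objects, semi_axis_range = c(60, 100),
         n_speckle = n_speckle, n_membrane_fragments = n_fragments))
}

# rasterise a solid axis-aligned ellipsoid into a volume grid (label 200,
# background 0) on an isotropic grid; independent of the phantom generator
ellipsoid_volume <- function(semi_axes_nm, voxel_nm = 5, pad_nm = 20,
                             value = 200) {
  half <- max(semi_axes_nm) + pad_nm
  n <- ceiling(2 * half / voxel_nm)
  ctr <- rep(n / 2 * voxel_nm, 3)
  ax <- (seq_len(n) - 0.5) * voxel_nm
  Z <- array(ax - ctr[1], c(n, n, n))
  Y <- array(rep(ax - ctr[2], each = n), c(n, n, n))
  X <- array(rep(ax - ctr[3], each = n * n), c(n, n, n))
  inside <- (Z / semi_axes_nm[1])^2 + (Y / semi_axes_nm[2])^2 +
    (X / semi_axes_nm[3])^2 <= 1
  v <- array(0, c(n, n, n))
  v[inside] <- value
  volume_grid(v, voxel_size = rep(voxel_nm, 3))
}
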