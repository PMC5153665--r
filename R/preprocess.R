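# discrete normalised Gaussian kernel; radius 3*sigma, always odd length
gauss_kernel1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

#' Non-local means denoising of a volume
#'
#' 3D non-local means with a cubic patch (default 3^3) and search window
#' (default 7^3). The weight of a candidate voxel decays with the mean
#' squared difference between the two patches, offset by `2 * sigma^2` so
#' that differences explained by noise alone do not penalise the match
#' (`sigma` is the assumed noise standard deviation, as in the common
#' Fiji/scikit-image parameterisation). `sigma = 0` is the identity.
#' Output values never leave the bit-depth domain (weighted averages of
#' in-domain values).
#'
#' @param volume a `volume_grid`.
#' @param sigma assumed noise sd in intensity units; the filtering strength
#'   `h` defaults to `sigma`.
#' @param h filtering strength; larger smooths more.
#' @param patch_radius,search_radius window radii in voxels (defaults 1 and
#'   3, i.e. 3^3 patch in a 7^3 search window); recorded in provenance.
#' @return denoised `volume_grid`.
#' @export
denoise_nlm <- function(volume, sigma = 5, h = sigma, patch_radius = 1L,
                        search_radius = 3L) {
  stopifnot(inherits(volume, "volume_grid"))
  if (sigma < 0) stop("`sigma` must be >= 0")
  params <- list(sigma = sigma, h = h, patch_radius = patch_radius,
                 search_radius = search_radius)
  if (sigma == 0) return(add_provenance(volume, "nlm", params))
  dims <- grid_dims(volume)
  out <- nlm3_cpp(as.numeric(volume$values), dims, sigma, h,
                  as.integer(patch_radius), as.integer(search_radius))
  with_values(volume, array(out, dims), "nlm", params)
}

#' Gaussian smoothing in physical units
#'
#' Separable Gaussian blur whose scale is given in nanometres per axis and
#' converted to voxel units through the grid's voxel size, so anisotropic
#' voxels are smoothed isotropically in physical space. Boundary handling is
#' mirror reflection, under which the normalised symmetric kernel conserves
#' total intensity exactly.
#'
#' @param volume a `volume_grid` with known voxel size.
#' @param sigma_nm smoothing sd in nm; a scalar (isotropic in physical
#'   space) or a length-3 `(z, y, x)` vector. `0` is the identity.
#' @return smoothed `volume_grid`.
#' @export
gaussian_smooth <- function(volume, sigma_nm) {
  stopifnot(inherits(volume, "volume_grid"))
  sigma_nm <- rep_len(as.numeric(sigma_nm), 3L)
  if (any(sigma_nm < 0)) stop("`sigma_nm` must be >= 0")
  params <- list(sigma_nm = sigma_nm, boundary = "reflect")
  if (all(sigma_nm == 0)) return(add_provenance(volume, "gaussian", params))
  require_voxel_size(volume$voxel_size)
  dims <- grid_dims(volume)
  v <- as.numeric(volume$values)
  for (ax in 0:2) {
    k <- gauss_kernel1d(sigma_nm[ax + 1] / volume$voxel_size[ax + 1])
    if (length(k) > 1L) v <- conv1d_reflect_cpp(v, dims, k, ax)
  }
  vmax <- bit_max(volume$bit_depth)
  with_values(volume, array(pmin(pmax(v, 0), vmax), dims), "gaussian", params)
}

#' Unsharp-mask sharpening
#'
#' Presentation filter; not part of the tested segmentation pipeline and off
#' by default everywhere.
#'
#' @param volume a `volume_grid`.
#' @param sigma_nm blur scale of the subtracted low-pass, nm.
#' @param amount strength of the high-frequency boost.
#' @return sharpened `volume_grid`, clipped to the bit-depth domain.
#' @export
unsharp_mask <- function(volume, sigma_nm = 50, amount = 0.5) {
  stopifnot(inherits(volume, "volume_grid"))
  blur <- gaussian_smooth(volume, sigma_nm)
  vmax <- bit_max(volume$bit_depth)
  v <- volume$values + amount * (volume$values - blur$values)
  with_values(volume, array(pmin(pmax(v, 0), vmax), grid_dims(volume)),
              "unsharp", list(sigma_nm = sigma_nm, amount = amount))
}

#' Downsample a volume by block binning
#'
#' Each output voxel is the MEAN of a `(z, y, x)` factor block (mean, not
#' sum, so intensity ranges stay comparable before and after binning).
#' Trailing voxels that do not fill a complete block are dropped (output
#' shape is the floor division) and the voxel size is multiplied by the
#' factors. The in-plane 3 x 3 binning typical for SBEM datasets is
#' `factors = c(1, 3, 3)` in this `(z, y, x)` convention.
#'
#' @param volume a `volume_grid`.
#' @param factors integer binning factors `(z, y, x)`, each >= 1 and no
#'   larger than the corresponding grid extent.
#' @return binned `volume_grid`.
#' @export
bin_volume <- function(volume, factors = c(1L, 3L, 3L)) {
  stopifnot(inherits(volume, "volume_grid"))
  f <- as.integer(factors)
  if (length(f) != 3L || any(f < 1L)) stop("`factors` must be 3 integers >= 1")
  dims <- grid_dims(volume)
  if (any(f > dims))
    stop("binning factor exceeds the grid extent on some axis")
  if (all(f == 1L))
    return(add_provenance(volume, "bin", list(factors = f)))
  nd <- dims %/% f
  v <- volume$values[seq_len(nd[1] * f[1]), seq_len(nd[2] * f[2]),
                     seq_len(nd[3] * f[3]), drop = FALSE]
  # reduce one axis at a time: bring it to the front, average factor-blocks
  # with colMeans, permute back
  for (ax in 1:3) {
    if (f[ax] == 1L) next
    d <- dim(v)
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(v, perm)
    dim(v) <- c(f[ax], length(v) / f[ax])
    v <- colMeans(v)
    dim(v) <- c(d[ax] %/% f[ax], d[perm[2]], d[perm[3]])
    v <- aperm(v, order(perm))
  }
  out <- array(v, nd)
  res <- volume
  res$values <- out
  res$voxel_size <- volume$voxel_size * f
  add_provenance(res, "bin", list(factors = f))
}
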