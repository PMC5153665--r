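#' Specification of a synthetic labelled EM phantom
#'
#' Describes the geometry and intensity model of a phantom volume emulating
#' genetically labelled (DAB-filled) structures in a stained EM stack.
#' Labelled structures are HIGH intensity in the working representation
#' (raw EM data showing stain as dark can be inverted on read). The default
#' geometry is the anisotropic SBEM preset (6.3 x 6.3 nm in-plane, 50 nm
#' sections); `phantom_preset()` provides the other acquisition geometries.
#'
#' Labelled-voxel intensities are drawn from a Gaussian clamped to
#' `[label_mean - 2*label_sd, bit-max]`, so the "separating range"
#' `separating_range(spec)` contains every labelled voxel by construction
#' while background (mean `background_mean`, sd `background_sd`, at least
#' 4 background sds below the label mean) essentially never enters it.
#'
#' @param grid_shape integer voxel counts `(z, y, x)`.
#' @param voxel_size physical voxel extents `(z, y, x)` in nm.
#' @param bit_depth working intensity domain (8 or 16).
#' @param background_mean,background_sd background intensity model.
#' @param label_mean,label_sd labelled-structure intensity model;
#'   `label_mean - background_mean` must be at least `4 * background_sd` so
#'   a separating range exists.
#' @param membrane_intensity upper intensity of membrane-fragment voxels
#'   (defaults to the bit-depth maximum).
#' @param rng_seed integer; identical seeds give bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(256L, 256L, 256L),
                         voxel_size = c(50, 6.3, 6.3),
                         bit_depth = 8L,
                         background_mean = 100, background_sd = 10,
                         label_mean = 200, label_sd = 5,
                         membrane_intensity = NULL,
                         rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("`grid_shape` must be 3 positive voxel counts (z, y, x)")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive extents (z, y, x) in nm")
  bit_depth <- as.integer(bit_depth)
  vmax <- bit_max(bit_depth)
  if (is.null(membrane_intensity)) membrane_intensity <- vmax
  if (label_mean - background_mean < 4 * background_sd)
    stop("label_mean must exceed background_mean by at least 4*background_sd")
  if (label_mean + 2 * label_sd > vmax + label_sd)
    warning("label distribution presses against the bit-depth maximum")
  structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size,
         bit_depth = bit_depth,
         background_mean = background_mean, background_sd = background_sd,
         label_mean = label_mean, label_sd = label_sd,
         membrane_intensity = membrane_intensity,
         rng_seed = as.integer(rng_seed)),
    class = "phantom_spec")
}

#' Acquisition-geometry presets for phantom generation
#'
#' `"mito-sbem"`: anisotropic SBEM sections, 6.3 x 6.3 x 50 nm voxels.
#' `"neurite-sbem"`: SBEM at 10.5 x 10.5 x 25 nm.
#' `"fibsem"`: near-isotropic FIB-SEM at 10 nm.
#'
#' @param preset preset name.
#' @param grid_shape voxel counts `(z, y, x)`.
#' @param rng_seed integer seed.
#' @param ... further arguments to [phantom_spec()].
#' @export
phantom_preset <- function(preset = c("mito-sbem", "neurite-sbem", "fibsem"),
                           grid_shape = c(256L, 256L, 256L), rng_seed = 1L,
                           ...) {
  preset <- match.arg(preset)
  vs <- switch(preset,
    "mito-sbem"    = c(50, 6.3, 6.3),
    "neurite-sbem" = c(25, 10.5, 10.5),
    "fibsem"       = c(10, 10, 10))
  phantom_spec(grid_shape = grid_shape, voxel_size = vs, rng_seed = rng_seed,
               ...)
}

#' The separating intensity range of a phantom spec
#'
#' Closed interval `[label_mean - 2*label_sd, bit-max]`; by construction it
#' contains all labelled voxels and (to ~7 sigma) no background voxels.
#'
#' @param spec a `phantom_spec`.
#' @return an `intensity_range`.
#' @export
separating_range <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  intensity_range(spec$label_mean - 2 * spec$label_sd,
                  bit_max(spec$bit_depth))
}

new_phantom_truth <- function(masks, catalogue) {
  structure(list(masks = masks, catalogue = catalogue),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> classes:\n")
  for (cl in names(x$masks)) {
    n <- max(x$masks[[cl]])
    cat(sprintf("  %-20s %d object(s), %d voxels\n", cl, n,
                sum(x$masks[[cl]] > 0L)))
  }
  invisible(x)
}

#' Binary mask of one ground-truth class
#' @param truth a `phantom_truth`.
#' @param class_name class name, e.g. `"mitochondria"` or `"cell_1"`.
#' @export
truth_mask <- function(truth, class_name) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (!class_name %in% names(truth$masks))
    stop("unknown truth class: ", class_name)
  truth$masks[[class_name]] > 0L
}

# ---- internal geometry helpers ---------------------------------------------

# voxel index window covered by physical interval [c - h, c + h] (nm)
axis_window <- function(centre, half, extent, n) {
  i0 <- max(1L, as.integer(floor((centre - half) / extent + 0.5)))
  i1 <- min(n, as.integer(ceiling((centre + half) / extent + 0.5)))
  if (i0 > i1) integer(0) else i0:i1
}

# physical coordinates (nm) of voxel centres, per axis window
centre_coords <- function(idx, extent) (idx - 0.5) * extent

# linear indices of voxels in the (iz, iy, ix) window satisfying `inside`
window_linear <- function(iz, iy, ix, dims, inside) {
  n1 <- length(iz); n2 <- length(iy); n3 <- length(ix)
  loc <- which(inside)
  if (!length(loc)) return(integer(0))
  a <- arrayInd(loc, c(n1, n2, n3))
  iz[a[, 1]] + dims[1] * (iy[a[, 2]] - 1L) +
    dims[1] * dims[2] * (ix[a[, 3]] - 1L)
}

# uniformly random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# voxels inside a solid ellipsoid: centre (z,y,x) nm, semi-axes nm, rotation R
rasterise_ellipsoid <- function(dims, voxel_size, centre, semi_axes, rot) {
  h <- max(semi_axes)
  iz <- axis_window(centre[1], h, voxel_size[1], dims[1])
  iy <- axis_window(centre[2], h, voxel_size[2], dims[2])
  ix <- axis_window(centre[3], h, voxel_size[3], dims[3])
  if (!length(iz) || !length(iy) || !length(ix)) return(integer(0))
  n1 <- length(iz); n2 <- length(iy); n3 <- length(ix)
  Z <- array(centre_coords(iz, voxel_size[1]) - centre[1], c(n1, n2, n3))
  Y <- array(rep(centre_coords(iy, voxel_size[2]) - centre[2], each = n1),
             c(n1, n2, n3))
  X <- array(rep(centre_coords(ix, voxel_size[3]) - centre[3],
                 each = n1 * n2), c(n1, n2, n3))
  q1 <- (rot[1, 1] * Z + rot[2, 1] * Y + rot[3, 1] * X) / semi_axes[1]
  q2 <- (rot[1, 2] * Z + rot[2, 2] * Y + rot[3, 2] * X) / semi_axes[2]
  q3 <- (rot[1, 3] * Z + rot[2, 3] * Y + rot[3, 3] * X) / semi_axes[3]
  window_linear(iz, iy, ix, dims, q1^2 + q2^2 + q3^2 <= 1)
}

# voxels within `radius` nm of the segment p0--p1 (a capsule; p0 == p1 is a
# sphere)
rasterise_capsule <- function(dims, voxel_size, p0, p1, radius) {
  lo <- pmin(p0, p1) - radius
  hi <- pmax(p0, p1) + radius
  ctr <- (lo + hi) / 2
  half <- (hi - lo) / 2
  iz <- axis_window(ctr[1], half[1], voxel_size[1], dims[1])
  iy <- axis_window(ctr[2], half[2], voxel_size[2], dims[2])
  ix <- axis_window(ctr[3], half[3], voxel_size[3], dims[3])
  if (!length(iz) || !length(iy) || !length(ix)) return(integer(0))
  n1 <- length(iz); n2 <- length(iy); n3 <- length(ix)
  Z <- array(centre_coords(iz, voxel_size[1]), c(n1, n2, n3))
  Y <- array(rep(centre_coords(iy, voxel_size[2]), each = n1), c(n1, n2, n3))
  X <- array(rep(centre_coords(ix, voxel_size[3]), each = n1 * n2),
             c(n1, n2, n3))
  d <- p1 - p0
  dd <- sum(d^2)
  if (dd == 0) {
    dist2 <- (Z - p0[1])^2 + (Y - p0[2])^2 + (X - p0[3])^2
  } else {
    t <- ((Z - p0[1]) * d[1] + (Y - p0[2]) * d[2] + (X - p0[3]) * d[3]) / dd
    t <- pmin(pmax(t, 0), 1)
    dist2 <- (Z - p0[1] - t * d[1])^2 + (Y - p0[2] - t * d[2])^2 +
      (X - p0[3] - t * d[3])^2
  }
  window_linear(iz, iy, ix, dims, dist2 <= radius^2)
}

# single-z-slice elliptical patch (membrane fragment): in-plane rotation
rasterise_patch <- function(dims, voxel_size, z_index, centre_yx, semi_yx,
                            angle) {
  iy <- axis_window(centre_yx[1], max(semi_yx), voxel_size[2], dims[2])
  ix <- axis_window(centre_yx[2], max(semi_yx), voxel_size[3], dims[3])
  if (!length(iy) || !length(ix)) return(integer(0))
  Y <- outer(centre_coords(iy, voxel_size[2]) - centre_yx[1],
             rep(1, length(ix)))
  X <- outer(rep(1, length(iy)),
             centre_coords(ix, voxel_size[3]) - centre_yx[2])
  u <- (cos(angle) * Y + sin(angle) * X) / semi_yx[1]
  v <- (-sin(angle) * Y + cos(angle) * X) / semi_yx[2]
  loc <- which(u^2 + v^2 <= 1)
  if (!length(loc)) return(integer(0))
  a <- arrayInd(loc, c(length(iy), length(ix)))
  z_index + dims[1] * (iy[a[, 1]] - 1L) + dims[1] * dims[2] * (ix[a[, 2]] - 1L)
}

# bounding box (iz0, iz1, iy0, iy1, ix0, ix1) of linear voxel indices
bbox_of <- function(lin, dims) {
  a <- arrayInd(lin, dims)
  c(min(a[, 1]), max(a[, 1]), min(a[, 2]), max(a[, 2]),
    min(a[, 3]), max(a[, 3]))
}

# TRUE if `box` expanded by `margin` voxels intersects any row of `boxes`
bbox_conflict <- function(box, boxes, margin = 1L) {
  if (is.null(boxes) || nrow(boxes) == 0L) return(FALSE)
  any(box[1] - margin <= boxes[, 2] & box[2] + margin >= boxes[, 1] &
      box[3] - margin <= boxes[, 4] & box[4] + margin >= boxes[, 3] &
      box[5] - margin <= boxes[, 6] & box[6] + margin >= boxes[, 5])
}

# band-limited Gaussian noise field, sd scaled to `amplitude`; consumes the
# current RNG stream
band_limited_noise <- function(dims, voxel_size, granularity_nm, amplitude) {
  w <- array(stats::rnorm(prod(dims)), dims)
  sig <- granularity_nm / voxel_size
  s <- w
  for (ax in 0:2) {
    k <- gauss_kernel1d(sig[ax + 1])
    if (length(k) > 1L)
      s <- array(conv1d_reflect_cpp(as.numeric(s), dims, k, ax), dims)
  }
  sdv <- stats::sd(s)
  if (sdv == 0) return(array(0, dims))
  s * (amplitude / sdv)
}

# clamped Gaussian label intensities: none falls below mean - 2 sd, none
# above the bit-depth maximum (dense DAB precipitate saturates)
label_intensities <- function(n, mean, sd, vmax) {
  pmin(pmax(stats::rnorm(n, mean, sd), mean - 2 * sd), vmax)
}

# ---- generators -------------------------------------------------------------

#' Mitochondria phantom: labelled ellipsoids over textured neuropil
#'
#' Emulates an SBEM volume in which mitochondria carry the genetically
#' encoded label: randomly oriented solid ellipsoids at label intensity,
#' plus two classes of distractor the bulk-segmentation filters must reject
#' -- sub-cutoff "speckle" blobs (each strictly smaller than 10 voxels) at
#' label intensity, and thin membrane fragments whose in-range intensities
#' alternate between the bit-depth maximum and the lower bound of the
#' separating range (strongly bimodal, hence high intensity variance).
#' All objects are placed by rejection sampling with a one-voxel clearance,
#' so distinct objects are never 26-adjacent and the ground-truth catalogue
#' count equals the connected-component count per class.
#'
#' @param spec a [phantom_spec()].
#' @param n_objects number of mitochondria (>= 1).
#' @param semi_axis_range ellipsoid semi-axis interval in nm; each of the
#'   three semi-axes is drawn uniformly from it. The default lower bound
#'   (150 nm) keeps every mitochondrion above 10 voxels even after
#'   3 x 3 x 1 binning of the SBEM voxel.
#' @param n_speckle,n_membrane_fragments distractor counts (>= 0).
#' @param texture list with `granularity_nm` and `amplitude` for the
#'   band-limited neuropil texture added to the background; `amplitude = 0`
#'   disables it.
#' @param max_attempts rejection-sampling cap per object.
#' @return list with elements `volume` (a `volume_grid`, integer-valued) and
#'   `truth` (a `phantom_truth` with classes `mitochondria`, `speckle`,
#'   `membrane_fragment`).
#' @export
make_mitochondria_phantom <- function(spec = phantom_spec(),
                                      n_objects = 50L,
                                      semi_axis_range = c(150, 300),
                                      n_speckle = 200L,
                                      n_membrane_fragments = 20L,
                                      texture = list(granularity_nm = 100,
                                                     amplitude = 8),
                                      max_attempts = 1000L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_objects < 1L) stop("`n_objects` must be positive")
  if (n_speckle < 0L || n_membrane_fragments < 0L)
    stop("distractor counts must be non-negative")
  if (length(semi_axis_range) != 2L || any(semi_axis_range <= 0) ||
      semi_axis_range[1] > semi_axis_range[2])
    stop("`semi_axis_range` must be a positive (lo, hi) interval in nm")
  dims <- spec$grid_shape
  vs <- spec$voxel_size
  vmax <- bit_max(spec$bit_depth)
  phys <- dims * vs
  set.seed(spec$rng_seed)

  vol <- array(stats::rnorm(prod(dims), spec$background_mean,
                            spec$background_sd), dims)
  if (!is.null(texture) && texture$amplitude > 0)
    vol <- vol + band_limited_noise(dims, vs, texture$granularity_nm,
                                    texture$amplitude)

  boxes <- NULL
  place <- function(class, sampler) {
    for (att in seq_len(max_attempts)) {
      lin <- sampler()
      if (!length(lin$idx)) next
      box <- bbox_of(lin$idx, dims)
      if (bbox_conflict(box, boxes)) next
      boxes <<- rbind(boxes, box)
      return(lin)
    }
    stop(sprintf("could not place a '%s' object after %d attempts", class,
                 max_attempts))
  }

  lab <- function() array(0L, dims)
  masks <- list(mitochondria = lab(), speckle = lab(),
                membrane_fragment = lab())
  cat_rows <- list()
  lo_sep <- spec$label_mean - 2 * spec$label_sd

  for (k in seq_len(n_objects)) {
    obj <- place("mitochondria", function() {
      ctr <- stats::runif(3, 0, phys)
      ax <- stats::runif(3, semi_axis_range[1], semi_axis_range[2])
      rot <- random_rotation()
      idx <- rasterise_ellipsoid(dims, vs, ctr, ax, rot)
      # reject placements clipped by the grid boundary
      if (length(idx)) {
        full <- all(ctr - max(ax) >= 0) && all(ctr + max(ax) <= phys)
        if (!full) idx <- integer(0)
      }
      list(idx = idx, params = list(centre_nm = ctr, semi_axes_nm = ax,
                                    rotation = rot))
    })
    masks$mitochondria[obj$idx] <- k
    vol[obj$idx] <- label_intensities(length(obj$idx), spec$label_mean,
                                      spec$label_sd, vmax)
    cat_rows[[length(cat_rows) + 1L]] <-
      list(class = "mitochondria", id = k, n_voxels = length(obj$idx),
           clipped = 0L, params = obj$params)
  }

  for (k in seq_len(n_speckle)) {
    obj <- place("speckle", function() {
      size <- sample(9L, 1L)
      start <- c(sample(dims[1], 1L), sample(dims[2], 1L), sample(dims[3], 1L))
      cells <- matrix(start, ncol = 3)
      while (nrow(cells) < size) {
        src <- cells[sample(nrow(cells), 1L), ]
        step <- diag(3)[sample(3L, 1L), ] * sample(c(-1L, 1L), 1L)
        cand <- src + step
        if (any(cand < 1L) || any(cand > dims)) next
        if (any(cells[, 1] == cand[1] & cells[, 2] == cand[2] &
                cells[, 3] == cand[3])) next
        cells <- rbind(cells, cand)
      }
      idx <- cells[, 1] + dims[1] * (cells[, 2] - 1L) +
        dims[1] * dims[2] * (cells[, 3] - 1L)
      list(idx = as.integer(idx), params = list(size = size))
    })
    masks$speckle[obj$idx] <- k
    vol[obj$idx] <- label_intensities(length(obj$idx), spec$label_mean,
                                      spec$label_sd, vmax)
    cat_rows[[length(cat_rows) + 1L]] <-
      list(class = "speckle", id = k, n_voxels = length(obj$idx),
           clipped = 0L, params = obj$params)
  }

  for (k in seq_len(n_membrane_fragments)) {
    obj <- place("membrane_fragment", function() {
      zi <- sample(dims[1], 1L)
      ctr <- stats::runif(2, 0, phys[2:3])
      ax <- sort(stats::runif(2, 150, 350), decreasing = TRUE)
      ang <- stats::runif(1, 0, pi)
      idx <- rasterise_patch(dims, vs, zi, ctr, ax, ang)
      if (length(idx) < 12L) idx <- integer(0)  # too small to need filtering
      list(idx = idx, params = list(z = zi, centre_nm = ctr, semi_axes_nm = ax,
                                    angle = ang))
    })
    masks$membrane_fragment[obj$idx] <- k
    # bimodal in-range intensities: alternate top / bottom of the range
    a <- arrayInd(obj$idx, dims)
    hi_side <- (a[, 2] + a[, 3]) %% 2L == 0L
    vol[obj$idx] <- ifelse(hi_side, spec$membrane_intensity, lo_sep)
    cat_rows[[length(cat_rows) + 1L]] <-
      list(class = "membrane_fragment", id = k, n_voxels = length(obj$idx),
           clipped = 0L, params = obj$params)
  }

  vol <- round(pmin(pmax(vol, 0), vmax))
  vg <- volume_grid(vol, voxel_size = vs, bit_depth = spec$bit_depth,
                    provenance = list(list(
                      op = "simulate", kind = "mitochondria",
                      rng_seed = spec$rng_seed, n_objects = n_objects,
                      n_speckle = n_speckle,
                      n_membrane_fragments = n_membrane_fragments)),
                    dataset_ref = sprintf("phantom-mito-seed%d",
                                          spec$rng_seed))
  list(volume = vg, truth = new_phantom_truth(masks, catalogue_df(cat_rows)))
}

catalogue_df <- function(rows) {
  if (!length(rows))
    return(data.frame(class = character(), id = integer(),
                      n_voxels = integer(), clipped = integer()))
  df <- data.frame(
    class = vapply(rows, `[[`, "", "class"),
    id = vapply(rows, function(r) as.integer(r$id), 1L),
    n_voxels = vapply(rows, function(r) as.integer(r$n_voxels), 1L),
    clipped = vapply(rows, function(r) as.integer(r$clipped), 1L),
    stringsAsFactors = FALSE)
  df$params <- lapply(rows, `[[`, "params")
  df
}

#' Neurite phantom: labelled cell trees with signal drop-off and crossovers
#'
#' Emulates a cytosol-labelled projection-neuron volume for seeded region
#' growing: a primary cell rendered as a soma sphere plus a branching
#' tubular tree; optional independent "crossover" cells whose somata cluster
#' against the primary soma (so the labelled masks touch); and optionally a
#' trachiole -- a fine tracheal tube at a constant intensity just below the
#' separating range, spuriously incorporated once a trial series steps the
#' lower bound past it.
#'
#' Signal drop-off: voxels of a segment that has passed `g` branch points
#' have intensity mean `label_mean * (1 - dropoff)^g`; segments with radius
#' above `calibre_threshold_nm` take one extra factor. With `dropoff = 0`
#' every cell voxel lies inside the separating range.
#'
#' @param spec a [phantom_spec()] (the neurite-SBEM preset is typical).
#' @param tree list of branching parameters: `depth` (tree depth in segment
#'   generations: 0 = soma only, 1 = soma + trunk, 2 adds the first pair of
#'   branches, ...), `branch_angle_deg` (interval), `taper` (radius factor
#'   per branch), `segment_length_nm` (trunk length), `length_taper`,
#'   `radius_nm` (trunk radius), `soma_radius_nm`, `calibre_threshold_nm`.
#' @param dropoff fractional intensity reduction in `[0, 1)` applied at each
#'   branch point (and once for large-calibre segments).
#' @param n_crossover_cells number of additional labelled cells.
#' @param with_trachiole add the trachiole tube.
#' @param trachiole list: `radius_nm`, `length_nm`, `offset` (intensity units
#'   below the separating lower bound).
#' @param soma_centre physical `(z, y, x)` nm position of the primary soma;
#'   default is the grid centre.
#' @param texture as in [make_mitochondria_phantom()].
#' @return list with `volume` (a `volume_grid`) and `truth` (classes
#'   `cell_1` for the primary cell, `cell_2` ... for crossovers, and
#'   `trachiole` when requested). Voxels contested between touching cells
#'   belong to the earlier-rendered cell; any voxels clipped at the grid
#'   boundary or detached by contested ownership are counted in the
#'   catalogue's `clipped` column, so each class mask stays one connected
#'   object.
#' @export
make_neurite_phantom <- function(spec = phantom_preset("neurite-sbem",
                                                       grid_shape = c(96L, 192L, 192L)),
                                 tree = list(),
                                 dropoff = 0,
                                 n_crossover_cells = 0L,
                                 with_trachiole = FALSE,
                                 trachiole = list(radius_nm = 80,
                                                  length_nm = 1200,
                                                  offset = 3),
                                 soma_centre = NULL,
                                 texture = list(granularity_nm = 100,
                                                amplitude = 8)) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (dropoff < 0 || dropoff >= 1) stop("`dropoff` must be in [0, 1)")
  tr <- utils::modifyList(
    list(depth = 3L, branch_angle_deg = c(25, 60), taper = 0.75,
         segment_length_nm = 800, length_taper = 0.85, radius_nm = 150,
         soma_radius_nm = 400, calibre_threshold_nm = Inf), tree)
  dims <- spec$grid_shape
  vs <- spec$voxel_size
  vmax <- bit_max(spec$bit_depth)
  phys <- dims * vs
  if (is.null(soma_centre)) soma_centre <- phys / 2
  set.seed(spec$rng_seed)

  vol <- array(stats::rnorm(prod(dims), spec$background_mean,
                            spec$background_sd), dims)
  if (!is.null(texture) && texture$amplitude > 0)
    vol <- vol + band_limited_noise(dims, vs, texture$granularity_nm,
                                    texture$amplitude)

  rand_unit <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  # rotate `d` away from itself by `theta` about a random perpendicular
  branch_dir <- function(d, theta) {
    u <- rand_unit()
    u <- u - sum(u * d) * d
    nu <- sqrt(sum(u^2))
    if (nu < 1e-8) return(branch_dir(d, theta))
    u <- u / nu
    cos(theta) * d + sin(theta) * u
  }

  # returns list of segments: each (p0, p1, radius, generation); the trunk
  # is generation 0, each branching multiplies intensity by (1 - dropoff)
  build_tree <- function(root, dir0) {
    segs <- list()
    recurse <- function(p0, dir, radius, len, gen) {
      p1 <- p0 + dir * len
      segs[[length(segs) + 1L]] <<- list(p0 = p0, p1 = p1, radius = radius,
                                         generation = gen)
      if (gen < tr$depth - 1L) {
        for (child in 1:2) {
          th <- stats::runif(1, tr$branch_angle_deg[1],
                             tr$branch_angle_deg[2]) * pi / 180
          recurse(p1, branch_dir(dir, th), radius * tr$taper,
                  len * tr$length_taper, gen + 1L)
        }
      }
    }
    recurse(root, dir0, tr$radius_nm, tr$segment_length_nm, 0L)
    segs
  }

  # rasterise one cell; returns idx vector and per-voxel intensity factor
  render_cell <- function(soma_p, dir0) {
    fac <- rep(NA_real_, 0)
    idx <- integer(0)
    put <- function(lin, f) {
      if (!length(lin)) return()
      new <- !(lin %in% idx)
      keep_new <- lin[new]
      idx <<- c(idx, keep_new)
      fac <<- c(fac, rep(f, length(keep_new)))
      # overlapping voxels keep the larger (more proximal) factor
      old <- match(lin[!new], idx)
      if (length(old)) fac[old] <<- pmax(fac[old], f)
    }
    put(rasterise_capsule(dims, vs, soma_p, soma_p, tr$soma_radius_nm), 1)
    if (tr$depth >= 1L) {
      for (s in build_tree(soma_p, dir0)) {
        f <- (1 - dropoff)^s$generation
        if (s$radius > tr$calibre_threshold_nm) f <- f * (1 - dropoff)
        put(rasterise_capsule(dims, vs, s$p0, s$p1, s$radius), f)
      }
    }
    list(idx = idx, fac = fac)
  }

  cells <- list()
  requested <- integer(0)
  # primary cell: trunk direction random
  cells[[1]] <- render_cell(soma_centre, rand_unit())
  # crossover cells: somata clustered against the primary soma, trees
  # directed outward
  if (n_crossover_cells > 0L) {
    for (k in seq_len(n_crossover_cells)) {
      away <- rand_unit()
      sp <- soma_centre + away * (1.9 * tr$soma_radius_nm)
      cells[[k + 1L]] <- render_cell(sp, away)
    }
  }

  owned <- array(0L, dims)          # cell ownership, first renderer wins
  masks <- list()
  cat_rows <- list()
  lo_sep <- spec$label_mean - 2 * spec$label_sd

  for (ci in seq_along(cells)) {
    idx <- cells[[ci]]$idx
    fac <- cells[[ci]]$fac
    requested <- length(idx)
    free <- owned[idx] == 0L
    idx <- idx[free]; fac <- fac[free]
    m <- array(0L, dims)
    m[idx] <- 1L
    # keep the connected component containing (or nearest) the soma centre
    cl <- array(cc_label_cpp(as.logical(m), dims, 26L), dims)
    keep_lab <- if (max(cl) > 1L) {
      sizes <- tabulate(cl[cl > 0L])
      which.max(sizes)
    } else 1L
    kept <- idx[cl[idx] == keep_lab]
    fac <- fac[cl[idx] == keep_lab]
    owned[kept] <- ci
    cname <- sprintf("cell_%d", ci)
    mk <- array(0L, dims); mk[kept] <- 1L
    masks[[cname]] <- mk
    mu <- spec$label_mean * fac
    vol[kept] <- pmin(pmax(stats::rnorm(length(kept), mu, spec$label_sd),
                           mu - 2 * spec$label_sd), vmax)
    cat_rows[[length(cat_rows) + 1L]] <-
      list(class = cname, id = 1L, n_voxels = length(kept),
           clipped = requested - length(kept),
           params = list(dropoff = dropoff, depth = tr$depth,
                         soma_radius_nm = tr$soma_radius_nm))
  }

  if (isTRUE(with_trachiole)) {
    dirt <- rand_unit()
    t0 <- soma_centre
    t1 <- soma_centre + dirt * (tr$soma_radius_nm + trachiole$length_nm)
    tidx <- rasterise_capsule(dims, vs, t0, t1, trachiole$radius_nm)
    req <- length(tidx)
    tidx <- tidx[owned[tidx] == 0L]
    m <- array(0L, dims); m[tidx] <- 1L
    cl <- array(cc_label_cpp(as.logical(m), dims, 26L), dims)
    if (max(cl) > 1L) {
      sizes <- tabulate(cl[cl > 0L])
      tidx <- tidx[cl[tidx] == which.max(sizes)]
    }
    masks$trachiole <- array(0L, dims)
    masks$trachiole[tidx] <- 1L
    vol[tidx] <- lo_sep - trachiole$offset
    cat_rows[[length(cat_rows) + 1L]] <-
      list(class = "trachiole", id = 1L, n_voxels = length(tidx),
           clipped = req - length(tidx),
           params = list(intensity = lo_sep - trachiole$offset,
                         radius_nm = trachiole$radius_nm))
  }

  vol <- round(pmin(pmax(vol, 0), vmax))
  vg <- volume_grid(vol, voxel_size = vs, bit_depth = spec$bit_depth,
                    provenance = list(list(
                      op = "simulate", kind = "neurite",
                      rng_seed = spec$rng_seed, dropoff = dropoff,
                      n_crossover_cells = n_crossover_cells,
                      with_trachiole = isTRUE(with_trachiole))),
                    dataset_ref = sprintf("phantom-neurite-seed%d",
                                          spec$rng_seed))
  list(volume = vg, truth = new_phantom_truth(masks, catalogue_df(cat_rows)),
       soma_centre_nm = soma_centre)
}

#' Add band-limited neuropil texture to a volume
#'
#' Adds spatially correlated (band-limited) Gaussian noise of a given
#' physical granularity, then clips to the bit-depth domain. With
#' `amplitude = 0` the volume is returned unchanged (identity).
#'
#' @param volume a `volume_grid` with known voxel size.
#' @param granularity_nm correlation length of the texture in nm.
#' @param amplitude standard deviation of the added field, intensity units.
#' @param rng_seed integer seed (reproducible).
#' @return a `volume_grid` with updated provenance.
#' @export
add_background_texture <- function(volume, granularity_nm = 100,
                                   amplitude = 8, rng_seed = 1L) {
  stopifnot(inherits(volume, "volume_grid"))
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  params <- list(granularity_nm = granularity_nm, amplitude = amplitude,
                 rng_seed = rng_seed)
  if (amplitude == 0)
    return(add_provenance(volume, "texture", params))
  require_voxel_size(volume$voxel_size)
  set.seed(rng_seed)
  dims <- grid_dims(volume)
  tex <- band_limited_noise(dims, volume$voxel_size, granularity_nm,
                            amplitude)
  vmax <- bit_max(volume$bit_depth)
  with_values(volume, array(pmin(pmax(volume$values + tex, 0), vmax), dims),
              "texture", params)
}
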