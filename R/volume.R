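#' 3D intensity volume with physical voxel metadata
#'
#' The universal substrate of the pipeline: a 3D scalar array in `(z, y, x)`
#' axis order together with the physical voxel extents in nanometres, the
#' working bit depth, and an append-only provenance list recording every
#' operation applied. Indices are 1-based; the centre of voxel `(i, j, k)`
#' sits at `((i - 0.5) * voxel_size[1], ...)` nm.
#'
#' @param values numeric 3D array, dimensions `(nz, ny, nx)`; all values must
#'   lie inside the bit-depth domain `[0, 2^bit_depth - 1]`.
#' @param voxel_size numeric length-3, physical voxel extents `(z, y, x)` in
#'   nm. May be `NA` for purely voxel-unit work; operations needing physical
#'   units then fail with an informative error.
#' @param bit_depth working intensity domain; 8 (default, values 0-255) or 16.
#' @param provenance list of operation records (name + parameters), oldest
#'   first.
#' @param dataset_ref free-text dataset reference carried through I/O.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(values, voxel_size = c(NA_real_, NA_real_, NA_real_),
                        bit_depth = 8L, provenance = list(),
                        dataset_ref = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array (z, y, x)")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L)
    stop("`voxel_size` must have 3 entries (z, y, x) in nm")
  if (any(!is.na(voxel_size) & voxel_size <= 0))
    stop("voxel extents must be > 0")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  vmax <- bit_max(bit_depth)
  rng <- range(values)
  if (rng[1] < 0 || rng[2] > vmax)
    stop(sprintf("values outside the %d-bit domain [0, %d]", bit_depth, vmax))
  structure(
    list(values = values, voxel_size = voxel_size, bit_depth = bit_depth,
         provenance = provenance, dataset_ref = dataset_ref),
    class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  vs <- ifelse(is.na(x$voxel_size), "?", format(x$voxel_size))
  cat(sprintf("<volume_grid> %d x %d x %d voxels (z, y, x), %d-bit\n",
              d[1], d[2], d[3], x$bit_depth))
  cat(sprintf("  voxel size: %s x %s x %s nm\n", vs[1], vs[2], vs[3]))
  if (!is.null(x$dataset_ref)) cat("  dataset:", x$dataset_ref, "\n")
  if (length(x$provenance))
    cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "op"),
                               collapse = " -> "), "\n")
  invisible(x)
}

bit_max <- function(bit_depth) as.numeric(2^bit_depth - 1)

grid_dims <- function(volume) dim(volume$values)

#' Physical volume of one voxel in cubic micrometres
#'
#' @param voxel_size voxel extents `(z, y, x)` in nm, or a `volume_grid`.
#' @return scalar volume in um^3 (1 um^3 = 1e9 nm^3).
#' @export
voxel_volume_um3 <- function(voxel_size) {
  if (inherits(voxel_size, "volume_grid")) voxel_size <- voxel_size$voxel_size
  require_voxel_size(voxel_size)
  prod(voxel_size) / 1e9
}

require_voxel_size <- function(voxel_size) {
  if (any(is.na(voxel_size)))
    stop("voxel size is unknown; supply metadata (JSON sidecar) before ",
         "physical-unit operations")
  invisible(voxel_size)
}

add_provenance <- function(volume, op, params = list()) {
  volume$provenance <- c(volume$provenance, list(c(list(op = op), params)))
  volume
}

# replace the values of a grid, keeping metadata, appending provenance
with_values <- function(volume, values, op, params = list()) {
  volume$values <- values
  add_provenance(volume, op, params)
}

#' Closed intensity interval
#'
#' @param lo,hi interval bounds, `lo <= hi`; both bounds are inclusive
#'   wherever a range is applied.
#' @return object of class `intensity_range`.
#' @export
intensity_range <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (length(lo) != 1 || length(hi) != 1 || is.na(lo) || is.na(hi))
    stop("`lo` and `hi` must be single non-missing numbers")
  if (lo > hi) stop("`lo` must not exceed `hi`")
  structure(list(lo = lo, hi = hi), class = "intensity_range")
}

#' @export
print.intensity_range <- function(x, ...) {
  cat(sprintf("<intensity_range> [%g, %g]\n", x$lo, x$hi))
  invisible(x)
}

as_intensity_range <- function(x) {
  if (inherits(x, "intensity_range")) return(x)
  if (is.numeric(x) && length(x) == 2) return(intensity_range(x[1], x[2]))
  stop("expected an intensity_range or a numeric (lo, hi) pair")
}

check_range_in_domain <- function(range, volume) {
  vmax <- bit_max(volume$bit_depth)
  if (range$lo < 0 || range$hi > vmax)
    stop(sprintf("range [%g, %g] outside the %d-bit domain [0, %g]",
                 range$lo, range$hi, volume$bit_depth, vmax))
  invisible(range)
}

#' Observed intensity range of a volume (the "true range")
#'
#' The true range is the observed minimum-to-maximum intensity span of the
#' working volume; its width parameterises the per-trial step of a seeded
#' trial series (each step is a fixed fraction, typically 0.2-0.4%, of this
#' width). Set `nominal = TRUE` to use the nominal bit-depth domain instead.
#'
#' @param volume a `volume_grid`.
#' @param nominal if `TRUE`, return `[0, 2^bit_depth - 1]` regardless of the
#'   data.
#' @return an `intensity_range`.
#' @export
true_range <- function(volume, nominal = FALSE) {
  stopifnot(inherits(volume, "volume_grid"))
  if (nominal) return(intensity_range(0, bit_max(volume$bit_depth)))
  if (length(volume$values) == 0) stop("empty volume has no range")
  r <- range(volume$values)
  intensity_range(r[1], r[2])
}
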