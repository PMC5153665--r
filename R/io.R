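sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a volume as a multi-page TIFF with a JSON metadata sidecar
#'
#' One TIFF page per z-slice, values quantised (rounded) to the volume's
#' bit depth, fixed compression settings so identical volumes produce
#' byte-identical files. Metadata (voxel size, bit depth, axis order,
#' dataset reference, provenance) goes to `<basename>.json` next to the
#' TIFF; it is not stored in TIFF tags, keeping the stack readable by any
#' generic viewer.
#'
#' @param volume a `volume_grid`.
#' @param path output path (`.tif`).
#' @param format only `"tiff"` is supported; `"hdf5"` raises an error.
#' @param compression `"deflate"` (default) or `"none"`.
#' @export
write_stack <- function(volume, path, format = c("tiff", "hdf5"),
                        compression = "deflate") {
  stopifnot(inherits(volume, "volume_grid"))
  format <- match.arg(format)
  if (format == "hdf5")
    stop("HDF5 output is not supported by this build; use format = \"tiff\"")
  vmax <- bit_max(volume$bit_depth)
  v <- round(volume$values)
  pages <- lapply(seq_len(dim(v)[1]), function(i) v[i, , ] / vmax)
  ok <- try(tiff::writeTIFF(pages, path,
                            bits.per.sample = volume$bit_depth,
                            compression = compression, reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write TIFF at '", path, "': ", attr(ok, "condition"))
  write_sidecar(path, list(
    voxel_size_nm = volume$voxel_size, bit_depth = volume$bit_depth,
    axis_order = "zyx", dataset_ref = volume$dataset_ref,
    inverted = FALSE, provenance = volume$provenance))
  invisible(path)
}

#' Read a multi-page TIFF stack into a volume grid
#'
#' The z axis is the page index. If a JSON sidecar (`<basename>.json`) is
#' present, voxel size, bit depth, dataset reference and provenance are
#' restored from it; without one the voxel size is unknown and
#' physical-unit operations will refuse to run. With `invert = TRUE` every
#' value `v` maps to `bit-max - v`, so raw "stain-dark" EM data enters the
#' label-high working convention.
#'
#' @param path TIFF path.
#' @param format only `"tiff"` is supported.
#' @param invert apply intensity inversion on read.
#' @return a `volume_grid`.
#' @export
read_stack <- function(path, format = c("tiff", "hdf5"), invert = FALSE) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("HDF5 input is not supported by this build; use format = \"tiff\"")
  if (!file.exists(path)) stop("no such file: '", path, "'")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("ragged TIFF: pages differ in shape")
  meta <- read_sidecar(path)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- if (max(unlist(pages)) > 255) 16L else 8L
  if (!is.null(meta$bit_depth)) bits <- meta$bit_depth
  if (!bits %in% c(8L, 16L)) stop("unsupported TIFF bit depth: ", bits)
  nz <- length(pages)
  v <- array(0, c(nz, shp[1, 1], shp[2, 1]))
  for (i in seq_len(nz)) v[i, , ] <- pages[[i]]
  prov <- list()
  if (!is.null(meta$provenance)) {
    prov <- meta$provenance
    if (is.data.frame(prov)) prov <- apply(prov, 1, as.list)
  }
  if (isTRUE(invert) || isTRUE(meta$inverted)) {
    v <- bit_max(bits) - v
    prov <- c(prov, list(list(op = "invert")))
  }
  volume_grid(v,
              voxel_size = if (!is.null(meta$voxel_size_nm))
                as.numeric(meta$voxel_size_nm) else c(NA, NA, NA),
              bit_depth = bits, provenance = prov,
              dataset_ref = meta$dataset_ref)
}

#' Write / read a label volume as 16-bit TIFF plus sidecar
#'
#' @param labels a `label_volume` (at most 65535 objects).
#' @param path output `.tif` path.
#' @rdname label_io
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  if (labels$n_objects > 65535L) stop("too many objects for 16-bit storage")
  v <- labels$labels
  pages <- lapply(seq_len(dim(v)[1]), function(i) v[i, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "deflate", reduce = FALSE)
  write_sidecar(path, list(
    kind = "labels", n_objects = labels$n_objects,
    connectivity = labels$connectivity,
    source_range = if (is.null(labels$source_range)) NULL
                   else list(lo = labels$source_range$lo,
                             hi = labels$source_range$hi),
    voxel_size_nm = labels$voxel_size))
  invisible(path)
}

#' @param path input `.tif` path.
#' @rdname label_io
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  d <- dim(pages[[1]])
  v <- array(0L, c(nz, d[1], d[2]))
  for (i in seq_len(nz)) v[i, , ] <- as.integer(pages[[i]])
  meta <- read_sidecar(path)
  rng <- NULL
  if (!is.null(meta$source_range))
    rng <- intensity_range(meta$source_range$lo, meta$source_range$hi)
  new_label_volume(v, if (!is.null(meta$n_objects)) meta$n_objects
                      else max(v),
                   if (!is.null(meta$connectivity)) meta$connectivity
                   else 26L,
                   rng,
                   if (!is.null(meta$voxel_size_nm))
                     as.numeric(meta$voxel_size_nm) else NULL)
}

#' Write / read phantom ground truth (per-class 16-bit TIFFs + catalogue)
#'
#' Each class mask goes to `<base>_<class>.tif`; the catalogue (without
#' generator parameters) to `<base>_catalogue.json`.
#'
#' @param truth a `phantom_truth`.
#' @param base path prefix.
#' @rdname truth_io
#' @export
write_truth <- function(truth, base) {
  stopifnot(inherits(truth, "phantom_truth"))
  for (cl in names(truth$masks)) {
    m <- truth$masks[[cl]]
    pages <- lapply(seq_len(dim(m)[1]), function(i) m[i, , ] / 65535)
    tiff::writeTIFF(pages, sprintf("%s_%s.tif", base, cl),
                    bits.per.sample = 16L, compression = "deflate",
                    reduce = FALSE)
  }
  cat_df <- truth$catalogue
  cat_df$params <- NULL
  jsonlite::write_json(
    list(classes = names(truth$masks), catalogue = cat_df),
    sprintf("%s_catalogue.json", base),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(base)
}

#' @rdname truth_io
#' @export
read_truth <- function(base) {
  meta <- jsonlite::read_json(sprintf("%s_catalogue.json", base),
                              simplifyVector = TRUE)
  masks <- list()
  for (cl in meta$classes) {
    pages <- tiff::readTIFF(sprintf("%s_%s.tif", base, cl), all = TRUE,
                            as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    nz <- length(pages)
    d <- dim(pages[[1]])
    v <- array(0L, c(nz, d[1], d[2]))
    for (i in seq_len(nz)) v[i, , ] <- as.integer(pages[[i]])
    masks[[cl]] <- v
  }
  new_phantom_truth(masks, meta$catalogue)
}

#' Expected z-slice count of an acquisition
#'
#' `round(depth_um * 1000 / z_step_nm)`: the number of sections a stated
#' physical depth implies at a stated section thickness. Used to check
#' sidecar-declared geometry against actual stacks; printed acquisition
#' tables show off-by-one bookkeeping in practice, so small mismatches are
#' tolerated by [validate_slice_count()].
#'
#' @param depth_um physical z extent in micrometres (> 0).
#' @param z_step_nm section thickness in nanometres (> 0).
#' @return integer slice count.
#' @export
slice_count <- function(depth_um, z_step_nm) {
  if (!is.numeric(depth_um) || !is.numeric(z_step_nm) ||
      depth_um <= 0 || z_step_nm <= 0)
    stop("`depth_um` and `z_step_nm` must be positive")
  as.integer(round(depth_um * 1000 / z_step_nm))
}

#' Validate a declared slice count against stated geometry
#'
#' A mismatch of at most one slice between the declared count and
#' `slice_count(depth_um, z_step_nm)` is reported as a warning (off-by-one
#' bookkeeping is common in printed acquisition descriptors); larger
#' mismatches are an error.
#'
#' @param declared declared z-slice count.
#' @param depth_um,z_step_nm stated geometry.
#' @return the computed count, invisibly.
#' @export
validate_slice_count <- function(declared, depth_um, z_step_nm) {
  expected <- slice_count(depth_um, z_step_nm)
  d <- abs(declared - expected)
  if (d == 0) return(invisible(expected))
  msg <- sprintf(
    "declared %d slices, geometry implies %d (%g um / %g nm)",
    declared, expected, depth_um, z_step_nm)
  if (d <= 1) warning(msg) else stop(msg)
  invisible(expected)
}
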