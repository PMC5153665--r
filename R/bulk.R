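#' Range thresholding
#'
#' Selects all voxels whose intensity lies inside the closed interval
#' `[lo, hi]` (both bounds inclusive), as when minima and maxima threshold
#' values are set interactively from pixel-probe readings.
#'
#' @param volume a `volume_grid`.
#' @param range an `intensity_range` (or numeric `(lo, hi)` pair) inside the
#'   bit-depth domain.
#' @return logical 3D array, `TRUE` where `lo <= value <= hi`.
#' @export
threshold_range <- function(volume, range) {
  stopifnot(inherits(volume, "volume_grid"))
  range <- as_intensity_range(range)
  check_range_in_domain(range, volume)
  volume$values >= range$lo & volume$values <= range$hi
}

new_label_volume <- function(labels, n_objects, connectivity,
                             source_range = NULL, voxel_size = NULL) {
  structure(list(labels = labels, n_objects = as.integer(n_objects),
                 connectivity = as.integer(connectivity),
                 source_range = source_range, voxel_size = voxel_size),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s, %d object(s), connectivity %d\n",
              paste(dim(x$labels), collapse = " x "), x$n_objects,
              x$connectivity))
  invisible(x)
}

check_connectivity <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  as.integer(connectivity)
}

#' 3D connected-component labelling
#'
#' Partitions a binary mask into connected objects under 6-, 18- or
#' 26-connectivity. Objects are numbered consecutively `1..K` in the order
#' of each object's first voxel in linear (z-fastest) scan order, so the
#' labelling is deterministic.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (all neighbours;
#'   the default, matching typical 3D visualisation software).
#' @param voxel_size optional `(z, y, x)` nm, carried for physical-unit
#'   filters.
#' @return a `label_volume`.
#' @export
connected_components <- function(mask, connectivity = 26L,
                                 voxel_size = NULL) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array")
  connectivity <- check_connectivity(connectivity)
  dims <- dim(mask)
  lab <- cc_label_cpp(as.logical(mask), dims, connectivity)
  k <- attr(lab, "n_objects")
  new_label_volume(array(as.integer(lab), dims), k, connectivity,
                   voxel_size = voxel_size)
}

# ---- filter log -------------------------------------------------------------

new_filter_log <- function(header = list()) {
  structure(list(header = header, records = list()), class = "filter_log")
}

add_filter_record <- function(log, filter, params, removed_ids, reason) {
  log$records[[length(log$records) + 1L]] <-
    list(filter = filter, params = params,
         removed_ids = as.integer(removed_ids), reason = reason)
  log
}

#' @export
print.filter_log <- function(x, ...) {
  cat("<filter_log>")
  if (length(x$header)) cat(" ", jsonlite::toJSON(x$header, auto_unbox = TRUE))
  cat("\n")
  for (r in x$records)
    cat(sprintf("  %s: removed %d object(s) (%s)\n", r$filter,
                length(r$removed_ids), r$reason))
  invisible(x)
}

#' Tabular view of a filter log
#' @param log a `filter_log`.
#' @return data.frame with one row per removed object.
#' @export
filter_log_table <- function(log) {
  stopifnot(inherits(log, "filter_log"))
  rows <- lapply(log$records, function(r) {
    if (!length(r$removed_ids)) return(NULL)
    data.frame(filter = r$filter, object_id = r$removed_ids,
               reason = r$reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(filter = character(), object_id = integer(),
                      reason = character())
  out
}

# drop the given object ids and relabel survivors consecutively, preserving
# the original label order
relabel_without <- function(labels, drop_ids) {
  k <- labels$n_objects
  keep <- setdiff(seq_len(k), drop_ids)
  map <- integer(k)
  map[keep] <- seq_along(keep)
  lab <- labels$labels
  fg <- lab > 0L
  lab[fg] <- map[lab[fg]]
  new_label_volume(lab, length(keep), labels$connectivity,
                   labels$source_range, labels$voxel_size)
}

#' Minimum-size object filter
#'
#' Removes objects that are too small to be genuine labelled structures,
#' i.e. high-contrast but low-volume non-specific background signals.
#' An object is removed when its voxel count is strictly below `min_voxels`
#' OR its physical volume is strictly below `min_volume_um3` (either
#' criterion suffices; the classic SBEM setting is `min_voxels = 10`,
#' `min_volume_um3 = 2e-4`). Survivors are relabelled consecutively.
#'
#' @param labels a `label_volume`.
#' @param min_voxels strict voxel-count cutoff (objects with
#'   `count < min_voxels` removed), or `NULL` to skip.
#' @param min_volume_um3 strict physical-volume cutoff in um^3, or `NULL`.
#' @param voxel_size `(z, y, x)` nm; needed only for the physical criterion
#'   (defaults to the label volume's own).
#' @param log an existing `filter_log` to append to.
#' @return list with `labels` (filtered `label_volume`) and `log`.
#' @export
filter_min_size <- function(labels, min_voxels = 10L, min_volume_um3 = NULL,
                            voxel_size = NULL, log = new_filter_log()) {
  stopifnot(inherits(labels, "label_volume"))
  if (is.null(min_voxels) && is.null(min_volume_um3))
    stop("provide at least one of `min_voxels`, `min_volume_um3`")
  counts <- tabulate(labels$labels[labels$labels > 0L], labels$n_objects)
  removed_vox <- integer(0)
  removed_phys <- integer(0)
  if (!is.null(min_voxels))
    removed_vox <- which(counts < min_voxels)
  if (!is.null(min_volume_um3)) {
    if (is.null(voxel_size)) voxel_size <- labels$voxel_size
    if (is.null(voxel_size))
      stop("physical-volume criterion requires `voxel_size`")
    vv <- voxel_volume_um3(voxel_size)
    removed_phys <- setdiff(which(counts * vv < min_volume_um3), removed_vox)
  }
  if (!is.null(min_voxels))
    log <- add_filter_record(log, "min_size",
                             list(min_voxels = min_voxels), removed_vox,
                             sprintf("voxel count < %d", min_voxels))
  if (!is.null(min_volume_um3))
    log <- add_filter_record(log, "min_size",
                             list(min_volume_um3 = min_volume_um3),
                             removed_phys,
                             sprintf("volume < %g um^3", min_volume_um3))
  list(labels = relabel_without(labels, c(removed_vox, removed_phys)),
       log = log)
}

#' Intensity-variance object filter
#'
#' Removes objects whose voxel-intensity population variance exceeds
#' `max_variance`: in labelled EM volumes these are typically highly
#' contrasted cell-membrane segments rather than compact DAB-filled
#' structures, whose in-range intensities are narrowly distributed.
#' Single-voxel objects have variance 0 and are kept.
#'
#' @param labels a `label_volume`.
#' @param volume the `volume_grid` the labels were segmented from (same
#'   shape); variance is computed on these values over each object's mask.
#' @param max_variance removal threshold, intensity-squared units. No
#'   universal default exists for real data; for phantoms generated here
#'   `(4 * label_sd)^2` separates label objects from membrane fragments.
#' @param log an existing `filter_log` to append to.
#' @return list with `labels` and `log`.
#' @export
filter_intensity_variance <- function(labels, volume, max_variance,
                                      log = new_filter_log()) {
  stopifnot(inherits(labels, "label_volume"),
            inherits(volume, "volume_grid"))
  if (!identical(dim(labels$labels), dim(volume$values)))
    stop("labels and volume shapes differ")
  if (max_variance < 0) stop("`max_variance` must be >= 0")
  fg <- which(labels$labels > 0L)
  removed <- integer(0)
  if (length(fg)) {
    g <- labels$labels[fg]
    v <- volume$values[fg]
    n <- tabulate(g, labels$n_objects)
    s1 <- as.numeric(rowsum(v, g, reorder = TRUE))
    s2 <- as.numeric(rowsum(v^2, g, reorder = TRUE))
    present <- sort(unique(g))
    varpop <- rep(0, labels$n_objects)
    varpop[present] <- pmax(s2 / n[present] - (s1 / n[present])^2, 0)
    removed <- which(varpop > max_variance)
  }
  log <- add_filter_record(log, "intensity_variance",
                           list(max_variance = max_variance), removed,
                           sprintf("population variance > %g", max_variance))
  list(labels = relabel_without(labels, removed), log = log)
}

#' Bulk range-threshold segmentation with object filters
#'
#' The complete bulk strategy: threshold the working volume to the selected
#' intensity range, extract 3D connected objects, remove sub-cutoff objects
#' (non-specific background) and then high-intensity-variance objects
#' (membrane segments), in that order. Every parameter and every removal is
#' recorded in the returned filter log.
#'
#' @param volume a `volume_grid`.
#' @param range selected `intensity_range`.
#' @param min_voxels,min_volume_um3 size cutoffs (see [filter_min_size()]);
#'   `NULL` disables each.
#' @param max_variance variance cutoff (see [filter_intensity_variance()]);
#'   `NULL` disables it.
#' @param connectivity 6, 18 or 26.
#' @return list with `labels` (a `label_volume`) and `log` (a `filter_log`).
#' @export
bulk_segment <- function(volume, range, min_voxels = 10L,
                         min_volume_um3 = NULL, max_variance = NULL,
                         connectivity = 26L) {
  stopifnot(inherits(volume, "volume_grid"))
  range <- as_intensity_range(range)
  connectivity <- check_connectivity(connectivity)
  log <- new_filter_log(header = list(
    op = "bulk_segment", lo = range$lo, hi = range$hi,
    min_voxels = min_voxels, min_volume_um3 = min_volume_um3,
    max_variance = max_variance, connectivity = connectivity))
  mask <- threshold_range(volume, range)
  labels <- connected_components(mask, connectivity,
                                 voxel_size = volume$voxel_size)
  labels$source_range <- range
  if (!is.null(min_voxels) || !is.null(min_volume_um3)) {
    st <- filter_min_size(labels, min_voxels, min_volume_um3,
                          voxel_size = volume$voxel_size, log = log)
    labels <- st$labels; log <- st$log
  }
  if (!is.null(max_variance)) {
    st <- filter_intensity_variance(labels, volume, max_variance, log = log)
    labels <- st$labels; log <- st$log
  }
  list(labels = labels, log = log)
}
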