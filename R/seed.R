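check_seed <- function(seed, dims) {
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(is.na(seed)))
    stop("`seed` must be a (z, y, x) voxel index")
  if (any(seed < 1L) || any(seed > dims))
    stop(sprintf("seed (%d, %d, %d) lies outside the grid", seed[1], seed[2],
                 seed[3]))
  seed
}

seed_linear0 <- function(seed, dims) {
  (seed[1] - 1) + dims[1] * ((seed[2] - 1) + dims[2] * (seed[3] - 1))
}

new_seed_trial <- function(index, range, roi, voxel_size = NULL,
                           seed = NULL, error = NULL) {
  vc <- sum(roi)
  structure(list(index = as.integer(index), range = range, roi = roi,
                 voxel_count = vc,
                 volume_um3 = if (is.null(voxel_size) ||
                                  any(is.na(voxel_size))) NA_real_
                              else vc * voxel_volume_um3(voxel_size),
                 seed = seed, error = error),
            class = "seed_trial")
}

#' @export
print.seed_trial <- function(x, ...) {
  cat(sprintf("<seed_trial %d> range [%g, %g]: %d voxels", x$index,
              x$range$lo, x$range$hi, x$voxel_count))
  if (!is.na(x$volume_um3)) cat(sprintf(" (%.4g um^3)", x$volume_um3))
  if (!is.null(x$error)) cat("  [", x$error, "]")
  cat("\n")
  invisible(x)
}

#' Point-seeded 3D region growing
#'
#' Grows a region of interest from a seed voxel by FIFO flood fill
#' constrained to a closed intensity range: the result is exactly the
#' connected component of `threshold_range(volume, range)` that contains
#' the seed. Deterministic.
#'
#' @param volume a `volume_grid`.
#' @param seed `(z, y, x)` voxel index, 1-based; its intensity must lie
#'   inside `range` (a seed outside the range signals a mis-placed seed and
#'   is an error).
#' @param range closed `intensity_range`.
#' @param connectivity 6, 18 or 26.
#' @return a `seed_trial` whose `roi` is a logical array.
#' @export
grow_from_seed <- function(volume, seed, range, connectivity = 26L) {
  stopifnot(inherits(volume, "volume_grid"))
  range <- as_intensity_range(range)
  check_range_in_domain(range, volume)
  connectivity <- check_connectivity(connectivity)
  dims <- grid_dims(volume)
  seed <- check_seed(seed, dims)
  sval <- volume$values[seed[1], seed[2], seed[3]]
  if (sval < range$lo || sval > range$hi)
    stop(sprintf(
      "seed intensity %g outside range [%g, %g]; re-place the seed",
      sval, range$lo, range$hi))
  roi <- flood_seed_cpp(as.numeric(volume$values), dims,
                        seed_linear0(seed, dims), range$lo, range$hi,
                        connectivity)
  new_seed_trial(1L, range, array(roi, dims), volume$voxel_size, seed)
}

#' Specification of an iterative seed-trial series
#'
#' A trial series holds the upper bound fixed at a common maximum and
#' lowers the lower bound stepwise; trial `k` uses the range
#' `[max(domain_min, lo_start - (k - 1) * step), hi]` where
#' `step = step_fraction * width(true range)`. Step fractions of
#' 0.002-0.004 (0.2-0.4% of the true range) are typical.
#'
#' @param hi fixed upper bound (the common maximum).
#' @param lo_start lower bound of trial 1; `lo_start <= hi`.
#' @param step_fraction fraction of the true-range width per step, in
#'   `(0, 1)`.
#' @param n_trials number of trials (>= 1).
#' @return object of class `trial_series_spec`.
#' @export
trial_series_spec <- function(hi, lo_start, step_fraction = 0.003,
                              n_trials = 12L) {
  if (lo_start > hi) stop("`lo_start` must not exceed `hi`")
  if (step_fraction <= 0 || step_fraction >= 1)
    stop("`step_fraction` must be in (0, 1)")
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("`n_trials` must be >= 1")
  structure(list(hi = hi, lo_start = lo_start,
                 step_fraction = step_fraction, n_trials = n_trials),
            class = "trial_series_spec")
}

#' Run an iterative seed-trial series
#'
#' Performs `n_trials` seeded growths with a fixed upper bound and a lower
#' bound stepped down by `step_fraction` of the observed true-range width
#' (computed once per series, on the working volume). Successive ROIs are
#' nested: each trial's region contains every earlier one. Trials whose
#' range excludes the seed intensity are recorded as empty with an error
#' note rather than aborting the series.
#'
#' @param volume a `volume_grid`.
#' @param seed `(z, y, x)` voxel index.
#' @param series a [trial_series_spec()].
#' @param connectivity 6, 18 or 26.
#' @param nominal_range use the nominal bit-depth domain as the true range
#'   instead of the observed min-max.
#' @return list of `seed_trial` objects, with the per-trial growth table
#'   attached as attribute `"growth"` (see [growth_curve()]).
#' @export
run_trial_series <- function(volume, seed, series, connectivity = 26L,
                             nominal_range = FALSE) {
  stopifnot(inherits(volume, "volume_grid"),
            inherits(series, "trial_series_spec"))
  tr <- true_range(volume, nominal = nominal_range)
  step <- series$step_fraction * (tr$hi - tr$lo)
  dims <- grid_dims(volume)
  seed <- check_seed(seed, dims)
  trials <- vector("list", series$n_trials)
  for (k in seq_len(series$n_trials)) {
    lo_k <- max(0, series$lo_start - (k - 1) * step)
    rng <- intensity_range(lo_k, series$hi)
    trials[[k]] <- tryCatch({
      t1 <- grow_from_seed(volume, seed, rng, connectivity)
      t1$index <- k
      t1
    }, error = function(e) {
      new_seed_trial(k, rng, array(FALSE, dims), volume$voxel_size, seed,
                     error = conditionMessage(e))
    })
  }
  attr(trials, "growth") <- growth_curve(trials)
  attr(trials, "step") <- step
  trials
}

#' Growth curve of a trial series
#' @param trials list of `seed_trial` objects.
#' @return data.frame with columns `trial`, `lo`, `hi`, `voxels`,
#'   `volume_um3`.
#' @export
growth_curve <- function(trials) {
  data.frame(
    trial = vapply(trials, `[[`, 1L, "index"),
    lo = vapply(trials, function(t) t$range$lo, 1),
    hi = vapply(trials, function(t) t$range$hi, 1),
    voxels = vapply(trials, `[[`, 1L, "voxel_count"),
    volume_um3 = vapply(trials, `[[`, 1, "volume_um3"))
}

#' Multi-seed tracing at a shared intensity range
#'
#' Grows each seed independently at the same range. Seeds that fall in the
#' same connected component receive the SAME object id (the merge is
#' reported); only seeded components are labelled, not all components of
#' the thresholded mask.
#'
#' @param volume a `volume_grid`.
#' @param seeds list (or n x 3 matrix) of `(z, y, x)` seed indices; must be
#'   distinct.
#' @param range shared `intensity_range`.
#' @param connectivity 6, 18 or 26.
#' @return a `label_volume` with one id per distinct component, plus
#'   attributes `"seed_object"` (object id per seed, in input order) and
#'   `"merges"` (data.frame of seeds that landed in an earlier seed's
#'   component).
#' @export
multi_seed_trace <- function(volume, seeds, range, connectivity = 26L) {
  stopifnot(inherits(volume, "volume_grid"))
  if (is.matrix(seeds)) seeds <- lapply(seq_len(nrow(seeds)),
                                        function(i) seeds[i, ])
  if (!length(seeds)) stop("no seeds given")
  dims <- grid_dims(volume)
  seeds <- lapply(seeds, check_seed, dims = dims)
  key <- vapply(seeds, paste, "", collapse = ",")
  if (anyDuplicated(key)) stop("seeds must be distinct")
  range <- as_intensity_range(range)
  connectivity <- check_connectivity(connectivity)

  labels <- array(0L, dims)
  seed_object <- integer(length(seeds))
  merges <- list()
  next_id <- 0L
  for (i in seq_along(seeds)) {
    s <- seeds[[i]]
    existing <- labels[s[1], s[2], s[3]]
    if (existing > 0L) {   # same component as an earlier seed: merge
      seed_object[i] <- existing
      merges[[length(merges) + 1L]] <-
        data.frame(seed = i, merged_into = existing)
      next
    }
    t1 <- grow_from_seed(volume, s, range, connectivity)
    next_id <- next_id + 1L
    labels[t1$roi] <- next_id
    seed_object[i] <- next_id
  }
  out <- new_label_volume(labels, next_id, connectivity, range,
                          volume$voxel_size)
  attr(out, "seed_object") <- seed_object
  attr(out, "merges") <- if (length(merges)) do.call(rbind, merges)
                         else data.frame(seed = integer(),
                                         merged_into = integer())
  out
}
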