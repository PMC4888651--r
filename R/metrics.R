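#' Global surface-area-to-volume ratio
#'
#' Sums the per-slice ledger: surface = sum of slice perimeters x slice
#' thickness, volume = sum of slice areas x slice thickness, and returns
#' surface / volume (1/um). This is a single pooled ratio over all segmented
#' material, not a mean of per-object ratios, so heavily fragmented wells
#' weight by their material.
#'
#' @param nodules A [segment_nodules()] result with a non-empty ledger.
#' @param pitch Optional pitch override (um per voxel, `(z, x, y)`); defaults
#'   to the pitch recorded at segmentation.
#' @return Ratio in 1/um.
#' @examples
#' m <- array(FALSE, c(16, 16, 3)); m[4:13, 4:13, 2] <- TRUE
#' mask_sa_to_v(m, c(1, 1, 1), estimator = "edge") # (4*10)/(100) = 0.4
#' @export
global_sa_to_v <- function(nodules, pitch = NULL) {
  stopifnot(inherits(nodules, "nodule_labels"))
  if (!nrow(nodules$ledger)) {
    abort("Surface-area-to-volume is undefined: the slice ledger is empty.",
          class = "oct_undefined_metric")
  }
  pitch <- pitch %||% nodules$pitch
  surface <- sum(nodules$ledger$perimeter_um) * pitch[3]
  volume <- sum(nodules$ledger$area_um2) * pitch[3]
  surface / volume
}

#' Surface-area-to-volume of a binary mask
#'
#' The same stacked-slice convention as [global_sa_to_v()], computed directly
#' from a logical volume: per xz slice, the foreground boundary length and
#' area are accumulated and multiplied by the slice thickness. Used for
#' phantom ground truth and for brute-force cross-checks.
#'
#' @param mask Logical 3D array `(z, x, y)`.
#' @param pitch Micrometres per voxel `(z, x, y)`.
#' @param estimator `"crofton"` (default) or `"edge"`; see [segment_nodules()].
#' @return Ratio in 1/um.
#' @export
mask_sa_to_v <- function(mask, pitch, estimator = c("crofton", "edge")) {
  estimator <- match.arg(estimator)
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (!any(mask)) {
    abort("Surface-area-to-volume is undefined for an empty mask.",
          class = "oct_undefined_metric")
  }
  gs <- dim(mask)
  # boundary transitions along z and x, including grid-face borders
  ez <- sum(mask != shift3(mask, 1L, 1L, FALSE)) + sum(mask[gs[1], , ])
  ex <- sum(mask != shift3(mask, 2L, 1L, FALSE)) + sum(mask[, gs[2], ])
  per <- ez * pitch[2] + ex * pitch[1]
  if (estimator == "crofton") per <- per * pi / 4
  surface <- per * pitch[3]
  volume <- sum(mask) * prod(pitch)
  surface / volume
}

#' Disruption index
#'
#' Control-normalized surface-area-to-volume ratio shifted so that zero means
#' intact spheroids: `sample_ratio / control_ratio - 1`. The unsubtracted
#' ratio (control = unity) is available via [normalize_to_control()].
#'
#' @param sample_ratio Sample SA:V ratio(s), 1/um.
#' @param control_ratio No-treatment control SA:V ratio (> 0).
#' @return Dimensionless index, 0 for an intact (control-like) well.
#' @examples
#' disruption_index(0.26, 0.20) # 0.3
#' @export
disruption_index <- function(sample_ratio, control_ratio) {
  if (!is.numeric(control_ratio) || any(!is.finite(control_ratio)) ||
      any(control_ratio <= 0)) {
    abort("`control_ratio` must be positive and finite.",
          class = "oct_validation_error")
  }
  sample_ratio / control_ratio - 1
}

#' Normalize a metric to its no-treatment control
#'
#' @param value Metric value(s).
#' @param control_value Control value (> 0).
#' @return `value / control_value`; the control maps to unity.
#' @export
normalize_to_control <- function(value, control_value) {
  if (!is.numeric(control_value) || any(!is.finite(control_value)) ||
      any(control_value <= 0)) {
    abort("`control_value` must be positive and finite.",
          class = "oct_validation_error")
  }
  value / control_value
}

#' Apoptotic density
#'
#' Summed volume of detected apoptotic features divided by the total measured
#' spheroid volume (dimensionless fraction).
#'
#' @param features A [detect_apoptotic_bodies()] result.
#' @return Fraction in `[0, 1]`; values above 1 (a segmentation
#'   inconsistency) are clipped with a warning.
#' @export
apoptotic_density <- function(features) {
  stopifnot(inherits(features, "apoptotic_features"))
  v <- features$parent_nodule_volume_um3
  if (!is.finite(v) || v <= 0) {
    abort("Apoptotic density is undefined: total spheroid volume is zero.",
          class = "oct_undefined_metric")
  }
  d <- sum(features$features$volume_um3) / v
  if (d > 1) {
    warn(paste0("Apoptotic density ", signif(d, 4),
                " exceeds 1; clipping (check segmentation consistency)."))
    d <- 1
  }
  d
}

#' Analyze one volume into a per-well metrics record
#'
#' Runs segmentation and apoptotic-body detection and returns one tidy row.
#' Wells with no detected foreground yield `NA` metrics (to be excluded from
#' group statistics, not imputed).
#'
#' @param volume An [oct_volume()].
#' @param well_id,treatment,day Annotations carried into the record.
#' @param segment_args,detect_args Named lists of extra arguments passed to
#'   [segment_nodules()] and [detect_apoptotic_bodies()].
#' @return A one-row tibble: `well_id`, `treatment`, `day`, `n_objects`,
#'   `sa_to_v`, `apoptotic_density`, `total_volume_um3`,
#'   `n_apoptotic_features`, `foreground_threshold`.
#' @export
analyze_volume <- function(volume, well_id = "well", treatment = "NT", day = 0,
                           segment_args = list(), detect_args = list()) {
  seg <- do.call(segment_nodules, c(list(volume = volume), segment_args))
  if (seg$n_objects == 0L) {
    return(tibble(well_id = well_id, treatment = treatment, day = day,
                  n_objects = 0L, sa_to_v = NA_real_,
                  apoptotic_density = NA_real_, total_volume_um3 = 0,
                  n_apoptotic_features = 0L,
                  foreground_threshold = seg$foreground_threshold))
  }
  feats <- do.call(detect_apoptotic_bodies,
                   c(list(volume = volume, nodules = seg), detect_args))
  tibble(
    well_id = well_id, treatment = treatment, day = day,
    n_objects = seg$n_objects,
    sa_to_v = global_sa_to_v(seg),
    apoptotic_density = apoptotic_density(feats),
    total_volume_um3 = seg$total_volume_um3,
    n_apoptotic_features = nrow(feats$features),
    foreground_threshold = seg$foreground_threshold
  )
}

#' Normalize per-well records to the no-treatment control
#'
#' Adds, per day, the control-normalized columns: `normalized_sa_to_v`
#' (control = 1), `disruption_index` (control = 0), and
#' `normalized_apoptotic_density` (control = 1; pooled control mean in the
#' denominator). Degenerate wells (`NA` metrics) are excluded from control
#' means and flagged.
#'
#' @param records Tidy per-well tibble from [analyze_volume()] rows.
#' @param control Treatment label of the no-treatment arm (default `"NT"`).
#' @return `records` with the normalized columns added.
#' @export
normalize_records <- function(records, control = "NT") {
  if (!all(c("treatment", "sa_to_v", "apoptotic_density") %in% names(records))) {
    abort("`records` must have treatment, sa_to_v and apoptotic_density columns.",
          class = "oct_validation_error")
  }
  if (!"day" %in% names(records)) records$day <- 0
  if (!any(records$treatment == control)) {
    abort(paste0("No rows with control treatment '", control, "'."),
          class = "oct_validation_error")
  }
  ctrl <- records |>
    filter(.data$treatment == control, is.finite(.data$sa_to_v)) |>
    group_by(.data$day) |>
    summarise(control_sa_to_v = mean(.data$sa_to_v),
              control_apoptotic_density = mean(.data$apoptotic_density),
              .groups = "drop")
  if (any(!is.finite(ctrl$control_sa_to_v)) || any(ctrl$control_sa_to_v <= 0)) {
    abort("Control SA:V mean is undefined or non-positive.",
          class = "oct_validation_error")
  }
  out <- records |>
    left_join(ctrl, by = "day") |>
    mutate(
      normalized_sa_to_v = .data$sa_to_v / .data$control_sa_to_v,
      disruption_index = .data$sa_to_v / .data$control_sa_to_v - 1,
      normalized_apoptotic_density = dplyr::if_else(
        .data$control_apoptotic_density > 0,
        .data$apoptotic_density / .data$control_apoptotic_density,
        NA_real_)
    )
  n_bad <- sum(!is.finite(records$sa_to_v))
  if (n_bad) inform(paste0(n_bad, " degenerate well(s) with no foreground excluded from normalization."))
  out
}

#' Tidy methods for octspheroid objects
#'
#' `tidy()` returns the underlying tibble of a segmentation ledger, feature
#' set, t-test or synergy result; `glance()` gives a one-row summary.
#'
#' @param x An octspheroid object.
#' @param ... Unused.
#' @name tidy_octspheroid
NULL
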