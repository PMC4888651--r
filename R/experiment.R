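#' Simulate a longitudinal multi-arm treatment course
#'
#' Generates one phantom per well for every (arm, day) cell of a treatment
#' schedule and analyzes each through the full segmentation/metrics chain.
#' The schedule drives the two treatment effects the phantoms can express:
#' structural disruption (`fragmentation`) and programmed cell death
#' (`apoptotic_fraction`). Typical use is a four-arm design (no-treatment,
#' PDT-like, carboplatin-like, combination) over days 0-4 with triplicate
#' wells, mirroring a combination-therapy monitoring experiment.
#'
#' @param schedule Tibble with columns `treatment`, `day`, `fragmentation`,
#'   `apoptotic_fraction`.
#' @param n_wells Replicate wells per (arm, day) cell.
#' @param seed Base seed; each well derives a distinct sub-seed.
#' @param phantom_args Named list overriding the scaled default phantom
#'   geometry (one ~300 um nodule on a 4 um grid; see
#'   `course_phantom_defaults()` in the source).
#' @param segment_args,detect_args Passed to [analyze_volume()].
#' @return Tidy per-well tibble of [analyze_volume()] rows.
#' @export
simulate_treatment_course <- function(schedule, n_wells = 3, seed = 1,
                                      phantom_args = list(),
                                      segment_args = list(),
                                      detect_args = list()) {
  need <- c("treatment", "day", "fragmentation", "apoptotic_fraction")
  missing_cols <- setdiff(need, names(schedule))
  if (length(missing_cols)) {
    abort(paste0("`schedule` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "oct_validation_error")
  }
  base_args <- utils::modifyList(course_phantom_defaults(), phantom_args)
  rows <- list()
  for (r in seq_len(nrow(schedule))) {
    for (w in seq_len(n_wells)) {
      sub_seed <- (as.integer(seed) %% 20000L) * 100000L + r * 100L + w
      spec <- do.call(phantom_spec, utils::modifyList(base_args, list(
        fragmentation = schedule$fragmentation[r],
        apoptotic_fraction = schedule$apoptotic_fraction[r],
        seed = sub_seed)))
      ph <- generate_phantom(spec)
      rec <- analyze_volume(
        ph$volume,
        well_id = paste0(schedule$treatment[r], "_d", schedule$day[r], "_w", w),
        treatment = schedule$treatment[r], day = schedule$day[r],
        segment_args = segment_args, detect_args = detect_args)
      rec$true_sa_to_v <- ph$truth$true_sa_to_v
      rec$true_apoptotic_fraction <- ph$truth$true_apoptotic_fraction
      rows[[length(rows) + 1L]] <- rec
    }
  }
  bind_rows(rows)
}

# Scaled phantom geometry used by the longitudinal course: one ~300 um
# nodule on a 4 um isotropic grid keeps a full 60-phantom course within
# minutes while preserving the size ordering body << nodule << volume.
course_phantom_defaults <- function() {
  list(grid_shape = c(88L, 96L, 96L), voxel_pitch = c(4, 4, 4),
       n_spheroids = 1L, radius_range = c(140, 165),
       apoptotic_radius_range = c(8, 15), attenuation_coeff = 5e-4)
}
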