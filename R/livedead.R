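#' Quantify Live/Dead viability from a two-channel fluorescence pair
#'
#' Well-level viability from co-registered live (calcein-like) and dead
#' (ethidium-like) channels: each channel is background-corrected by
#' subtracting a low percentile (default 5th) with negative clipping, then
#' viability = sum(live) / (sum(live) + sum(dead)). Intensity sums, not cell
#' counts, define the signals; at 3D-culture scale the summed signal is the
#' robust quantity.
#'
#' @param live,dead Non-negative numeric arrays (2D or 3D) of equal shape.
#' @param background_quantile Percentile used as the background estimate for
#'   each channel, in `[0, 1)`.
#' @param well_id Annotation carried into the result.
#' @return A one-row tibble of class `viability_result`: `well_id`,
#'   `live_signal`, `dead_signal`, `viability`.
#' @examples
#' live <- matrix(c(rep(0, 8), rep(9, 8)), 4) # dark background + signal
#' dead <- matrix(c(rep(0, 8), rep(1, 8)), 4)
#' quantify_viability(live, dead, background_quantile = 0)$viability # 0.9
#' @export
quantify_viability <- function(live, dead, background_quantile = 0.05,
                               well_id = "well") {
  if (!identical(dim(live), dim(dead))) {
    abort("`live` and `dead` must have identical shapes.",
          class = "oct_validation_error")
  }
  if (anyNA(live) || anyNA(dead) || any(!is.finite(live)) || any(!is.finite(dead)) ||
      any(live < 0) || any(dead < 0)) {
    abort("Channel intensities must be finite and non-negative.",
          class = "oct_validation_error")
  }
  if (background_quantile < 0 || background_quantile >= 1) {
    abort("`background_quantile` must be in [0, 1).", class = "oct_validation_error")
  }
  correct <- function(ch) {
    bg <- quantile(ch, background_quantile, names = FALSE)
    sum(pmax(ch - bg, 0))
  }
  ls <- correct(live)
  ds <- correct(dead)
  if (ls + ds <= 0) {
    abort("Viability undefined: both channels are zero after background correction.",
          class = "oct_undefined_metric")
  }
  out <- tibble(well_id = well_id, live_signal = ls, dead_signal = ds,
                viability = ls / (ls + ds))
  class(out) <- c("viability_result", class(out))
  out
}

#' Compare OCT metrics with the Live/Dead benchmark
#'
#' Joins per-well OCT records with viability results and reports the Spearman
#' rank correlation between the fluorogenic kill fraction
#' `1 - normalized_viability` and each available OCT treatment-response
#' metric across wells.
#'
#' @param oct_records Tidy per-well tibble (e.g. from [normalize_records()])
#'   with `well_id` and one or more of `disruption_index`,
#'   `normalized_sa_to_v`, `sa_to_v`, `apoptotic_density`,
#'   `normalized_apoptotic_density`.
#' @param viability Tibble with `well_id` and `normalized_viability`
#'   (viability normalized to the no-treatment control, e.g. via
#'   [normalize_to_control()]).
#' @return A tibble of class `assay_comparison`: `metric`, `spearman_rho`,
#'   `n_wells`.
#' @export
compare_assays <- function(oct_records, viability) {
  if (!"well_id" %in% names(oct_records) || !"well_id" %in% names(viability)) {
    abort("Both tables need a `well_id` column.", class = "oct_validation_error")
  }
  if (!"normalized_viability" %in% names(viability)) {
    abort("`viability` must contain `normalized_viability`.",
          class = "oct_validation_error")
  }
  joined <- inner_join(oct_records, viability, by = "well_id")
  if (!nrow(joined)) {
    abort("No overlapping well_ids between the OCT and viability tables.",
          class = "oct_validation_error")
  }
  kill <- 1 - joined$normalized_viability
  candidates <- intersect(
    c("sa_to_v", "normalized_sa_to_v", "disruption_index",
      "apoptotic_density", "normalized_apoptotic_density"),
    names(oct_records))
  rows <- map(candidates, function(m) {
    v <- joined[[m]]
    ok <- is.finite(v) & is.finite(kill)
    rho <- if (sum(ok) >= 2) cor(kill[ok], v[ok], method = "spearman") else NA_real_
    tibble(metric = m, spearman_rho = rho, n_wells = sum(ok))
  })
  out <- bind_rows(rows)
  class(out) <- c("assay_comparison", class(out))
  out
}
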