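#' Simulate an imaged case-control cohort with designed effect sizes
#'
#' Generates a two-group serum cohort (healthy controls vs cases), renders
#' one assay well per sample, runs the full spot-calling chain on each
#' image, and returns the per-sample normalized intensity matrix ready for
#' panel statistics.
#'
#' Biological signal is drawn on the amplitude scale from the binormal
#' model: healthy samples have analyte amplitude
#' `N(base_amplitude, biological_sd)` and cases are shifted by
#' `sqrt(2) * qnorm(design_auc) * biological_sd`, the separation that
#' yields the designed AUC under equal variances.  All three replicate
#' spots of an analyte share the sample's biological amplitude; replicate
#' scatter comes from the imaging chain (pixel noise, detection,
#' quantification).  Draws are clamped to `[1, 230]` so the rendered
#' scene stays below saturation; at the default settings the clamping
#' probability is < 0.5% and its effect on the attained AUC is
#' negligible.
#'
#' @param n_hc,n_ln group sizes (default 10 vs 10).
#' @param design_auc named vector of target AUCs per analyte.
#' @param seed master seed; fully determines the cohort (biology and
#'   imaging noise).
#' @param base_amplitude healthy-group mean spot amplitude (default 110).
#' @param biological_sd between-sample amplitude standard deviation
#'   (default 25).
#' @param noise_sigma imaging pixel noise passed to the renderer
#'   (default 5).
#' @param layout an [array_layout].
#' @param params a [detection_params].
#' @return list with `values` (samples x analytes matrix of normalized
#'   intensities), `labels` (0 = HC, 1 = LN), `amplitudes` (the true
#'   per-sample biological amplitudes) and `design_auc`.
#' @export
simulate_cohort <- function(n_hc = 10, n_ln = 10,
                            design_auc = c(VSIG4 = 0.80, OPN = 0.90,
                                           VCAM1 = 0.95, ALCAM = 0.85,
                                           TNFRSF1B = 0.92),
                            seed = 1L,
                            base_amplitude = 110, biological_sd = 25,
                            noise_sigma = 5,
                            layout = default_layout(names(design_auc)),
                            params = detection_params()) {
  n <- n_hc + n_ln
  labels <- rep(c(0L, 1L), c(n_hc, n_ln))
  analytes <- names(design_auc)
  shift <- sqrt(2) * stats::qnorm(design_auc) * biological_sd

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  amp <- matrix(NA_real_, n, length(analytes),
                dimnames = list(NULL, analytes))
  for (j in seq_along(analytes))
    amp[, j] <- stats::rnorm(n, base_amplitude + shift[j] * labels,
                             biological_sd)
  amp <- pmin(pmax(amp, 1), 230)
  scene_seeds <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  values <- matrix(NA_real_, n, length(analytes),
                   dimnames = list(sprintf("s%02d", seq_len(n)), analytes))
  for (i in seq_len(n)) {
    amps <- default_amplitudes(layout, mode = "assay",
                               test_amplitudes = amp[i, ])
    cfg <- scene_config(layout = layout, amplitudes = amps,
                        noise_sigma = noise_sigma,
                        seed = scene_seeds[i])
    m <- process_well(render_synthetic_array(cfg)$image, layout, params,
                      well_id = rownames(values)[i])
    agg <- normalize_intensity(aggregate_replicates(m), m)
    values[i, agg$analyte] <- agg$normalized
  }
  list(values = values, labels = labels, amplitudes = amp,
       design_auc = design_auc)
}
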