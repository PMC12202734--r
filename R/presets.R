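## Protocol presets bundling the study conditions of the two imaging
## scenarios: a T2-weighted 3D FSE with a very long echo train, and a 3D
## FLAIR (dark-fluid) variant with inversion preparation.

#' T2-weighted 3D FSE preset
#'
#' ETL 200, ESP 3.8 ms, TR 3200 ms, effective TE 380 ms (centre echo 100),
#' relative SAR 9%, linear view ordering. The phantom's phase-encoding axis
#' carries the protocol's full PE matrix (Ny = ETL = 200, one line per echo)
#' so that every echo of the train contributes to the image; the readout axis
#' is reduced to keep the optimisation fast. The PSF loss uses the same
#' full-length line-to-echo map. The spin-echo target uses TE 45 ms /
#' TR 6000 ms scaled by `cTRG = 0.65`, and all tissues are weighted equally
#' in the PSF loss.
#'
#' @param w PSF/SNR balance (1 = PSF-optimised, 0 = SNR-optimised).
#' @param grid_shape phantom grid, `c(readout, PE)`; the PE size must equal
#'   the protocol's PE matrix.
#' @param phantom_seed seed of the synthetic phantom.
#' @param max_iterations,learning_rate optimizer budget; the defaults suit
#'   the reduced phantom.
#' @return List with `descr`, `protocol`, `table`, `psf_table`, `weights`,
#'   `config`, `target_spec`, `name`.
#' @export
preset_t2w <- function(w = 1, grid_shape = c(64, 200), phantom_seed = 1,
                       max_iterations = 400, learning_rate = 0.02) {
  protocol <- sequence_protocol(ETL = 200, ESP = 3.8, TR = 3200, TE_eff = 380)
  descr <- make_synthetic_brain(grid_shape, seed = phantom_seed)
  table <- linear_view_ordering(Ny = grid_shape[2], ETL = protocol$ETL,
                                center_echo = protocol$center_echo)
  psf_table <- linear_view_ordering(Ny = protocol$ETL, ETL = protocol$ETL,
                                    center_echo = protocol$center_echo)
  weights <- loss_weights(w = w, cTRG = 0.65, cT = 1,
                          lambda_R = 1 / (1800 * protocol$ETL))
  config <- optimizer_config(c_SAR = 0.09, learning_rate = learning_rate,
                             max_iterations = max_iterations,
                             c_STOP = 1e-3, stop_mode = "relative")
  list(name = "t2w", descr = descr, protocol = protocol, table = table,
       psf_table = psf_table, weights = weights, config = config,
       target_spec = list(TE = 45, TR = 6000))
}

#' 3D FLAIR preset
#'
#' ETL 220, ESP 4.04 ms, TR 8000 ms, centre echo 75, TI 2250 ms inversion
#' preparation, relative SAR 6%. The CSF compartment is suppressed in the
#' spin-echo target and carries no weight in the PSF loss (white and grey
#' matter are weighted equally).
#'
#' @inheritParams preset_t2w
#' @return Same structure as [preset_t2w()].
#' @export
preset_flair <- function(w = 1, grid_shape = c(64, 220), phantom_seed = 1,
                         max_iterations = 400, learning_rate = 0.02) {
  protocol <- sequence_protocol(ETL = 220, ESP = 4.04, TR = 8000,
                                center_echo = 75, inversion = TRUE, TI = 2250)
  descr <- make_synthetic_brain(grid_shape, seed = phantom_seed)
  table <- linear_view_ordering(Ny = grid_shape[2], ETL = protocol$ETL,
                                center_echo = protocol$center_echo)
  psf_table <- linear_view_ordering(Ny = protocol$ETL, ETL = protocol$ETL,
                                    center_echo = protocol$center_echo)
  weights <- loss_weights(w = w, cTRG = 0.65, cT = c(WM = 1, GM = 1, CSF = 0),
                          lambda_R = 1 / (1800 * protocol$ETL))
  config <- optimizer_config(c_SAR = 0.06, learning_rate = learning_rate,
                             max_iterations = max_iterations,
                             c_STOP = 1e-3, stop_mode = "relative")
  list(name = "flair", descr = descr, protocol = protocol, table = table,
       psf_table = psf_table, weights = weights, config = config,
       target_spec = list(TE = 45, TR = 6000, suppressed = "CSF"))
}

#' Run a preset optimisation
#'
#' @param preset a list from [preset_t2w()] or [preset_flair()].
#' @param verbose print optimizer progress.
#' @return A `vfa_optimization` object.
#' @export
run_preset <- function(preset, verbose = FALSE) {
  optimize_vfa(preset$descr, preset$protocol, preset$table, preset$weights,
               preset$config, psf_table = preset$psf_table,
               target_spec = preset$target_spec, verbose = verbose)
}
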