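# Synthetic ITC thermograms with known ground truth: forward single-site
# model heats plus a constant heat of dilution and seeded Gaussian noise.

#' Default titration protocol
#'
#' Seventeen 2.4 ul injections after a 0.5 ul pre-injection into a 200 ul
#' cell at 298 K — the serial-injection protocol of a small-cell titration
#' calorimeter.
#'
#' @param cell_conc_M macromolecule concentration, mol/l.
#' @param syringe_conc_M ligand concentration, mol/l.
#' @param n_injections number of injections (default 17).
#' @param injection_ul per-injection volume, microlitre (default 2.4).
#' @param cell_volume_ul cell volume, microlitre (default 200).
#' @param temperature_K temperature, K (default 298).
#' @param pre_injection_ul discarded pre-injection volume (default 0.5).
#' @return a [thermogram()] without heats (protocol only).
#' @export
default_protocol <- function(cell_conc_M, syringe_conc_M,
                             n_injections = 17L, injection_ul = 2.4,
                             cell_volume_ul = 200, temperature_K = 298,
                             pre_injection_ul = 0.5) {
  thermogram(cell_volume_ul = cell_volume_ul, temperature_K = temperature_K,
             cell_conc_M = cell_conc_M, syringe_conc_M = syringe_conc_M,
             injection_volumes_ul = rep(injection_ul, n_injections),
             pre_injection_ul = pre_injection_ul)
}

#' Generate a synthetic ITC thermogram
#'
#' Per-injection heats are the single-site model heats plus a constant heat
#' of dilution plus Gaussian noise; control heats are the dilution heat
#' plus independent noise of the same magnitude. Ground-truth parameters,
#' the noise level and the seed are recorded in the thermogram metadata.
#'
#' @param params a [binding_params()] (ground truth).
#' @param protocol a [thermogram()] protocol (heats ignored).
#' @param noise_sd_uJ Gaussian noise standard deviation, microjoule.
#' @param dilution_heat_uJ constant heat of dilution per injection, microjoule.
#' @param seed integer RNG seed (mandatory; no hidden global randomness).
#' @return a [thermogram()] with `heats_uJ` and `control_heats_uJ`.
#' @export
generate_isotherm <- function(params, protocol, noise_sd_uJ = 0,
                              dilution_heat_uJ = 0, seed) {
  stopifnot(inherits(params, "binding_params"), inherits(protocol, "thermogram"))
  if (missing(seed)) stop_cavitherm("seed is required", "cavitherm_config_error")
  if (noise_sd_uJ < 0)
    stop_cavitherm("noise sd must be non-negative", "cavitherm_validation_error")
  model <- single_site_model(params, protocol)
  # near-total saturation already at injection 2 leaves the transition
  # unsampled; warn that the fit will be ill-conditioned
  V0 <- protocol$cell_volume_ul * 1e-6
  v2 <- sum(protocol$injection_volumes_ul[1:2]) * 1e-6
  cc <- .effective_conc(protocol, v2)
  if (cc$X[1] > 0 && sum(abs(model[1:2])) > 0.99 * sum(abs(model)))
    warning("saturation before injection 2: fit will be ill-conditioned")
  nin <- length(protocol$injection_volumes_ul)
  rng <- local({set.seed(seed); list(e1 = rnorm(nin), e2 = rnorm(nin))})
  tg <- protocol
  tg$heats_uJ <- model + dilution_heat_uJ + noise_sd_uJ * rng$e1
  tg$control_heats_uJ <- dilution_heat_uJ + noise_sd_uJ * rng$e2
  tg$metadata <- list(truth = params, noise_sd_uJ = noise_sd_uJ,
                      dilution_heat_uJ = dilution_heat_uJ, seed = seed)
  tg
}
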