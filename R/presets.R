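# Named experiment presets bundling network, stimulus and protocol
# parameters for the canonical model conditions.

#' Experiment presets
#'
#' Named bundles reproducing the canonical conditions of the model study:
#' \describe{
#'   \item{fig1}{feedforward-only network (bFB = 0), sigma = 1,
#'     non-replicate.}
#'   \item{fig2_bottomup}{bottom-up only: non-replicate stimuli, bFB = 0.}
#'   \item{fig2_topdown}{top-down only: replicate stimuli, global
#'     background, bFB = 1.}
#'   \item{fig3_combined}{both mechanisms: non-replicate, bFB = 1.}
#'   \item{fig3_slow}{slower decision dynamics: feedforward efficacy
#'     x 0.75, sigma = 1.33, non-replicate, bFB = 1.}
#'   \item{fig5_heterogeneous}{heterogeneous stimulus/feedback inputs,
#'     non-replicate, bFB = 1.}
#'   \item{fig7_bounds}{bound-crossing analysis: sigma = 2.7,
#'     non-replicate, bFB in {0, 4} (bFB argument selects).}
#'   \item{fig7_sweep}{trade-off sweep: bFB in {0, 1.5, 3, 4.5, 6}
#'     (bFB argument selects), sigma = 1.}
#' }
#'
#' @param name preset name.
#' @param scale network size factor.
#' @param bFB feedback strength for the sweep/bounds presets.
#' @return List: `network` (NetworkConfig), `stimulus` (StimulusConfig),
#'   `mode`, and the preset's deviations from defaults in `notes`.
#' @export
#' @examples
#' p <- experimentPreset("fig2_bottomup", scale = 0.25)
experimentPreset <- function(name = c("fig1", "fig2_bottomup", "fig2_topdown",
                                      "fig3_combined", "fig3_slow",
                                      "fig5_heterogeneous", "fig7_bounds",
                                      "fig7_sweep"),
                             scale = 1, bFB = NULL) {
  name <- match.arg(name)
  gFF0 <- defaultParameters()$coupling$gFF
  p <- switch(name,
    fig1 = list(net = networkConfig(bFB = 0, scale = scale),
      stim = stimulusConfig(sigma = 1), mode = "non-replicate",
      notes = "bFB = 0, sigma = 1"),
    fig2_bottomup = list(net = networkConfig(bFB = 0, scale = scale),
      stim = stimulusConfig(sigma = 1), mode = "non-replicate",
      notes = "non-replicate, bFB = 0"),
    fig2_topdown = list(net = networkConfig(bFB = 1, scale = scale),
      stim = stimulusConfig(sigma = 1, replicate = TRUE), mode = "replicate",
      notes = "replicate, global background, bFB = 1"),
    fig3_combined = list(net = networkConfig(bFB = 1, scale = scale),
      stim = stimulusConfig(sigma = 1), mode = "non-replicate",
      notes = "non-replicate, bFB = 1"),
    fig3_slow = list(net = networkConfig(bFB = 1, scale = scale,
        gFF = 0.75 * gFF0),
      stim = stimulusConfig(sigma = 1.33), mode = "non-replicate",
      notes = "gFF x 0.75, sigma = 1.33, non-replicate, bFB = 1"),
    fig5_heterogeneous = list(
      net = makeHeterogeneous(networkConfig(bFB = 1, scale = scale)),
      stim = stimulusConfig(sigma = 1), mode = "non-replicate",
      notes = "heterogeneous stimulus/feedback groups, bFB = 1"),
    fig7_bounds = list(
      net = networkConfig(bFB = if (is.null(bFB)) 0 else bFB, scale = scale),
      stim = stimulusConfig(sigma = 2.7), mode = "non-replicate",
      notes = "sigma = 2.7, bFB in {0, 4}"),
    fig7_sweep = list(
      net = networkConfig(bFB = if (is.null(bFB)) 0 else bFB, scale = scale),
      stim = stimulusConfig(sigma = 2.7), mode = "non-replicate",
      notes = "bFB in {0, 1.5, 3, 4.5, 6}; strong modulations (sigma = 2.7) as in the bound analyses"))
  list(network = p$net, stimulus = p$stim, mode = p$mode, notes = p$notes,
       name = name)
}
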