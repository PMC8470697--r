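#' Scaled-down synthetic seal benchmark
#'
#' Bundles the package's standard end-to-end benchmark: a 400-ROI
#' synthetic dataset (class balance proportional to the 1123/989 reference
#' composition, 32 x 32 ROIs, 16 bands) together with reduced-epoch
#' classifier configurations for the full fusion-by-classifier grid. At
#' `effect_size = 5` the spectral contrast between contamination and seal
#' background is far above the per-band noise floor and the grid's
#' PCA-fusion + ELM cell separates the held-out ROIs almost perfectly; at
#' `effect_size = 0` the generator carries no class signal at all and
#' every cell should sit at chance.
#'
#' The classifier settings trade depth/epochs for runtime so the whole
#' 8 x 4 grid finishes in minutes on one CPU; the ELM cell uses one fixed
#' point of the reference (h, activation) grid — 1000 triangular-basis
#' neurons — because locally responsive units pick up the
#' amplitude-distribution cue that separates contaminated seals.
#'
#' @param effect_size spectral contrast multiplier (default 5; 0 gives the
#'   null benchmark).
#' @param n_total total number of ROIs (default 400).
#' @param seed master seed for the generator and splits.
#' @return List with `config` (an [sim_config()]), `model_args` and
#'   `fusion_args` ready for [run_grid()].
#' @export
seal_benchmark <- function(effect_size = 5, n_total = 400L, seed = 1L) {
  n_normal <- round(n_total * 1123 / 2112)
  cfg <- sim_config(roi_size = 32L, n_bands = 16L,
                    n_normal = n_normal, n_faulty = n_total - n_normal,
                    blob_radius = c(3, 6), effect_size = effect_size,
                    noise_sd = 1, illum_sd = 0.01, seed = seed)
  model_args <- list(
    cnn = list(epochs = 20L, batch_size = 32L),
    sae = list(hidden_sizes = c(64L, 32L, 16L), pretrain_epochs = 15L,
               finetune_epochs = 30L),
    dbn = list(hidden_sizes = c(64L, 32L, 16L), epochs = 5L,
               batch_size = 32L, finetune_epochs = 60L),
    elm = list(h = 1000L, activation = "tribas"))
  fusion_args <- list(dwt = list(levels = 3L), sidwt = list(levels = 3L),
                      dtcwt = list(levels = 3L), laplacian = list(T = 3L))
  list(config = cfg, model_args = model_args, fusion_args = fusion_args)
}
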