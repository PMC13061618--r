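# End-to-end convenience pipelines for populations of analytic cells:
# MEI synthesis, ideal-cell VEIs, bipartite series and BII per cell.

#' BII pipeline for one analytic Gabor cell
#'
#' Synthesizes the cell's MEI by gradient ascent and its nonparametric VEIs
#' by the activation-floor / max-min-diversity loss, derives the
#' variable-mask series from the VEI variance map, and runs the texture/BII
#' pipeline.
#'
#' @param model a `simple_cell()` or `complex_cell()` neuron
#' @param config a [synthesis_config()] with `seed`
#' @param fractions variance fractions for the mask series
#' @param iters,K texture-optimization steps and crops per step
#' @return a `bipartite_fit`
#' @export
bii_for_cell <- function(model, config = synthesis_config(seed = 1),
                         fractions = seq(0.20, 0.60, by = 0.05),
                         iters = 400, K = 8) {
  mei <- synthesize_mei(model, config)
  veis <- synthesize_veis(model, mei, config)
  fit_bipartite(model, mei, veis, config, fractions = fractions,
                iters = iters, K = K)
}

#' Population BII study on analytic simple or complex cells
#'
#' Samples `n_cells` Gabor parameter sets, builds the requested cell type
#' for each, runs the per-cell BII pipeline and collects the indices.
#' Defaults use the population-study scale (shortened VEI schedule, a
#' three-point diversity-weight grid, variance fractions in steps of 0.1 and
#' 500-step texture optimizations with 12 crops per step); single-neuron
#' work should prefer the full [synthesis_config()] defaults.
#'
#' @param kind "simple" or "complex"
#' @param n_cells number of cells (default 20)
#' @param shape grid c(rows, cols)
#' @param deg_per_pixel degrees per pixel
#' @param seed RNG seed (mandatory)
#' @param config a [synthesis_config()]; its seed is re-derived per cell
#' @param fractions variance fractions for the mask series
#' @param iters,K texture-optimization steps and crops per step
#' @return list: bii (vector), median, fits (list of `bipartite_fit`)
#' @export
bii_population <- function(kind = c("simple", "complex"), n_cells = 20,
                           shape = default_shape(), deg_per_pixel = 2,
                           seed,
                           config = synthesis_config(
                             seed = seed, vei_iters = 800,
                             lambda_grid = c(1e-4, 2e-3, 5e-2)),
                           fractions = seq(0.2, 0.6, by = 0.1),
                           iters = 500, K = 12) {
  kind <- match.arg(kind)
  pop <- sample_gabor_population(n_cells, seed = seed)
  fits <- vector("list", n_cells)
  bii <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    model <- if (kind == "simple")
      simple_cell(pop[[i]], shape, deg_per_pixel)
    else complex_cell(pop[[i]], shape, deg_per_pixel)
    cfg <- config
    cfg$seed <- seed + 997 * i
    fits[[i]] <- bii_for_cell(model, cfg, fractions = fractions,
                              iters = iters, K = K)
    bii[i] <- fits[[i]]$bii
  }
  list(bii = bii, median = stats::median(bii), fits = fits, kind = kind)
}
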