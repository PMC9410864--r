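#' Read a segmentation configuration from YAML
#'
#' The YAML layout mirrors [segmentation_config()] field for field:
#'
#' ```yaml
#' superpixel: {n_superpixels: 256, m: 10, max_iter: 10}
#' scaling:    {h_s: 16, h_r: 1}       # optional; default h_s = S, h_r = 1
#' dpc:        {d_c: ~, k: ~, density_kernel: weighted_cutoff,
#'              use_entropy_weight: true, decision_rule: product}
#' noise:      {enabled: true, threshold: ~, iterations: 1}
#' seed: 0
#' ```
#'
#' Missing sections fall back to the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A [segmentation_config()].
#' @export
read_segmentation_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(ctor, section) {
    args <- y[[section]]
    if (is.null(args)) ctor() else do.call(ctor, args)
  }
  scaling <- if (is.null(y$scaling)) NULL else do.call(scaling_config,
                                                       y$scaling)
  nz <- y$noise
  if (!is.null(nz) && !is.null(nz$W)) nz$W <- as.numeric(nz$W)
  segmentation_config(
    superpixel = take(superpixel_config, "superpixel"),
    scaling = scaling,
    dpc = take(dpc_config, "dpc"),
    noise = if (is.null(nz)) noise_config() else do.call(noise_config, nz),
    seed = if (is.null(y$seed)) 0L else y$seed)
}
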