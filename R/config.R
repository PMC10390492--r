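#' Analysis configuration with published default thresholds
#'
#' Flat container of every tunable threshold of the toolkit. Defaults are
#' the working values used throughout: colocalization edges require
#' `pcc > min_pcc` (0.06) and BH-adjusted `p < alpha` (0.05); the regulon
#' co-activation network keeps edges with CSI strictly above `csi_edge`
#' (0.85); anterior-posterior gene selection takes the union of the
#' `top_k` (20) correlations per section pattern; axis regulons need
#' `|PCC| > sd_mult (1.5) x SD` of all regulon correlations and a maximum
#' activity above `min_max_ras` (0.2); z-score binarization zeroes spots
#' below `z_min` (2.5); recovery-curve scoring integrates the top
#' `top_frac` (0.05) of the gene ranking; permutation tests draw `n_perm`
#' (1000) label shuffles; log-normalization uses `scale_factor` (10000);
#' occupancy binarization thresholds weights at `weight_threshold` (0.1).
#'
#' @param min_pcc Colocalization PCC threshold (strict >), in \[-1, 1\].
#' @param alpha Significance level for adjusted p-values, in (0, 1).
#' @param csi_edge CSI network edge threshold (strict >), in \[0, 1\].
#' @param top_k Genes kept per section pattern, positive integer.
#' @param sd_mult Multiplier on the SD of regulon-axis correlations.
#' @param min_max_ras Minimum maximum regulon activity (strict >), in \[0, 1\].
#' @param z_min Z-score floor for score binarization.
#' @param top_frac Fraction of the ranking integrated by the recovery
#'   score, in (0, 1\].
#' @param n_perm Number of label permutations, nonnegative integer.
#' @param scale_factor Log-normalization scale factor, positive.
#' @param weight_threshold Occupancy threshold on weights, in (0, 1).
#' @param kh Half-saturation constant of the communication probability.
#' @param n_modules Number of regulon modules cut from the dendrogram.
#' @param seed Integer seed for all stochastic steps.
#' @return An `AnalysisConfig` (classed named list).
#' @export
analysis_config <- function(min_pcc = 0.06, alpha = 0.05, csi_edge = 0.85,
                            top_k = 20L, sd_mult = 1.5, min_max_ras = 0.2,
                            z_min = 2.5, top_frac = 0.05, n_perm = 1000L,
                            scale_factor = 10000, weight_threshold = 0.1,
                            kh = 0.5, n_modules = 7L, seed = 1L) {
  cfg <- list(min_pcc = as.numeric(min_pcc), alpha = as.numeric(alpha),
              csi_edge = as.numeric(csi_edge), top_k = as.integer(top_k),
              sd_mult = as.numeric(sd_mult),
              min_max_ras = as.numeric(min_max_ras),
              z_min = as.numeric(z_min), top_frac = as.numeric(top_frac),
              n_perm = as.integer(n_perm),
              scale_factor = as.numeric(scale_factor),
              weight_threshold = as.numeric(weight_threshold),
              kh = as.numeric(kh), n_modules = as.integer(n_modules),
              seed = as.integer(seed))
  class(cfg) <- c("AnalysisConfig", "list")
  validate_analysis_config(cfg)
  cfg
}

#' Validate an AnalysisConfig
#' @param cfg Object to validate.
#' @return `cfg`, invisibly.
#' @export
validate_analysis_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop("invalid config: ", what)
  chk(cfg$min_pcc >= -1 && cfg$min_pcc <= 1, "min_pcc must be in [-1, 1]")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  chk(cfg$csi_edge >= 0 && cfg$csi_edge <= 1, "csi_edge must be in [0, 1]")
  chk(cfg$top_k >= 1L, "top_k must be >= 1")
  chk(cfg$sd_mult > 0, "sd_mult must be positive")
  chk(cfg$min_max_ras >= 0 && cfg$min_max_ras <= 1, "min_max_ras must be in [0, 1]")
  chk(cfg$top_frac > 0 && cfg$top_frac <= 1, "top_frac must be in (0, 1]")
  chk(cfg$n_perm >= 0L, "n_perm must be >= 0")
  chk(cfg$scale_factor > 0, "scale_factor must be positive")
  chk(cfg$weight_threshold > 0 && cfg$weight_threshold < 1,
      "weight_threshold must be in (0, 1)")
  chk(cfg$kh > 0, "kh must be positive")
  chk(cfg$n_modules >= 2L, "n_modules must be >= 2")
  invisible(cfg)
}

#' Read / write an AnalysisConfig as flat YAML
#'
#' Unknown keys error; missing keys take their defaults, so a partial
#' config is valid. The write/read cycle is lossless.
#'
#' @param path YAML file path.
#' @return `read_config`: an `AnalysisConfig`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) {
    stop("unknown config key(s) in ", path, ": ", paste(bad, collapse = ", "))
  }
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param cfg An `AnalysisConfig`.
#' @export
write_config <- function(cfg, path) {
  validate_analysis_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
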