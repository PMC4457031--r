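#' Pipeline configuration with study defaults
#'
#' Bundles every tunable threshold of the pipeline with its default value.
#' Defaults are the thresholds of the original study design: marker QC at
#' call rate 0.90 / MAF 0.05 / HWE 1e-6, genome-wide alpha 0.05 with
#' Bonferroni correction, variant-site QC depth window [6, 70] with 5-bp
#' spacing and quality 20, panel segregation frequency 0.1, DEG thresholds
#' FDR 0.001 and |log2 ratio| 1, consensus top fraction 0.20, and the human
#' variant filter at damaging score 0.85 with full conservation.
#'
#' @param seed non-negative integer seed used by simulation stages.
#' @param qc,association,finemap,variants,deg,consensus,human named lists
#'   overriding individual block parameters (unknown keys are rejected).
#' @param paths free-form named list of input/output paths.
#' @return A \code{pipeline_config} object (nested named list).
#' @export
pipeline_config <- function(seed = 1L, qc = list(), association = list(),
                            finemap = list(), variants = list(), deg = list(),
                            consensus = list(), human = list(),
                            paths = list()) {
  defaults <- list(
    seed = seed,
    qc = list(call_rate_min = 0.90, maf_min = 0.05, hwe_p_min = 1e-6),
    association = list(alpha = 0.05, max_unknown_frac = 0.5,
                       method = "trend"),
    finemap = list(min_markers = 2L, max_discordant = 1L, refine_min_run = 2L,
                   strict_match = FALSE),
    variants = list(depth_min = 6, depth_max = 70, min_spacing_bp = 5,
                    quality_min = 20, panel_freq_threshold = 0.1),
    deg = list(fdr_max = 0.001, min_abs_log2 = 1, two_sided = "doubled_tail"),
    consensus = list(fraction = 0.20),
    human = list(damaging_min = 0.85, conservation_min = 1.0,
                 required_absent_dbs = c("g1000", "dbsnp", "evs")),
    paths = paths)
  blocks <- list(qc = qc, association = association, finemap = finemap,
                 variants = variants, deg = deg, consensus = consensus,
                 human = human)
  for (b in names(blocks)) {
    unknown <- setdiff(names(blocks[[b]]), names(defaults[[b]]))
    if (length(unknown))
      stop("unknown config key in block '", b, "': ",
           paste(unknown, collapse = ", "))
    defaults[[b]][names(blocks[[b]])] <- blocks[[b]]
  }
  cfg <- structure(defaults, class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  chk <- function(x, lo, hi, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
      stop("config value ", what, " must be a finite number in [", lo, ", ",
           hi, "]")
  }
  if (!is.numeric(cfg$seed) || cfg$seed < 0 || cfg$seed != round(cfg$seed))
    stop("seed must be an integer >= 0")
  chk(cfg$qc$call_rate_min, 0, 1, "qc$call_rate_min")
  chk(cfg$qc$maf_min, 0, 0.5, "qc$maf_min")
  chk(cfg$qc$hwe_p_min, 0, 1, "qc$hwe_p_min")
  chk(cfg$association$alpha, 0, 1, "association$alpha")
  chk(cfg$association$max_unknown_frac, 0, 1, "association$max_unknown_frac")
  if (!cfg$association$method %in% c("trend", "welch"))
    stop("association$method must be 'trend' or 'welch'")
  chk(cfg$finemap$min_markers, 1, Inf, "finemap$min_markers")
  chk(cfg$finemap$max_discordant, 0, Inf, "finemap$max_discordant")
  chk(cfg$finemap$refine_min_run, 1, Inf, "finemap$refine_min_run")
  chk(cfg$variants$depth_min, 0, Inf, "variants$depth_min")
  chk(cfg$variants$depth_max, cfg$variants$depth_min, Inf,
      "variants$depth_max")
  chk(cfg$variants$min_spacing_bp, 0, Inf, "variants$min_spacing_bp")
  chk(cfg$variants$quality_min, 0, Inf, "variants$quality_min")
  chk(cfg$variants$panel_freq_threshold, 0, 1,
      "variants$panel_freq_threshold")
  chk(cfg$deg$fdr_max, 0, 1, "deg$fdr_max")
  chk(cfg$deg$min_abs_log2, 0, Inf, "deg$min_abs_log2")
  if (!cfg$deg$two_sided %in% c("doubled_tail", "minlike"))
    stop("deg$two_sided must be 'doubled_tail' or 'minlike'")
  chk(cfg$consensus$fraction, 1e-12, 1, "consensus$fraction")
  chk(cfg$human$damaging_min, 0, 1, "human$damaging_min")
  chk(cfg$human$conservation_min, 0, 1, "human$conservation_min")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' Unknown keys in the document are rejected; all thresholds are validated
#' against their documented bounds.
#'
#' @param path YAML file.
#' @return [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- c("seed", "qc", "association", "finemap", "variants", "deg",
             "consensus", "human", "paths")
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, c(list(seed = doc$seed %||% 1L),
                             doc[setdiff(names(doc), "seed")]))
}

#' @rdname read_pipeline_config
#' @param cfg a [pipeline_config()].
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
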