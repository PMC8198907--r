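#' Analysis run configuration
#'
#' Collects every threshold of the inference pipeline with its default:
#' the mRNA differential-expression gate (linear fold change strictly
#' greater than 1.6 in either direction, raw p below 0.05), the miRNA gate
#' (fold change of at least 1.3 in either direction, inclusive), the
#' common-target-count percentile filter (nearest-rank 75th percentile),
#' the lncRNA binding-score threshold (0.7), and the descriptive
#' miRNA:lncRNA abundance band (0.25 to 1, inclusive).
#'
#' @param mrna_fc mRNA fold-change gate (strict `>`), default 1.6.
#' @param mrna_p mRNA p-value gate (strict `<`), default 0.05.
#' @param mirna_fc miRNA fold-change gate (inclusive `>=`), default 1.3.
#' @param mirna_p miRNA p-value gate (strict `<`), default 0.05.
#' @param target_count_percentile Nearest-rank percentile of common-target
#'   counts a candidate must reach, in (0, 100]. Default 75.
#' @param binding_score_threshold Minimum lncRNA binding score for a
#'   "predicted to bind" call, default 0.7.
#' @param abundance_band Length-2 numeric, inclusive miRNA:lncRNA abundance
#'   band reported descriptively. Default `c(0.25, 1)`.
#' @param min_site Weakest seed-match site type that makes a transcript a
#'   predicted target; one of `"6mer"`, `"7mer-A1"`, `"7mer-m8"`, `"8mer"`.
#' @param pseudocount Pseudocount added to linear intensities before log2
#'   and to group means before fold changes. Default 1.
#' @param scaling Cross-platform scaling for abundance ratios:
#'   `"per_array_median"` (default) or `"none"`.
#' @param mirna_whitelist Optional character vector restricting candidate
#'   miRNAs (e.g. to an assay-validated subset); `NULL` keeps all.
#' @param seed Integer random seed recorded with the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mrna_fc = 1.6, mrna_p = 0.05,
                       mirna_fc = 1.3, mirna_p = 0.05,
                       target_count_percentile = 75,
                       binding_score_threshold = 0.7,
                       abundance_band = c(0.25, 1.0),
                       min_site = "7mer-A1",
                       pseudocount = 1.0,
                       scaling = c("per_array_median", "none"),
                       mirna_whitelist = NULL,
                       seed = 1L) {
  scaling <- match.arg(scaling)
  min_site <- match.arg(min_site, SITE_TYPES)
  cfg <- list(mrna_fc = mrna_fc, mrna_p = mrna_p,
              mirna_fc = mirna_fc, mirna_p = mirna_p,
              target_count_percentile = target_count_percentile,
              binding_score_threshold = binding_score_threshold,
              abundance_band = abundance_band,
              min_site = min_site,
              pseudocount = pseudocount,
              scaling = scaling,
              mirna_whitelist = mirna_whitelist,
              seed = as.integer(seed))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  thr <- c(cfg$mrna_fc, cfg$mrna_p, cfg$mirna_fc, cfg$mirna_p,
           cfg$binding_score_threshold)
  if (any(!is.finite(thr)) || any(thr <= 0))
    stop("all thresholds must be finite and > 0", call. = FALSE)
  p <- cfg$target_count_percentile
  if (!is.finite(p) || p <= 0 || p > 100)
    stop("target_count_percentile must lie in (0, 100]", call. = FALSE)
  if (length(cfg$abundance_band) != 2L ||
      cfg$abundance_band[1] > cfg$abundance_band[2])
    stop("abundance_band must be an increasing length-2 numeric",
         call. = FALSE)
  if (cfg$pseudocount < 0)
    stop("pseudocount must be >= 0", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file written by [write_run_config()] (or hand-authored
#'   with the same keys; missing keys fall back to defaults).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- run_config()
  keep <- intersect(names(raw), names(base))
  base[keep] <- raw[keep]
  if (!is.null(base$abundance_band))
    base$abundance_band <- as.numeric(base$abundance_band)
  base$seed <- as.integer(base$seed)
  validate_run_config(base)
}

#' Write a run configuration to YAML
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}
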