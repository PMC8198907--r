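#' Relative concentration index (RCI) of a transcript
#'
#' `RCI = log2(cytoplasmic / nuclear)` on abundances in the same normalized
#' units: positive values mean cytoplasmic enrichment, negative nuclear.
#' Non-detection is an explicit state: pass `NA` (or zero) for a compartment
#' in which the transcript was not detected and the result is an `NA` RCI
#' carrying a `status` attribute instead of an error.
#'
#' @param cytoplasmic,nuclear Abundances in the same units; `NA` or 0 marks
#'   non-detection.
#' @return Numeric RCI, or `NA` with attribute `status = "not_detected"` and
#'   a `reason` attribute naming the undetected compartment(s).
#' @export
compute_rci <- function(cytoplasmic, nuclear) {
  nd <- c(if (is.na(cytoplasmic) || cytoplasmic == 0) "cytoplasmic",
          if (is.na(nuclear) || nuclear == 0) "nuclear")
  if (length(nd)) {
    return(structure(NA_real_, status = "not_detected",
                     reason = paste(nd, collapse = ",")))
  }
  if (cytoplasmic < 0 || nuclear < 0)
    stop("compartment abundances must be > 0", call. = FALSE)
  log2(cytoplasmic / nuclear)
}

#' Construct a qPCR sample
#'
#' A sample is the threshold cycle (Ct) of the target gene plus the Cts of
#' at least two reference genes, with a per-primer amplification efficiency
#' `E` in (1, 2.2] (2 = perfect doubling each cycle). Technical-replicate
#' Cts should be averaged before construction.
#'
#' @param target_ct Named length-1 numeric: the target gene's Ct.
#' @param reference_ct Named numeric of length >= 2: reference gene Cts.
#' @param efficiency Named numeric covering the target and every reference
#'   gene; defaults to 2 for all primers when `NULL`.
#' @return A list of class `QpcrSample`.
#' @export
qpcr_sample <- function(target_ct, reference_ct, efficiency = NULL) {
  stopifnot(length(target_ct) == 1L, !is.null(names(target_ct)))
  if (length(reference_ct) < 2L || is.null(names(reference_ct)))
    stop("at least two named reference genes are required", call. = FALSE)
  ct <- c(target_ct, reference_ct)
  if (any(ct <= 0 | ct >= 45))
    stop("Ct values must lie in (0, 45)", call. = FALSE)
  genes <- names(ct)
  if (is.null(efficiency))
    efficiency <- stats::setNames(rep(2, length(genes)), genes)
  missing <- setdiff(genes, names(efficiency))
  if (length(missing))
    stop("missing efficiency for gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  eff <- efficiency[genes]
  if (any(eff <= 1 | eff > 2.2))
    stop("primer efficiencies must lie in (1, 2.2]", call. = FALSE)
  structure(list(target = names(target_ct), target_ct = unname(target_ct),
                 reference_ct = reference_ct, efficiency = eff),
            class = "QpcrSample")
}

#' Efficiency-corrected relative expression against multiple references
#'
#' The target's efficiency-weighted Ct shift between calibrator and sample
#' is normalized by the geometric mean of the reference genes' shifts:
#' `ratio = E_t^(Ct_t,cal - Ct_t,sample) /
#'          geomean_r( E_r^(Ct_r,cal - Ct_r,sample) )`.
#' With all efficiencies equal to 2 this reduces to the classical
#' 2^-ddCt formula, and `relative_expression(s, s)` is exactly 1.
#'
#' @param sample,calibrator `QpcrSample` objects sharing the same target and
#'   reference panel (and efficiencies).
#' @return The relative expression ratio (> 0).
#' @export
relative_expression <- function(sample, calibrator) {
  stopifnot(inherits(sample, "QpcrSample"), inherits(calibrator, "QpcrSample"))
  if (sample$target != calibrator$target)
    stop("sample and calibrator quantify different targets", call. = FALSE)
  refs <- names(sample$reference_ct)
  if (!setequal(refs, names(calibrator$reference_ct)))
    stop("sample and calibrator use different reference panels",
         call. = FALSE)
  e_t <- sample$efficiency[[sample$target]]
  num <- e_t^(calibrator$target_ct - sample$target_ct)
  ref_terms <- vapply(refs, function(r) {
    e_r <- sample$efficiency[[r]]
    e_r^(calibrator$reference_ct[[r]] - sample$reference_ct[[r]])
  }, numeric(1))
  num / exp(mean(log(ref_terms)))
}
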