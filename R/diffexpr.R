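#' Linear and signed fold change between two replicate groups
#'
#' Fold change is computed on the linear intensity scale as
#' `(mean(treated) + pc) / (mean(control) + pc)`. The signed form follows
#' the microarray reporting convention: values below 1 are reported as the
#' negative reciprocal, so a halving is -2 rather than 0.5 and thresholds
#' like "greater than 1.6 or less than -1.6" apply symmetrically.
#'
#' @param control,treated Numeric vectors of linear intensities (>= 2
#'   replicates each).
#' @param pseudocount Non-negative stabilizer added to both group means
#'   (default 1).
#' @return List with elements `fc` (linear, > 0) and `signed`.
#' @export
fold_change <- function(control, treated, pseudocount = 1.0) {
  stopifnot(length(control) >= 2L, length(treated) >= 2L, pseudocount >= 0)
  mc <- mean(control) + pseudocount
  mt <- mean(treated) + pseudocount
  if (mc == 0)
    stop("control mean is zero with pseudocount 0; fold change undefined",
         call. = FALSE)
  fc <- mt / mc
  list(fc = fc, signed = signed_fold_change(fc))
}

#' Signed form of a linear fold change
#' @param fc Linear fold change(s), > 0.
#' @return `fc` when `fc >= 1`, otherwise `-1/fc`.
#' @export
signed_fold_change <- function(fc) ifelse(fc < 1, -1 / fc, fc)

#' Two-group t-test on log2 intensities
#'
#' Two-sided two-sample t-test on `log2(x + pseudocount)`. The default is
#' the pooled-variance Student test, which is exactly calibrated at the
#' small replicate numbers typical of array knockdown designs (3 vs 3; the
#' Welch approximation is noticeably conservative there and is available
#' via `method = "welch"`). Degenerate inputs are defined, not errors: when
#' both groups have zero variance the p-value is 1 for equal means and 0
#' for unequal means.
#'
#' @param control,treated Numeric vectors (>= 2 replicates each).
#' @param pseudocount Added before the log2 transform (default 1).
#' @param method `"student"` (pooled variance, default) or `"welch"`.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
group_test <- function(control, treated, pseudocount = 1.0,
                       method = c("student", "welch")) {
  stopifnot(length(control) >= 2L, length(treated) >= 2L)
  method <- match.arg(method)
  x <- log2(control + pseudocount)
  y <- log2(treated + pseudocount)
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1.0 else 0.0
    if (p == 0 && isTRUE(getOption("spongenet.verbose", FALSE)))
      message("zero variance with unequal means: p = 0 by convention")
    return(p)
  }
  stats::t.test(y, x, var.equal = (method == "student"))$p.value
}

#' Gate differentially expressed features against a knockdown design
#'
#' For every feature and every knockdown arm the linear/signed fold change
#' versus control and a two-sample t-test p-value are computed; a feature is
#' selected
#' when the gate holds in at least one arm (the "at least one reagent"
#' union rule). The fold-change inequality is strict (`>`) by default,
#' matching the mRNA gate; set `ge = TRUE` for the inclusive (`>=`) miRNA
#' gate. The p-value inequality is always strict (`<`).
#'
#' @param x An `ExpressionMatrix`.
#' @param design A `SampleDesign` with a control arm and >= 1 knockdown arm,
#'   each with >= 2 replicates.
#' @param fc_threshold Signed fold-change gate (default 1.6).
#' @param p_threshold p-value gate (default 0.05).
#' @param ge Use `>=` for the fold-change comparison (default `FALSE`).
#' @param pseudocount Passed to [fold_change()] and [group_test()].
#' @param method Test variant passed to [group_test()].
#' @return A data frame of class `ContrastResult` with one row per feature:
#'   per-arm `fc_*`, `signed_fc_*`, `p_*` and `pass_*` columns, a
#'   `direction` (`"up"`, `"down"`, `"mixed"`, `"none"`) derived from the
#'   passing arms, and the `selected` flag.
#' @export
select_regulated <- function(x, design, fc_threshold = 1.6,
                             p_threshold = 0.05, ge = FALSE,
                             pseudocount = 1.0,
                             method = c("student", "welch")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "ExpressionMatrix"))
  check_design(x, design)
  arms <- intersect(c("kd1", "kd2"), unique(design$arm))
  if (!"control" %in% design$arm || !length(arms))
    stop("design needs a control arm and at least one knockdown arm",
         call. = FALSE)
  ctrl <- x$values[, design$sample_id[design$arm == "control"], drop = FALSE]

  res <- data.frame(feature_id = feature_ids(x), stringsAsFactors = FALSE)
  pass <- matrix(FALSE, nrow(res), length(arms),
                 dimnames = list(NULL, arms))
  up <- down <- pass
  for (a in arms) {
    trt <- x$values[, design$sample_id[design$arm == a], drop = FALSE]
    fc <- (rowMeans(trt) + pseudocount) / (rowMeans(ctrl) + pseudocount)
    sfc <- signed_fold_change(fc)
    p <- vapply(seq_len(nrow(res)), function(i)
      group_test(ctrl[i, ], trt[i, ], pseudocount, method), numeric(1))
    ok <- if (ge) abs(sfc) >= fc_threshold else abs(sfc) > fc_threshold
    ok <- ok & (p < p_threshold)
    res[[paste0("fc_", a)]] <- fc
    res[[paste0("signed_fc_", a)]] <- sfc
    res[[paste0("p_", a)]] <- p
    res[[paste0("pass_", a)]] <- ok
    pass[, a] <- ok
    up[, a] <- ok & fc > 1
    down[, a] <- ok & fc < 1
  }
  n_pass <- rowSums(pass)
  n_up <- rowSums(up)
  n_down <- rowSums(down)
  res$direction <- ifelse(n_pass == 0, "none",
                   ifelse(n_up == n_pass, "up",
                   ifelse(n_down == n_pass, "down", "mixed")))
  res$selected <- n_pass > 0
  class(res) <- c("ContrastResult", "data.frame")
  res
}

#' Partition selected features by biotype
#'
#' Tallies a selected feature set by annotation biotype and rolls the tally
#' up into coding vs non-coding, the summary used to show that a knockdown
#' perturbs a large non-coding complement alongside protein-coding genes.
#'
#' @param selected Character vector of selected feature ids (may be empty).
#' @param annotations Annotation data frame (`feature_id`, `biotype`).
#' @return List of class `BiotypePartition`: `counts` (named integer vector
#'   over observed biotypes), `fractions`, `total`, `n_coding`,
#'   `n_noncoding`, `coding_fraction`.
#' @export
partition_biotypes <- function(selected, annotations) {
  if (!length(selected)) {
    out <- list(counts = integer(0), fractions = numeric(0), total = 0L,
                n_coding = 0L, n_noncoding = 0L, coding_fraction = NA_real_)
    class(out) <- "BiotypePartition"
    return(out)
  }
  idx <- match(selected, annotations$feature_id)
  if (anyNA(idx))
    stop("selected feature(s) without annotation: ",
         paste(selected[is.na(idx)], collapse = ", "), call. = FALSE)
  bt <- annotations$biotype[idx]
  bad <- setdiff(unique(bt), BIOTYPES)
  if (length(bad))
    stop("unknown biotype label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  counts <- table(factor(bt, levels = BIOTYPES))
  counts <- counts[counts > 0]
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  n_coding <- sum(counts[names(counts) == "protein_coding"])
  out <- list(counts = counts,
              fractions = counts / total,
              total = total,
              n_coding = n_coding,
              n_noncoding = total - n_coding,
              coding_fraction = n_coding / total)
  class(out) <- "BiotypePartition"
  out
}

#' @export
print.BiotypePartition <- function(x, ...) {
  cat(sprintf("BiotypePartition: %d selected feature(s)\n", x$total))
  if (x$total > 0) {
    for (b in names(x$counts))
      cat(sprintf("  %-15s %5d (%.1f%%)\n", b, x$counts[[b]],
                  100 * x$fractions[[b]]))
    cat(sprintf("  coding fraction: %.3f\n", x$coding_fraction))
  }
  invisible(x)
}
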