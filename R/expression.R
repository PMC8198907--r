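#' Recognized feature biotypes
#'
#' The biotype vocabulary used to annotate expression features: one coding
#' class and the non-coding classes reported by gene-level microarray
#' annotation (long non-coding RNA, microRNA, small nuclear and nucleolar
#' RNA, pseudogene, miscellaneous RNA).
#'
#' @export
BIOTYPES <- c("protein_coding", "lncRNA", "miRNA", "snRNA", "snoRNA",
              "pseudogene", "misc_RNA")

#' Construct an expression matrix with feature annotations
#'
#' The common currency of the pipeline: a features x samples matrix of
#' linear-scale, non-negative intensities, together with a per-feature
#' annotation table (biotype and display symbol). Feature identity is the
#' row-name string; symbols are display attributes only and are never used
#' to collapse features.
#'
#' @param values Numeric matrix, features in rows (rownames required) and
#'   samples in columns (colnames required). All values must be >= 0.
#' @param annotations Data frame with columns `feature_id`, `biotype` and
#'   optionally `symbol`. Every feature of `values` must be annotated unless
#'   `default_biotype` is given.
#' @param default_biotype Optional biotype assigned to features missing from
#'   `annotations`. Defaulting must be explicit: when `NULL` (the default), a
#'   missing annotation is an error.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the numeric matrix) and `annotations` (data frame aligned to
#'   the rows of `values`).
#' @export
expression_matrix <- function(values, annotations = NULL,
                              default_biotype = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("'values' must have feature rownames and sample colnames",
         call. = FALSE)
  dup <- fid[duplicated(fid)]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- sid[duplicated(sid)]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative expression value at feature '%s', sample '%s'",
                 fid[neg[1, 1]], sid[neg[1, 2]]), call. = FALSE)

  if (is.null(annotations))
    annotations <- data.frame(feature_id = character(),
                              biotype = character(),
                              symbol = character(),
                              stringsAsFactors = FALSE)
  if (!all(c("feature_id", "biotype") %in% names(annotations)))
    stop("'annotations' needs columns 'feature_id' and 'biotype'",
         call. = FALSE)
  if (is.null(annotations$symbol))
    annotations$symbol <- annotations$feature_id
  if (anyDuplicated(annotations$feature_id))
    stop("duplicate feature id(s) in annotations", call. = FALSE)

  idx <- match(fid, annotations$feature_id)
  missing <- fid[is.na(idx)]
  if (length(missing)) {
    if (is.null(default_biotype))
      stop("no biotype annotation for feature(s): ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) ", ..." else "",
           "; pass 'default_biotype' to default explicitly", call. = FALSE)
    extra <- data.frame(feature_id = missing, biotype = default_biotype,
                        symbol = missing, stringsAsFactors = FALSE)
    annotations <- rbind(annotations[, c("feature_id", "biotype", "symbol")],
                         extra)
    idx <- match(fid, annotations$feature_id)
  }
  ann <- annotations[idx, c("feature_id", "biotype", "symbol"), drop = FALSE]
  rownames(ann) <- NULL
  bad <- setdiff(unique(ann$biotype), BIOTYPES)
  if (length(bad))
    stop("unknown biotype label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(values = values, annotations = ann),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$annotations$biotype)
  cat("biotypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Feature ids of an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of feature ids in row order.
#' @export
feature_ids <- function(x) rownames(x$values)

#' Sample ids of an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of sample ids in column order.
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from TSV
#'
#' The expression file is tab-separated with a header row of sample ids and
#' the feature id in the first column. Values are linear-scale intensities;
#' scientific notation is accepted and the decimal separator is always the
#' point, independent of locale.
#'
#' @param path Path to the expression TSV.
#' @param annotation_path Optional path to a feature annotation TSV with
#'   columns `feature_id`, `biotype`, `symbol`.
#' @param default_biotype See [expression_matrix()].
#' @return An `ExpressionMatrix` preserving the file's row and column order.
#' @export
read_expression <- function(path, annotation_path = NULL,
                            default_biotype = NULL) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  dup <- samples[duplicated(samples)]
  if (length(dup))
    stop("duplicate sample id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = c("character",
                                          rep("numeric", length(samples))))
  fid <- tab[[1]]
  dup <- fid[duplicated(fid)]
  if (length(dup))
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(values) <- list(fid, samples)
  ann <- if (!is.null(annotation_path)) read_annotations(annotation_path)
  expression_matrix(values, ann, default_biotype = default_biotype)
}

#' Write an expression matrix (and optionally its annotations) to TSV
#'
#' Values are serialized at full double precision so that a write/read
#' round trip reproduces the matrix bit-identically.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output TSV path.
#' @param annotation_path Optional path for the annotation TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, annotation_path = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  lines <- c(paste(c("feature_id", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i) {
               paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  if (!is.null(annotation_path))
    write_annotations(x$annotations, annotation_path)
  invisible(path)
}

#' Read a feature annotation table
#' @param path TSV with columns `feature_id`, `biotype`, optionally `symbol`.
#' @return Data frame of annotations.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("feature_id", "biotype") %in% names(ann)))
    stop("annotation file needs columns 'feature_id' and 'biotype'",
         call. = FALSE)
  ann
}

#' Write a feature annotation table
#' @param annotations Data frame with `feature_id`, `biotype`, `symbol`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a sample design table
#'
#' Maps each sample to a treatment arm (`control`, `kd1`, `kd2`) and a
#' replicate index, emulating the negative-control vs two-knockdown-reagent
#' layout of an antisense-oligonucleotide experiment.
#'
#' @param sample_id Character vector of sample ids (unique).
#' @param arm Character vector, one of `"control"`, `"kd1"`, `"kd2"`.
#' @param replicate Integer replicate index within arm.
#' @return A data frame of class `SampleDesign`.
#' @export
sample_design <- function(sample_id, arm, replicate) {
  if (anyDuplicated(sample_id))
    stop("duplicate sample id(s) in design", call. = FALSE)
  bad <- setdiff(unique(arm), c("control", "kd1", "kd2"))
  if (length(bad))
    stop("unknown arm label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(data.frame(sample_id = as.character(sample_id),
                       arm = as.character(arm),
                       replicate = as.integer(replicate),
                       stringsAsFactors = FALSE),
            class = c("SampleDesign", "data.frame"))
}

#' Read a sample design TSV
#' @param path TSV with columns `sample_id`, `arm`, `replicate`.
#' @return A `SampleDesign` data frame.
#' @export
read_sample_design <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE)
  sample_design(tab$sample_id, tab$arm, tab$replicate)
}

#' Write a sample design TSV
#' @param design A `SampleDesign`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# every design sample must exist in the matrix; >=2 replicates per used arm
check_design <- function(x, design) {
  missing <- setdiff(design$sample_id, sample_ids(x))
  if (length(missing))
    stop("design sample(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  n <- table(design$arm)
  small <- names(n)[n < 2]
  if (length(small))
    stop("arm(s) with fewer than 2 replicates: ",
         paste(small, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Median-scale each array of an expression matrix
#'
#' Divides every sample column by its own median intensity, the default
#' cross-platform scaling applied before miRNA:lncRNA abundance ratios are
#' computed from two different chip types.
#'
#' @param x An `ExpressionMatrix`.
#' @return An `ExpressionMatrix` with scaled values.
#' @export
scale_by_array_median <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  med <- apply(x$values, 2, stats::median)
  if (any(med <= 0))
    stop("array median <= 0; cannot median-scale", call. = FALSE)
  x$values <- sweep(x$values, 2, med, "/")
  x
}
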