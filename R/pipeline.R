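#' Run the full sponge-network inference pipeline
#'
#' Orchestrates the analysis on a dataset (simulated or read from disk):
#' differential-expression gating of the mRNA-level matrix (strict
#' `|FC| > mrna_fc`, `p < mrna_p`, in at least one knockdown arm) and of
#' the miRNA matrix (inclusive `|FC| >= mirna_fc`), biotype partition of
#' the regulated features, seed-match target prediction for the
#' differentially expressed miRNAs, common-target counting against the
#' regulated coding genes with the nearest-rank percentile filter, lncRNA
#' binding scoring, abundance ratios, sponged/induced classification,
#' network assembly and the explained-fraction statistic.
#'
#' Every differentially expressed miRNA is classified; the percentile
#' filter flags the candidates carried into the network (the reportable
#' shortlist), so a sponged call never depends on the count ranking.
#'
#' @param dataset List with elements `mrna`, `mirna` (`ExpressionMatrix`),
#'   `design` (`SampleDesign`), `sequences` (list with `lncrna`, `mirnas`,
#'   `utrs`), `lncrna_id` — a `sponge_simulation` or the result of
#'   [read_dataset()].
#' @param config A [run_config()].
#' @return A list of class `sponge_result`: `mrna_de`, `mirna_de`
#'   (ContrastResult frames), `regulated_coding`, `partition`, `candidates`
#'   (per-miRNA evidence table with classification and filter flag),
#'   `target_map`, `network`, `explained`, `missing_utr` (regulated coding
#'   genes without a UTR sequence, never silently dropped), and `report`.
#' @export
run_sponge_pipeline <- function(dataset, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  mrna <- dataset$mrna
  mirna <- dataset$mirna
  design <- dataset$design
  lncrna_id <- dataset$lncrna_id

  mrna_de <- select_regulated(mrna, design, config$mrna_fc, config$mrna_p,
                              ge = FALSE, pseudocount = config$pseudocount)
  sel <- mrna_de$feature_id[mrna_de$selected]
  ann <- mrna$annotations
  partition <- partition_biotypes(sel, ann)
  regulated_coding <- intersect(
    sel, ann$feature_id[ann$biotype == "protein_coding"])

  mirna_de <- select_regulated(mirna, design, config$mirna_fc, config$mirna_p,
                               ge = TRUE, pseudocount = config$pseudocount)
  cand_ids <- mirna_de$feature_id[mirna_de$selected]
  if (!is.null(config$mirna_whitelist))
    cand_ids <- intersect(cand_ids, config$mirna_whitelist)

  utrs <- dataset$sequences$utrs
  missing_utr <- setdiff(regulated_coding, names(utrs))
  pred <- predict_targets(dataset$sequences$mirnas[cand_ids], utrs,
                          min_site = config$min_site)

  ctrl_samples <- design$sample_id[design$arm == "control"]
  if (identical(config$scaling, "per_array_median")) {
    mirna_sc <- scale_by_array_median(mirna)
    mrna_sc <- scale_by_array_median(mrna)
  } else {
    mirna_sc <- mirna
    mrna_sc <- mrna
  }
  lnc_ctrl <- mrna_sc$values[lncrna_id, ctrl_samples]

  lnc_seqs <- dataset$sequences$lncrna
  de_rows <- mirna_de[match(cand_ids, mirna_de$feature_id), , drop = FALSE]
  candidates <- data.frame(mirna_id = cand_ids, stringsAsFactors = FALSE)
  for (col in setdiff(names(de_rows), c("feature_id", "selected")))
    candidates[[col]] <- de_rows[[col]]
  candidates$common_target_count <- vapply(cand_ids, function(m)
    common_target_count(pred$targets[[m]], regulated_coding), integer(1))
  # max binding score over lncRNA isoforms
  candidates$binding_score <- vapply(cand_ids, function(m) {
    max(vapply(seq_along(lnc_seqs), function(i)
      score_lncrna_binding(lnc_seqs[[i]], dataset$sequences$mirnas[[m]],
                           config$binding_score_threshold)$score,
      numeric(1)), 0)
  }, numeric(1))
  ab <- lapply(cand_ids, function(m)
    abundance_ratio(mirna_sc$values[m, ctrl_samples], lnc_ctrl,
                    band = config$abundance_band))
  candidates$abundance_ratio <- vapply(ab, `[[`, numeric(1), "ratio")
  candidates$in_abundance_band <- vapply(ab, `[[`, logical(1), "in_band")
  candidates$classification <- vapply(seq_len(nrow(candidates)), function(i)
    classify_mirna(candidates$direction[i], candidates$binding_score[i],
                   config$binding_score_threshold), character(1))
  filtered <- percentile_filter(candidates, config$target_count_percentile)
  candidates$passes_count_filter <-
    candidates$mirna_id %in% filtered$mirna_id
  rownames(candidates) <- NULL

  net_cand <- candidates[candidates$passes_count_filter, , drop = FALSE]
  network <- build_network(lncrna_id, net_cand, regulated_coding,
                           pred$targets)
  explained <- if (length(regulated_coding))
    explained_fraction(network, regulated_coding)
  else list(n_regulated_coding = 0L, n_explained = 0L,
            fraction = NA_real_, independent_fraction = NA_real_)

  report <- list(
    config = unclass(config),
    n_mrna_selected = length(sel),
    n_regulated_coding = length(regulated_coding),
    n_missing_utr = length(missing_utr),
    biotype_counts = as.list(partition$counts),
    n_mirna_selected = length(cand_ids),
    n_candidates_after_filter = nrow(net_cand),
    min_common_target_count = attr(filtered, "min_count"),
    n_sponged = sum(candidates$classification == "sponged"),
    n_induced = sum(candidates$classification == "induced"),
    n_unclassified = sum(candidates$classification == "unclassified"),
    n_network_nodes = nrow(network$nodes),
    n_network_edges = nrow(network$edges),
    explained = explained[c("n_regulated_coding", "n_explained", "fraction",
                            "independent_fraction")],
    abundance_ratio_summary = if (nrow(candidates))
      as.list(summary(candidates$abundance_ratio)) else NULL,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("spongenet")))

  structure(list(mrna_de = mrna_de, mirna_de = mirna_de,
                 regulated_coding = regulated_coding,
                 partition = partition, candidates = candidates,
                 target_map = pred$targets, sites = pred$sites,
                 network = network, explained = explained,
                 missing_utr = missing_utr, report = report),
            class = "sponge_result")
}

#' @export
print.sponge_result <- function(x, ...) {
  r <- x$report
  cat("sponge_result\n")
  cat(sprintf("  regulated features: %d (%d coding)\n",
              r$n_mrna_selected, r$n_regulated_coding))
  cat(sprintf("  DE miRNAs: %d (%d sponged, %d induced, %d unclassified)\n",
              r$n_mirna_selected, r$n_sponged, r$n_induced,
              r$n_unclassified))
  if (!is.null(r$explained$fraction) && !is.na(r$explained$fraction))
    cat(sprintf("  explained fraction: %.3f (%d / %d coding genes)\n",
                r$explained$fraction, r$explained$n_explained,
                r$explained$n_regulated_coding))
  invisible(x)
}

#' Simulate, analyse, and export one complete study
#'
#' One reproducible end-to-end run: generates a dataset (unless one is
#' supplied), runs [run_sponge_pipeline()], writes the candidate table, the
#' network in all three formats, and a machine-readable JSON report, then
#' cross-checks every reported count against the written artifacts.
#' Scientific outputs carry no timestamps, so two runs with the same
#' configuration and seed are byte-identical.
#'
#' @param out_dir Output directory for artifacts.
#' @param sim_config A [simulation_config()] (used when `dataset` is
#'   `NULL`).
#' @param config A [run_config()].
#' @param dataset Optional pre-built dataset (see [run_sponge_pipeline()]).
#' @param write_data Also write the simulated dataset files (default
#'   `FALSE`).
#' @param force Overwrite non-empty `out_dir`.
#' @return The `sponge_result`, invisibly; artifacts on disk.
#' @export
run_sponge_study <- function(out_dir, sim_config = simulation_config(),
                             config = run_config(), dataset = NULL,
                             write_data = FALSE, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("output directory exists and is not empty; use force = TRUE",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(dataset)) dataset <- simulate_dataset(sim_config)
  result <- run_sponge_pipeline(dataset, config)

  fp <- function(f) file.path(out_dir, f)
  cand <- result$candidates
  num <- vapply(cand, is.numeric, logical(1))
  cand[num] <- lapply(cand[num], function(v) sprintf("%.17g", v))
  utils::write.table(cand, fp("candidates.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_network(result$network, fp("network.sif"), "SIF")
  write_network(result$network, fp("network.graphml"), "GraphML")
  write_network(result$network, fp("network.json"), "JSON")
  jsonlite::write_json(result$report, fp("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (write_data && inherits(dataset, "sponge_simulation"))
    write_dataset(dataset, file.path(out_dir, "dataset"), force = force)

  audit_report(result, out_dir)
  invisible(result)
}

# self-audit: reported counts must equal artifact sizes
audit_report <- function(result, out_dir) {
  r <- result$report
  sif <- readLines(file.path(out_dir, "network.sif"))
  sif <- sif[nzchar(sif)]
  if (length(sif) != r$n_network_edges)
    stop("report/audit mismatch: SIF edge count", call. = FALSE)
  cand <- utils::read.table(file.path(out_dir, "candidates.tsv"),
                            sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  if (nrow(cand) != r$n_mirna_selected)
    stop("report/audit mismatch: candidate table rows", call. = FALSE)
  net <- read_network(file.path(out_dir, "network.json"), "JSON")
  if (nrow(net$nodes) != r$n_network_nodes)
    stop("report/audit mismatch: network node count", call. = FALSE)
  invisible(TRUE)
}

#' Validate a set of pipeline input files
#'
#' Reads every provided input through the package's checked readers and
#' returns a structured report of what was found; errors are collected per
#' file rather than thrown.
#'
#' @param expression_paths Named character vector of expression TSVs.
#' @param annotation_path Feature annotation TSV (optional).
#' @param design_path Sample design TSV (optional).
#' @param fasta_paths Named character vector of FASTA paths; names give the
#'   role of each file (`lncRNA`, `mature_miRNA`, `utr3`).
#' @return Data frame with columns `input`, `ok`, `detail`.
#' @export
validate_inputs <- function(expression_paths = character(0),
                            annotation_path = NULL, design_path = NULL,
                            fasta_paths = character(0)) {
  rows <- list()
  try_one <- function(label, expr) {
    out <- tryCatch(list(ok = TRUE, detail = expr()),
                    error = function(e) list(ok = FALSE,
                                             detail = conditionMessage(e)))
    rows[[length(rows) + 1L]] <<- data.frame(
      input = label, ok = out$ok, detail = out$detail,
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(expression_paths))
    try_one(expression_paths[[i]], function() {
      x <- read_expression(expression_paths[[i]], annotation_path)
      sprintf("%d features x %d samples", nrow(x$values), ncol(x$values))
    })
  if (!is.null(design_path))
    try_one(design_path, function() {
      d <- read_sample_design(design_path)
      sprintf("%d samples, arms: %s", nrow(d),
              paste(sort(unique(d$arm)), collapse = ","))
    })
  for (i in seq_along(fasta_paths))
    try_one(fasta_paths[[i]], function() {
      s <- read_fasta(fasta_paths[[i]], names(fasta_paths)[i])
      sprintf("%d sequence(s), role %s", length(s), attr(s, "role"))
    })
  do.call(rbind, rows)
}
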