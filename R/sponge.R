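#' Nearest-rank percentile
#'
#' The smallest observed value such that at least `p` percent of the
#' observations are less than or equal to it.
#'
#' @param x Numeric vector (non-empty).
#' @param p Percentile in (0, 100].
#' @return The nearest-rank percentile value.
#' @export
nearest_rank_percentile <- function(x, p) {
  stopifnot(length(x) > 0, p > 0, p <= 100)
  sort(x)[ceiling(p / 100 * length(x))]
}

#' Filter candidate miRNAs by common-target-count percentile
#'
#' Keeps candidates whose common-target count reaches the nearest-rank
#' percentile of the counts among candidates with at least one common
#' target (inclusive comparison, so a fully tied distribution keeps
#' everything). The implied minimum count is attached as the `min_count`
#' attribute.
#'
#' @param candidates Data frame with a `common_target_count` column.
#' @param percentile Percentile in (0, 100], default 75.
#' @return The filtered data frame (possibly empty) with attribute
#'   `min_count`.
#' @export
percentile_filter <- function(candidates, percentile = 75) {
  stopifnot(is.data.frame(candidates),
            "common_target_count" %in% names(candidates))
  if (!nrow(candidates)) {
    attr(candidates, "min_count") <- NA_integer_
    return(candidates)
  }
  counts <- candidates$common_target_count
  pop <- counts[counts >= 1]
  if (!length(pop)) {
    out <- candidates[integer(0), , drop = FALSE]
    attr(out, "min_count") <- NA_integer_
    return(out)
  }
  cutoff <- nearest_rank_percentile(pop, percentile)
  out <- candidates[counts >= cutoff, , drop = FALSE]
  attr(out, "min_count") <- cutoff
  out
}

#' miRNA:lncRNA abundance ratio
#'
#' Ratio of mean miRNA signal to mean lncRNA signal in control-arm samples,
#' with an inclusive in-band flag for the descriptive stoichiometry band.
#' Signals from different chip types should be put on a common scale first
#' (see [scale_by_array_median()]); the ratio is reported as descriptive
#' evidence and is never used as a hard gate.
#'
#' @param mirna_signal,lncrna_signal Numeric vectors of control-arm signals.
#' @param band Inclusive length-2 band, default `c(0.25, 1)`.
#' @return List with `ratio` and `in_band`.
#' @export
abundance_ratio <- function(mirna_signal, lncrna_signal,
                            band = c(0.25, 1.0)) {
  ml <- mean(lncrna_signal)
  if (ml == 0)
    stop("lncRNA signal is zero; abundance ratio undefined", call. = FALSE)
  ratio <- mean(mirna_signal) / ml
  list(ratio = ratio, in_band = ratio >= band[1] && ratio <= band[2])
}

#' Classify a candidate miRNA as sponged, induced, or unclassified
#'
#' A miRNA that rises upon lncRNA knockdown and is predicted to bind the
#' lncRNA (binding score at or above threshold) behaves as a sponged miRNA
#' released by the knockdown. A miRNA that falls upon knockdown is induced
#' (dependent on the lncRNA through an indirect mechanism, with or without
#' predicted binding). Up-regulation without predicted binding, or a mixed
#' direction across knockdown arms, is left unclassified.
#'
#' @param direction Differential-expression direction on knockdown:
#'   `"up"`, `"down"`, or `"mixed"` (see [select_regulated()]).
#' @param binding_score lncRNA binding score in `[0, 1]`.
#' @param binding_threshold Binding call threshold, default 0.7.
#' @return One of `"sponged"`, `"induced"`, `"unclassified"`.
#' @export
classify_mirna <- function(direction, binding_score, binding_threshold = 0.7) {
  direction <- match.arg(direction, c("up", "down", "mixed"))
  if (direction == "down") return("induced")
  if (direction == "up" && binding_score >= binding_threshold)
    return("sponged")
  "unclassified"
}

#' Assemble the tripartite lncRNA-miRNA-mRNA network
#'
#' Nodes are the lncRNA, the classified candidate miRNAs (sponged or
#' induced), and every regulated protein-coding gene connected to at least
#' one candidate. Edges are typed: lncRNA-miRNA edges are `binds` (sponged)
#' or `induces` (induced); miRNA-mRNA edges are `targets` and exist exactly
#' when the gene is regulated and carries a predicted site for that miRNA.
#' Up/down pairing between miRNAs and genes is deliberately not enforced.
#'
#' @param lncrna_id Identifier of the lncRNA node.
#' @param candidates Data frame of classified candidates with columns
#'   `mirna_id`, `classification`, and optionally `signed_fc_kd1`,
#'   `signed_fc_kd2`, `binding_score`, `common_target_count`. Unclassified
#'   rows are ignored.
#' @param regulated_coding Character vector of regulated protein-coding
#'   feature ids.
#' @param target_map Named list, miRNA id -> predicted target transcript
#'   ids. Every classified candidate must be present.
#' @return A `CeRNANetwork`: list with `nodes` and `edges` data frames and
#'   the `lncrna_id`.
#' @export
build_network <- function(lncrna_id, candidates, regulated_coding,
                          target_map) {
  keep <- candidates$classification %in% c("sponged", "induced")
  cand <- candidates[keep, , drop = FALSE]
  absent <- setdiff(cand$mirna_id, names(target_map))
  if (length(absent))
    stop("candidate(s) absent from target map: ",
         paste(absent, collapse = ", "), call. = FALSE)

  num_or_na <- function(col) {
    if (col %in% names(cand)) as.numeric(cand[[col]])
    else rep(NA_real_, nrow(cand))
  }
  nodes <- data.frame(
    id = c(lncrna_id, cand$mirna_id),
    node_type = c("lncRNA", rep("miRNA", nrow(cand))),
    classification = c("", cand$classification),
    signed_fc_kd1 = c(NA_real_, num_or_na("signed_fc_kd1")),
    signed_fc_kd2 = c(NA_real_, num_or_na("signed_fc_kd2")),
    binding_score = c(NA_real_, num_or_na("binding_score")),
    common_target_count = c(NA_real_, num_or_na("common_target_count")),
    stringsAsFactors = FALSE)

  edges <- data.frame(from = character(0), interaction = character(0),
                      to = character(0), stringsAsFactors = FALSE)
  if (nrow(cand)) {
    lnc_edges <- data.frame(
      from = lncrna_id,
      interaction = ifelse(cand$classification == "sponged",
                           "binds", "induces"),
      to = cand$mirna_id, stringsAsFactors = FALSE)
    tgt <- lapply(seq_len(nrow(cand)), function(i) {
      hits <- intersect(target_map[[cand$mirna_id[i]]], regulated_coding)
      if (!length(hits)) return(NULL)
      data.frame(from = cand$mirna_id[i], interaction = "targets",
                 to = hits, stringsAsFactors = FALSE)
    })
    edges <- rbind(lnc_edges, do.call(rbind, tgt))
  }
  mrna_ids <- sort(unique(edges$to[edges$interaction == "targets"]))
  if (length(mrna_ids)) {
    nodes <- rbind(nodes, data.frame(
      id = mrna_ids, node_type = "mRNA", classification = "",
      signed_fc_kd1 = NA_real_, signed_fc_kd2 = NA_real_,
      binding_score = NA_real_, common_target_count = NA_real_,
      stringsAsFactors = FALSE))
  }
  rownames(nodes) <- rownames(edges) <- NULL
  cerna_network(nodes, edges, lncrna_id)
}

#' Construct (and validate) a ceRNA network object
#'
#' @param nodes Data frame with columns `id`, `node_type`
#'   (`lncRNA`/`miRNA`/`mRNA`), `classification`, `signed_fc_kd1`,
#'   `signed_fc_kd2`, `binding_score`, `common_target_count`.
#' @param edges Data frame with columns `from`, `interaction`
#'   (`binds`/`induces`/`targets`), `to`.
#' @param lncrna_id The lncRNA node id.
#' @return A `CeRNANetwork`.
#' @export
cerna_network <- function(nodes, edges, lncrna_id) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s)", call. = FALSE)
  bad <- setdiff(unique(edges$interaction), c("binds", "induces", "targets"))
  if (length(bad))
    stop("unknown edge type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  mi <- nodes$id[nodes$node_type == "miRNA"]
  if (any(!nodes$classification[nodes$node_type == "miRNA"] %in%
          c("sponged", "induced")))
    stop("every miRNA node must be a classified candidate", call. = FALSE)
  mr <- nodes$id[nodes$node_type == "mRNA"]
  orphan <- setdiff(mr, edges$to[edges$interaction == "targets"])
  if (length(orphan))
    stop("orphan mRNA node(s): ", paste(orphan, collapse = ", "),
         call. = FALSE)
  structure(list(nodes = nodes, edges = edges, lncrna_id = lncrna_id),
            class = "CeRNANetwork")
}

#' @export
print.CeRNANetwork <- function(x, ...) {
  tab <- table(factor(x$nodes$node_type, c("lncRNA", "miRNA", "mRNA")))
  cat(sprintf(paste0("CeRNANetwork: lncRNA '%s', %d miRNA node(s), ",
                     "%d mRNA node(s), %d edge(s)\n"),
              x$lncrna_id, tab[["miRNA"]], tab[["mRNA"]], nrow(x$edges)))
  invisible(x)
}

#' Fraction of regulated coding genes explained by candidate miRNAs
#'
#' A regulated protein-coding gene is "explained" when the network connects
#' it to at least one candidate miRNA (it is a predicted target of a
#' sponged or induced miRNA). The complementary fraction is the share of
#' regulation independent of the detected miRNA changes.
#'
#' @param network A `CeRNANetwork` built from the same regulated set.
#' @param regulated_coding Character vector of regulated protein-coding
#'   feature ids (non-empty).
#' @return List of class `ExplainedFraction`: `n_regulated_coding`,
#'   `n_explained`, `fraction`, `independent_fraction`.
#' @export
explained_fraction <- function(network, regulated_coding) {
  stopifnot(inherits(network, "CeRNANetwork"))
  if (!length(regulated_coding))
    stop("regulated coding set is empty; fraction undefined", call. = FALSE)
  connected <- unique(network$edges$to[network$edges$interaction == "targets"])
  n_exp <- length(intersect(regulated_coding, connected))
  out <- list(n_regulated_coding = length(regulated_coding),
              n_explained = n_exp,
              fraction = n_exp / length(regulated_coding),
              independent_fraction = 1 - n_exp / length(regulated_coding))
  class(out) <- "ExplainedFraction"
  out
}

#' @export
print.ExplainedFraction <- function(x, ...) {
  cat(sprintf(paste0("ExplainedFraction: %d / %d regulated coding genes ",
                     "explained (%.1f%%; %.1f%% miRNA-independent)\n"),
              x$n_explained, x$n_regulated_coding, 100 * x$fraction,
              100 * x$independent_fraction))
  invisible(x)
}

#' Venn region counts of regulated genes across miRNA target sets
#'
#' Enumerates all 2^k - 1 intersection regions of up to six target sets,
#' restricted to a regulated universe, and counts the regulated genes
#' falling in each exclusive region. Region counts sum to the size of the
#' union intersected with the regulated set.
#'
#' @param target_sets Named list (length 1-6) of character vectors.
#' @param regulated_set Character vector; the universe of counted genes.
#' @return Data frame with one row per region: logical membership columns
#'   (one per set), a `region` label, and `count`.
#' @export
venn_counts <- function(target_sets, regulated_set) {
  k <- length(target_sets)
  if (k < 1L) stop("need at least one set", call. = FALSE)
  if (k > 6L)
    stop("more than 6 sets; region enumeration is intractable, ",
         "use pairwise overlaps instead", call. = FALSE)
  if (is.null(names(target_sets)))
    names(target_sets) <- paste0("set", seq_len(k))
  sets <- lapply(target_sets, intersect, y = regulated_set)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(patterns) <- names(sets)
  patterns$region <- apply(patterns[, seq_len(k), drop = FALSE], 1, function(r)
    paste(names(sets)[as.logical(r)], collapse = "&"))
  patterns$count <- apply(patterns[, seq_len(k), drop = FALSE], 1, function(r) {
    if (!length(universe)) return(0L)
    sum(apply(member, 1, function(m) all(m == as.logical(r))))
  })
  rownames(patterns) <- NULL
  patterns
}
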