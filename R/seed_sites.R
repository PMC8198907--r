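#' Canonical seed-match site types, weakest to strongest
#'
#' `6mer` matches miRNA nucleotides 2-7; `7mer-A1` adds an adenosine on the
#' target opposite miRNA position 1; `7mer-m8` instead extends the match to
#' miRNA position 8; `8mer` has both. Order encodes the efficacy hierarchy
#' used by `min_site` thresholds.
#'
#' @export
SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

#' Per-site binding weights
#'
#' Surrogate contribution of a single site of each type to the 0-1 lncRNA
#' binding score (combined across sites as a noisy-OR). Calibrated so a
#' single 8mer clears the default 0.7 binding threshold while weak sites
#' alone do not.
#'
#' @export
SITE_WEIGHTS <- c("6mer" = 0.15, "7mer-A1" = 0.40,
                  "7mer-m8" = 0.55, "8mer" = 0.80)

#' Seed of a mature miRNA
#'
#' Nucleotides 2-8 of the mature sequence (the canonical 7-nt seed).
#'
#' @param mature Mature miRNA sequence, 5' to 3' (18-26 nt).
#' @return The 7-nt seed string.
#' @export
mirna_seed <- function(mature) {
  s <- chartr("T", "U", toupper(mature))
  if (nchar(s) < 8L)
    stop("mature sequence too short to carry a 2-8 seed", call. = FALSE)
  substr(s, 2L, 8L)
}

# target-strand patterns derived from a mature sequence:
#   core6    rc(miRNA nt 2-7), present in every site type
#   m8_base  complement of miRNA nt 8, immediately 5' of the core on target
# 6mer = core6; 7mer-m8 = m8_base+core6; 7mer-A1 = core6+"A"; 8mer = both.
seed_patterns <- function(mature) {
  s <- chartr("T", "U", toupper(mature))
  seed <- mirna_seed(s)
  list(core6 = reverse_complement(substr(s, 2L, 7L)),
       m8_base = complement_base(substr(s, 8L, 8L)))
}

# all (possibly overlapping) start positions of fixed-width 'pat' in 'x'
match_all <- function(x, pat) {
  n <- nchar(x)
  w <- nchar(pat)
  if (n < w) return(integer(0))
  which(substring(x, seq_len(n - w + 1L), seq_len(n - w + 1L) + w - 1L) == pat)
}

#' Find canonical seed-match sites on a target transcript
#'
#' Scans every position of the target (5' to 3') for the Watson-Crick match
#' to the miRNA seed. Each occurrence of the 6-nt core is assigned its single
#' best site type by inspecting the flanking bases: a complement of miRNA
#' position 8 immediately 5' of the core upgrades the match at that end, an
#' adenosine immediately 3' anchors position 1. Overlapping readings of the
#' same core are thereby merged into the longest type; distinct cores are
#' all reported, sorted by start. G:U wobble pairs are not allowed.
#'
#' @param target_seq Target transcript sequence (length >= 6).
#' @param mature Mature miRNA sequence, 5' to 3'.
#' @param mirna_id,transcript_id Identifiers copied into the result.
#' @return Data frame with columns `mirna_id`, `transcript_id`, `site_type`,
#'   `start`, `end` (0-based, half-open, on the target strand), `weight`,
#'   and `site_seq` (the matched substring).
#' @export
find_seed_sites <- function(target_seq, mature, mirna_id = NA_character_,
                            transcript_id = NA_character_) {
  target <- chartr("T", "U", toupper(target_seq))
  pat <- seed_patterns(mature)
  n <- nchar(target)
  hits <- match_all(target, pat$core6)
  if (!length(hits)) return(empty_sites())

  has_m8 <- hits > 1L &
    substring(target, hits - 1L, hits - 1L) == pat$m8_base
  has_a1 <- hits + 6L <= n &
    substring(target, hits + 6L, hits + 6L) == "A"
  type <- ifelse(has_m8 & has_a1, "8mer",
          ifelse(has_m8, "7mer-m8",
          ifelse(has_a1, "7mer-A1", "6mer")))
  start1 <- ifelse(has_m8, hits - 1L, hits)           # 1-based
  len <- c("6mer" = 6L, "7mer-A1" = 7L, "7mer-m8" = 7L, "8mer" = 8L)[type]
  out <- data.frame(mirna_id = mirna_id, transcript_id = transcript_id,
                    site_type = unname(type),
                    start = as.integer(start1 - 1L),
                    end = as.integer(start1 - 1L + len),
                    weight = unname(SITE_WEIGHTS[type]),
                    site_seq = substring(target, start1, start1 + len - 1L),
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

empty_sites <- function() {
  data.frame(mirna_id = character(0), transcript_id = character(0),
             site_type = character(0), start = integer(0), end = integer(0),
             weight = numeric(0), site_seq = character(0),
             stringsAsFactors = FALSE)
}

#' Predict miRNA targets across a set of 3'UTRs
#'
#' A transcript is a predicted target of a miRNA when it carries at least
#' one seed-match site of type `min_site` or stronger (site strength
#' ordered `6mer < 7mer-A1 < 7mer-m8 < 8mer`).
#'
#' @param mirnas A `SequenceSet` of mature miRNAs.
#' @param utrs A `SequenceSet` of target transcript sequences.
#' @param min_site Weakest qualifying site type (default `"7mer-A1"`).
#' @return List with `targets` (named list: miRNA id -> character vector of
#'   target transcript ids) and `sites` (data frame of all qualifying
#'   sites).
#' @export
predict_targets <- function(mirnas, utrs, min_site = "7mer-A1") {
  min_site <- match.arg(min_site, SITE_TYPES)
  min_rank <- match(min_site, SITE_TYPES)
  all_sites <- vector("list", length(mirnas) * length(utrs))
  k <- 0L
  targets <- stats::setNames(vector("list", length(mirnas)), names(mirnas))
  for (m in names(mirnas)) {
    hit <- character(0)
    for (t in names(utrs)) {
      s <- find_seed_sites(utrs[[t]], mirnas[[m]], m, t)
      s <- s[match(s$site_type, SITE_TYPES) >= min_rank, , drop = FALSE]
      if (nrow(s)) {
        hit <- c(hit, t)
        k <- k + 1L
        all_sites[[k]] <- s
      }
    }
    targets[[m]] <- hit
  }
  sites <- if (k) do.call(rbind, all_sites[seq_len(k)]) else empty_sites()
  rownames(sites) <- NULL
  list(targets = targets, sites = sites)
}

#' Score the binding of a miRNA to a lncRNA
#'
#' All canonical sites on the lncRNA are combined by a noisy-OR:
#' `score = 1 - prod(1 - w(site))` with the weights in [SITE_WEIGHTS].
#' The score is 0 exactly when there are no sites, lies in `[0, 1]`, and
#' strictly increases with every added site. A miRNA is "predicted to bind"
#' when the score reaches `threshold`.
#'
#' @param lncrna_seq lncRNA sequence (length >= 6).
#' @param mature Mature miRNA sequence.
#' @param threshold Binding call threshold (default 0.7).
#' @param mirna_id,transcript_id Identifiers copied into the site table.
#' @return List of class `BindingScore`: `score`, `bound`, `sites`.
#' @export
score_lncrna_binding <- function(lncrna_seq, mature, threshold = 0.7,
                                 mirna_id = NA_character_,
                                 transcript_id = NA_character_) {
  sites <- find_seed_sites(lncrna_seq, mature, mirna_id, transcript_id)
  score <- 1 - prod(1 - sites$weight)
  structure(list(score = score, bound = score >= threshold, sites = sites),
            class = "BindingScore")
}

#' Number of common targets between a miRNA and a regulated gene set
#'
#' @param mirna_targets Character vector of predicted target transcript ids
#'   for one miRNA (an element of `predict_targets()$targets`).
#' @param regulated_gene_ids Character vector of regulated feature ids.
#' @return Integer size of the intersection.
#' @export
common_target_count <- function(mirna_targets, regulated_gene_ids) {
  length(intersect(mirna_targets, regulated_gene_ids))
}
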