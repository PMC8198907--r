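#' Configuration of the ceRNA titration simulator
#'
#' The generator emulates a lncRNA knockdown study: three arms (control and
#' two knockdown reagents of different efficiency) with replicate arrays for
#' an mRNA-level and a miRNA-level matrix, transcript sequences carrying
#' planted canonical seed-match sites, and a mass-action titration model
#' that converts site occupancy into equilibrium expression levels.
#'
#' Planted structure: `n_sponged` miRNAs carry 8mer sites on the lncRNA and
#' rise when it is knocked down; `n_induced` miRNAs depend on the lncRNA
#' without binding it and fall on knockdown; the remaining miRNAs are null.
#' Sponged and induced miRNAs repress dedicated pools of protein-coding
#' genes (each pool gene is hit by several miRNAs so its regulation clears
#' the fold-change gate), null miRNAs repress a disjoint pool so their free
#' levels are provably arm-invariant, and `n_direct_coding` +
#' `n_direct_noncoding` features respond to the lncRNA directly without any
#' miRNA involvement — these are the ground-truth "miRNA-independent"
#' complement of the explained fraction.
#'
#' @param n_mrna Features on the mRNA-level array (default 500).
#' @param frac_coding Fraction of protein-coding features (default 0.8).
#' @param n_mirna Number of miRNAs (default 60).
#' @param n_sponged,n_induced Planted sponged / induced miRNAs (6 / 4).
#' @param lncrna_length,utr_length,mirna_length Sequence lengths in nt
#'   (2500 / 1000 / 22).
#' @param lncrna_log2_mean,lncrna_log2_sd,mirna_log2_mean,mirna_log2_sd,mrna_log2_mean,mrna_log2_sd
#'   Log2 mean and sd of the log-normal base abundances (lncRNA copies L0,
#'   miRNA totals M, mRNA basals T0).
#' @param K Affinity constant of the titration model, abundance units
#'   (default 100).
#' @param rho Repression strength, dimensionless (default 1).
#' @param gamma Induction exponent linking induced-miRNA totals to the
#'   lncRNA level (default 1).
#' @param e_kd1,e_kd2 Knockdown efficiencies of the two reagents in
#'   `[0, 1)` (defaults 0.6, 0.5).
#' @param replicates Replicates per arm (default 3).
#' @param sigma Log2-scale sd of multiplicative measurement noise
#'   (default 0.15).
#' @param lnc_sites_min,lnc_sites_max Planted lncRNA 8mer sites per sponged
#'   miRNA (1-3).
#' @param utr_sites_min,utr_sites_max Planted sites per miRNA-target pair in
#'   the sponged/induced pools (2-3).
#' @param n_sponge_pool,mirnas_per_sponge_gene Size of the sponged-miRNA
#'   target pool and miRNAs hitting each pool gene (18, 3).
#' @param n_induced_pool,mirnas_per_induced_gene Same for induced miRNAs
#'   (18, 2).
#' @param n_null_pool,null_targets_per_mirna Disjoint pool repressed by null
#'   miRNAs (60 genes, 5 targets each, one site per pair).
#' @param n_direct_coding,n_direct_noncoding Features regulated by the
#'   lncRNA without miRNA involvement (12 coding, 6 non-coding).
#' @param direct_exponent Magnitude of the log-linear direct response
#'   (level scales with `(L/L0)^(+/- direct_exponent)`; default 1.2).
#' @param seed Integer random seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_mrna = 500, frac_coding = 0.8,
                              n_mirna = 60, n_sponged = 6, n_induced = 4,
                              lncrna_length = 2500, utr_length = 1000,
                              mirna_length = 22,
                              lncrna_log2_mean = 9, lncrna_log2_sd = 0.2,
                              mirna_log2_mean = 9, mirna_log2_sd = 0.25,
                              mrna_log2_mean = 7.5, mrna_log2_sd = 0.5,
                              K = 100, rho = 1, gamma = 1,
                              e_kd1 = 0.6, e_kd2 = 0.5,
                              replicates = 3, sigma = 0.15,
                              lnc_sites_min = 1, lnc_sites_max = 3,
                              utr_sites_min = 2, utr_sites_max = 3,
                              n_sponge_pool = 18, mirnas_per_sponge_gene = 3,
                              n_induced_pool = 18, mirnas_per_induced_gene = 2,
                              n_null_pool = 60, null_targets_per_mirna = 5,
                              n_direct_coding = 12, n_direct_noncoding = 6,
                              direct_exponent = 1.2,
                              seed = 1L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (cfg$e_kd1 < 0 || cfg$e_kd1 >= 1 || cfg$e_kd2 < 0 || cfg$e_kd2 >= 1)
    stop("knockdown efficiencies must lie in [0, 1)", call. = FALSE)
  if (cfg$sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (cfg$n_sponged + cfg$n_induced > cfg$n_mirna)
    stop("n_sponged + n_induced exceeds n_mirna", call. = FALSE)
  if (cfg$K <= 0 || cfg$rho < 0)
    stop("K must be > 0 and rho >= 0", call. = FALSE)
  if (cfg$replicates < 2)
    stop("at least 2 replicates per arm are required", call. = FALSE)
  n_coding <- round(cfg$n_mrna * cfg$frac_coding)
  need <- cfg$n_sponge_pool + cfg$n_induced_pool + cfg$n_null_pool +
    cfg$n_direct_coding
  if (need > n_coding)
    stop("target pools exceed the number of coding genes", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' Solve the mass-action titration steady state
#'
#' The sponge model: each miRNA `m` distributes between a free pool and
#' site-bound pools on its target transcripts, so its free level is
#' `F_m = M_m / (1 + sum_t n_mt * T_t / K)`, where `t` runs over the mRNAs
#' and the lncRNA (whose abundance `L` is exogenous). Each mRNA is in turn
#' repressed by the free miRNAs bound to it:
#' `T_t = T0_t / prod_m (1 + rho * n_mt * F_m / K)`.
#' The coupled system is solved by fixed-point iteration from `T = T0`; the
#' composite map is componentwise monotone, so the iteration converges
#' monotonically from above.
#'
#' @param M Total miRNA pools (length `n_mirna`); for induced miRNAs pass
#'   the lncRNA-scaled totals.
#' @param T0 Basal mRNA levels (length `n_mrna`).
#' @param L Exogenous lncRNA abundance.
#' @param N Site-count matrix, `n_mirna` rows x `n_mrna + 1` columns; the
#'   last column holds lncRNA site counts.
#' @param K Affinity constant (> 0).
#' @param rho Repression strength (>= 0).
#' @param tol Maximum absolute relative change for convergence
#'   (default 1e-10).
#' @param max_iter Iteration cap (default 1000); non-convergence is an
#'   error reporting the residual.
#' @return List with `T` (equilibrium mRNA levels), `F` (free miRNA
#'   levels), and `iterations`.
#' @export
steady_state <- function(M, T0, L, N, K = 100, rho = 1,
                         tol = 1e-10, max_iter = 1000L) {
  nt <- length(T0)
  stopifnot(nrow(N) == length(M), ncol(N) == nt + 1L, L >= 0,
            all(T0 > 0), all(M > 0))
  Tl <- T0
  Fm <- M
  delta <- Inf
  for (it in seq_len(max_iter)) {
    F_new <- M / (1 + as.vector(N %*% c(Tl, L)) / K)
    rep_log <- colSums(log1p(rho * N[, seq_len(nt), drop = FALSE] *
                               F_new / K))
    T_new <- T0 / exp(rep_log)
    delta <- max(abs(T_new - Tl) / pmax(Tl, .Machine$double.xmin),
                 abs(F_new - Fm) / pmax(Fm, .Machine$double.xmin))
    Tl <- T_new
    Fm <- F_new
    if (delta < tol) break
  }
  if (delta >= tol)
    stop(sprintf("steady state did not converge in %d iterations (residual %.3e)",
                 max_iter, delta), call. = FALSE)
  list(T = Tl, F = Fm, iterations = it)
}

# ---- sequence construction ------------------------------------------------

.SIM_BASES <- c("A", "C", "G", "U")

random_bases <- function(n) sample(.SIM_BASES, n, replace = TRUE)

# positions (1-based) of every occurrence of any core in the string,
# as a data frame (core index, position)
scan_cores <- function(s, cores) {
  n <- nchar(s)
  if (n < 6L) return(data.frame(core = integer(0), pos = integer(0)))
  windows <- substring(s, seq_len(n - 5L), seq_len(n - 5L) + 5L)
  idx <- which(windows %in% cores)
  data.frame(core = match(windows[idx], cores), pos = idx)
}

# draw a panel of mature miRNA sequences whose seed cores are mutually
# orthogonal: cores are unique, never occur inside another miRNA's full
# 8mer site pattern, and do not self-overlap (so a planted site scans back
# as exactly one core occurrence)
generate_mirnas <- function(n, len) {
  seqs <- character(n)
  cores <- character(n)
  p8s <- character(n)
  i <- 1L
  tries <- 0L
  while (i <= n) {
    tries <- tries + 1L
    if (tries > 20000L)
      stop("failed to draw an orthogonal miRNA panel", call. = FALSE)
    cand <- paste(random_bases(len), collapse = "")
    pat <- seed_patterns(cand)
    core <- pat$core6
    p8 <- paste0(pat$m8_base, core, "A")
    # self-overlap: core may only appear at offset 2 of its own pattern
    wins <- substring(p8, 1:3, 6:8)
    if (sum(wins == core) != 1L) next
    ok <- TRUE
    for (j in seq_len(i - 1L)) {
      if (core == cores[j] ||
          core %in% substring(p8s[j], 1:3, 6:8) ||
          cores[j] %in% wins) { ok <- FALSE; break }
    }
    if (!ok) next
    seqs[i] <- cand
    cores[i] <- core
    p8s[i] <- p8
    i <- i + 1L
  }
  list(seqs = seqs, cores = cores)
}

# remove every chance occurrence of the given cores from a background
# character vector by point mutation
scrub_background <- function(chars, cores) {
  for (pass in 1:50) {
    hits <- scan_cores(paste(chars, collapse = ""), cores)
    if (!nrow(hits)) return(chars)
    for (p in hits$pos) {
      off <- sample.int(6L, 1L) - 1L
      chars[p + off] <- sample(setdiff(.SIM_BASES, chars[p + off]), 1L)
    }
  }
  stop("failed to scrub chance seed matches", call. = FALSE)
}

.SITE_LEN <- c("6mer" = 6L, "7mer-A1" = 7L, "7mer-m8" = 7L, "8mer" = 8L)

# Plant the requested sites into one background sequence. 'requests' is a
# data frame (mirna, site_type) of sites to place at non-overlapping
# positions. Flanking bases are fixed so the planted site scans back as
# exactly its requested type. Returns the mutated chars plus bookkeeping:
# planted site table, protected pattern intervals, per-position forbidden
# flank bases.
plant_sites <- function(chars, requests, patterns) {
  n <- length(chars)
  forbidden <- character(n)
  zones <- matrix(numeric(0), ncol = 2)      # reserved [start-1, end+1]
  planted <- data.frame(mirna = integer(0), site_type = character(0),
                        start1 = integer(0), core_pos = integer(0),
                        stringsAsFactors = FALSE)
  if (nrow(requests) == 0L)
    return(list(chars = chars, planted = planted, forbidden = forbidden,
                protected = zones))
  protected <- matrix(numeric(0), ncol = 2)  # pattern body [start, end]
  for (r in seq_len(nrow(requests))) {
    m <- requests$mirna[r]
    type <- requests$site_type[r]
    w <- .SITE_LEN[[type]]
    pat <- patterns[[m]]
    placed <- FALSE
    for (attempt in 1:500) {
      s1 <- sample(2:(n - w), 1L)            # keep 1-nt flanks inside
      lo <- s1 - 1L
      hi <- s1 + w
      if (nrow(zones) &&
          any(zones[, 1] <= hi & zones[, 2] >= lo)) next
      body <- switch(type,
        "8mer"    = c(pat$m8_base, strsplit(pat$core6, "")[[1]], "A"),
        "7mer-m8" = c(pat$m8_base, strsplit(pat$core6, "")[[1]]),
        "7mer-A1" = c(strsplit(pat$core6, "")[[1]], "A"),
        "6mer"    = strsplit(pat$core6, "")[[1]])
      chars[s1:(s1 + w - 1L)] <- body
      if (type %in% c("7mer-A1", "6mer")) {  # must not read as m8-extended
        chars[s1 - 1L] <- sample(setdiff(.SIM_BASES, pat$m8_base), 1L)
        forbidden[s1 - 1L] <- pat$m8_base
      }
      if (type %in% c("7mer-m8", "6mer")) {  # must not read as A1-anchored
        chars[s1 + w] <- sample(setdiff(.SIM_BASES, "A"), 1L)
        forbidden[s1 + w] <- "A"
      }
      zones <- rbind(zones, c(lo, hi))
      protected <- rbind(protected, c(s1, s1 + w - 1L))
      core_pos <- if (type %in% c("8mer", "7mer-m8")) s1 + 1L else s1
      planted <- rbind(planted, data.frame(
        mirna = m, site_type = type, start1 = s1, core_pos = core_pos,
        stringsAsFactors = FALSE))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("sequence too short to host the requested sites", call. = FALSE)
  }
  list(chars = chars, planted = planted, forbidden = forbidden,
       protected = protected)
}

# after planting, mutate away any stray core occurrence that is not a
# recorded planted core, without touching pattern bodies and respecting
# flank constraints
fix_strays <- function(chars, cores, planted, protected, forbidden) {
  in_protected <- function(p) {
    nrow(protected) && any(protected[, 1] <= p & protected[, 2] >= p)
  }
  for (pass in 1:50) {
    hits <- scan_cores(paste(chars, collapse = ""), cores)
    expected <- paste(planted$mirna, planted$core_pos)
    stray <- hits[!paste(hits$core, hits$pos) %in% expected, , drop = FALSE]
    if (!nrow(stray)) return(chars)
    for (r in seq_len(nrow(stray))) {
      ps <- stray$pos[r] + 0:5
      ps <- ps[!vapply(ps, in_protected, logical(1))]
      if (!length(ps))
        stop("stray seed match inside a planted site; cannot repair",
             call. = FALSE)
      p <- ps[[sample.int(length(ps), 1L)]]
      avoid <- c(chars[p], forbidden[p])
      chars[p] <- sample(setdiff(.SIM_BASES, avoid), 1L)
    }
  }
  stop("failed to repair stray seed matches", call. = FALSE)
}

#' Generate simulator sequences with planted seed sites
#'
#' Draws the mature miRNA panel, the lncRNA, and one 3'UTR per coding gene,
#' plants the configured sites (8mers on the lncRNA for sponged miRNAs;
#' sites of types 8mer/7mer-m8/7mer-A1 in target UTRs), and removes chance
#' seed matches from every background so the planted site map is exactly
#' the set of scannable sites. Uses the current RNG state; callers seed it.
#'
#' @param config A `simulation_config`.
#' @param assignment Data frame (`mirna_id`, `transcript_id`, `n_sites`)
#'   describing which miRNA targets which transcript; rows with
#'   `transcript_id` equal to the lncRNA id plant 8mers on the lncRNA.
#' @param mirna_ids,coding_ids,lncrna_id Identifier vectors.
#' @return List with `mirnas`, `lncrna`, `utrs` (SequenceSets) and
#'   `planted_sites` (data frame: `mirna_id`, `transcript_id`, `site_type`,
#'   `start` 0-based).
#' @export
generate_sequences <- function(config, assignment, mirna_ids, coding_ids,
                               lncrna_id) {
  panel <- generate_mirnas(config$n_mirna, config$mirna_length)
  patterns <- lapply(panel$seqs, seed_patterns)
  names(panel$seqs) <- mirna_ids

  build_seq <- function(len, reqs) {
    chars <- scrub_background(random_bases(len), panel$cores)
    pl <- plant_sites(chars, reqs, patterns)
    chars <- fix_strays(pl$chars, panel$cores, pl$planted, pl$protected,
                        pl$forbidden)
    list(seq = paste(chars, collapse = ""), planted = pl$planted)
  }
  expand_requests <- function(rows, types) {
    if (!nrow(rows)) return(data.frame(mirna = integer(0),
                                       site_type = character(0)))
    do.call(rbind, lapply(seq_len(nrow(rows)), function(i) data.frame(
      mirna = match(rows$mirna_id[i], mirna_ids),
      site_type = sample(types, rows$n_sites[i], replace = TRUE),
      stringsAsFactors = FALSE)))
  }

  site_rows <- list()
  lnc_req <- expand_requests(
    assignment[assignment$transcript_id == lncrna_id, , drop = FALSE],
    "8mer")
  lnc <- build_seq(config$lncrna_length, lnc_req)
  if (nrow(lnc$planted))
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      mirna_id = mirna_ids[lnc$planted$mirna], transcript_id = lncrna_id,
      site_type = lnc$planted$site_type, start = lnc$planted$start1 - 1L,
      stringsAsFactors = FALSE)

  utr_types <- c("8mer", "7mer-m8", "7mer-A1")
  utrs <- character(length(coding_ids))
  for (i in seq_along(coding_ids)) {
    reqs <- expand_requests(
      assignment[assignment$transcript_id == coding_ids[i], , drop = FALSE],
      utr_types)
    built <- build_seq(config$utr_length, reqs)
    utrs[i] <- built$seq
    if (nrow(built$planted))
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        mirna_id = mirna_ids[built$planted$mirna],
        transcript_id = coding_ids[i],
        site_type = built$planted$site_type,
        start = built$planted$start1 - 1L, stringsAsFactors = FALSE)
  }
  names(utrs) <- coding_ids
  planted_sites <- if (length(site_rows)) do.call(rbind, site_rows)
    else data.frame(mirna_id = character(0), transcript_id = character(0),
                    site_type = character(0), start = integer(0))
  rownames(planted_sites) <- NULL
  list(mirnas = sequence_set(panel$seqs, "mature_miRNA"),
       lncrna = sequence_set(stats::setNames(lnc$seq, lncrna_id), "lncRNA"),
       utrs = sequence_set(utrs, "utr3"),
       planted_sites = planted_sites)
}

# ---- full dataset ---------------------------------------------------------

#' Simulate a complete lncRNA-knockdown dataset with ground truth
#'
#' Runs the whole generative model: sequence generation with planted sites,
#' steady-state titration per arm (control and two knockdown reagents),
#' lncRNA-coupled induction, direct (miRNA-independent) responses, and
#' multiplicative log-normal measurement noise per feature and replicate.
#' Sponged and null miRNAs are measured as their free level (the bound pool
#' is assumed undetectable); induced miRNAs are measured as their
#' lncRNA-scaled total.
#'
#' @param config A `simulation_config`.
#' @return A list of class `sponge_simulation`: `mrna` and `mirna`
#'   (`ExpressionMatrix`), `design` (`SampleDesign`), `sequences` (list of
#'   `SequenceSet`s: `lncrna`, `mirnas`, `utrs`), `lncrna_id`, `truth`
#'   (planted ground truth: roles, site counts, expected per-arm levels,
#'   true fold changes, regulated/explained coding sets and the true
#'   explained fraction), and the `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_coding <- round(config$n_mrna * config$frac_coding)
  n_nc <- config$n_mrna - n_coding
  coding_ids <- sprintf("gene_%04d", seq_len(n_coding))
  lncrna_id <- "lnc_sponge"
  nc_biotypes <- rep(c("lncRNA", "snRNA", "snoRNA", "pseudogene",
                       "misc_RNA"), length.out = n_nc - 1L)
  nc_ids <- sprintf("nc_%s_%02d", sub("_", "", nc_biotypes),
                    stats::ave(seq_along(nc_biotypes), nc_biotypes,
                               FUN = seq_along))
  mirna_ids <- sprintf("mir_sim_%02d", seq_len(config$n_mirna))

  sponged <- sample(mirna_ids, config$n_sponged)
  induced <- sample(setdiff(mirna_ids, sponged), config$n_induced)
  nulls <- setdiff(mirna_ids, c(sponged, induced))

  pool <- sample(coding_ids, config$n_sponge_pool + config$n_induced_pool +
                   config$n_null_pool + config$n_direct_coding)
  sponge_pool <- pool[seq_len(config$n_sponge_pool)]
  induced_pool <- pool[config$n_sponge_pool + seq_len(config$n_induced_pool)]
  null_pool <- pool[config$n_sponge_pool + config$n_induced_pool +
                      seq_len(config$n_null_pool)]
  direct_coding <- pool[config$n_sponge_pool + config$n_induced_pool +
                          config$n_null_pool + seq_len(config$n_direct_coding)]
  direct_nc <- sample(nc_ids, config$n_direct_noncoding)

  draw_sites <- function() sample(config$utr_sites_min:config$utr_sites_max, 1L)
  # deal miRNAs to pool genes with load balancing so every perturbed miRNA
  # ends up with a comparable number of planted targets
  balanced_deal <- function(genes, mirnas, per_gene) {
    load <- stats::setNames(numeric(length(mirnas)), mirnas)
    out <- list()
    for (g in genes) {
      pick <- mirnas[order(load, stats::runif(length(mirnas)))][seq_len(per_gene)]
      load[pick] <- load[pick] + 1
      out[[g]] <- pick
    }
    out
  }
  rows <- list()
  sponge_deal <- balanced_deal(sponge_pool, sponged,
                               config$mirnas_per_sponge_gene)
  for (g in sponge_pool)
    for (m in sponge_deal[[g]])
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = m, transcript_id = g, n_sites = draw_sites())
  induced_deal <- balanced_deal(induced_pool, induced,
                                config$mirnas_per_induced_gene)
  for (g in induced_pool)
    for (m in induced_deal[[g]])
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = m, transcript_id = g, n_sites = draw_sites())
  for (m in nulls)
    for (g in sample(null_pool, config$null_targets_per_mirna))
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = m, transcript_id = g, n_sites = 1L)
  for (m in sponged)
    rows[[length(rows) + 1L]] <- data.frame(
      mirna_id = m, transcript_id = lncrna_id,
      n_sites = sample(config$lnc_sites_min:config$lnc_sites_max, 1L))
  assignment <- do.call(rbind, rows)

  seqs <- generate_sequences(config, assignment, mirna_ids, coding_ids,
                             lncrna_id)

  # site-count matrix driving the titration dynamics (planted map)
  N <- matrix(0, config$n_mirna, n_coding + 1L,
              dimnames = list(mirna_ids, c(coding_ids, lncrna_id)))
  for (r in seq_len(nrow(assignment)))
    N[assignment$mirna_id[r], assignment$transcript_id[r]] <-
      assignment$n_sites[r]

  L0 <- 2^stats::rnorm(1, config$lncrna_log2_mean, config$lncrna_log2_sd)
  M <- 2^stats::rnorm(config$n_mirna, config$mirna_log2_mean,
                      config$mirna_log2_sd)
  names(M) <- mirna_ids
  T0 <- 2^stats::rnorm(n_coding, config$mrna_log2_mean, config$mrna_log2_sd)
  names(T0) <- coding_ids
  nc_basal <- 2^stats::rnorm(length(nc_ids), config$mrna_log2_mean,
                             config$mrna_log2_sd)
  names(nc_basal) <- nc_ids
  direct_sign <- stats::setNames(
    sample(c(-1, 1), config$n_direct_coding + config$n_direct_noncoding,
           replace = TRUE),
    c(direct_coding, direct_nc))

  arms <- c(control = 0, kd1 = config$e_kd1, kd2 = config$e_kd2)
  mrna_feats <- c(coding_ids, lncrna_id, nc_ids)
  E_mrna <- matrix(NA_real_, length(mrna_feats), length(arms),
                   dimnames = list(mrna_feats, names(arms)))
  E_mirna <- matrix(NA_real_, config$n_mirna, length(arms),
                    dimnames = list(mirna_ids, names(arms)))
  for (a in names(arms)) {
    L <- L0 * (1 - arms[[a]])
    rel <- L / L0
    M_eff <- M
    M_eff[induced] <- M[induced] * rel^config$gamma
    ss <- steady_state(M_eff, T0, L, N, K = config$K, rho = config$rho)
    lev <- ss$T
    for (g in direct_coding) lev[g] <- T0[g] * rel^(direct_sign[g] *
                                                     config$direct_exponent)
    nc_lev <- nc_basal
    for (g in direct_nc) nc_lev[g] <- nc_basal[g] * rel^(direct_sign[g] *
                                                  config$direct_exponent)
    E_mrna[, a] <- c(lev, L, nc_lev)
    f <- ss$F
    f[induced] <- M_eff[induced]
    E_mirna[, a] <- f
  }

  reps <- config$replicates
  samp_ids <- as.vector(vapply(names(arms), function(a)
    paste0(a, "_", seq_len(reps)), character(reps)))
  design <- sample_design(samp_ids,
                          rep(names(arms), each = reps),
                          rep(seq_len(reps), times = length(arms)))
  noisy <- function(E) {
    v <- E[, rep(names(arms), each = reps), drop = FALSE] *
      2^matrix(stats::rnorm(nrow(E) * reps * length(arms), 0, config$sigma),
               nrow(E))
    colnames(v) <- samp_ids
    v
  }
  mrna_ann <- data.frame(
    feature_id = mrna_feats,
    biotype = c(rep("protein_coding", n_coding), "lncRNA", nc_biotypes),
    symbol = toupper(mrna_feats), stringsAsFactors = FALSE)
  mirna_ann <- data.frame(feature_id = mirna_ids, biotype = "miRNA",
                          symbol = mirna_ids, stringsAsFactors = FALSE)
  mrna <- expression_matrix(noisy(E_mrna), mrna_ann)
  mirna <- expression_matrix(noisy(E_mirna), mirna_ann)

  # true (noise-free) signed fold changes and the planted truth sets
  signed_fc <- function(E) {
    sapply(c("kd1", "kd2"), function(a)
      signed_fold_change(E[, a] / E[, "control"]))
  }
  fc_mrna <- signed_fc(E_mrna)
  fc_mirna <- signed_fc(E_mirna)
  coding_reg <- coding_ids[apply(abs(fc_mrna[coding_ids, , drop = FALSE]) >
                                   1.6, 1, any)]
  mirna_de <- mirna_ids[apply(abs(fc_mirna) >= 1.3, 1, any)]
  perturbed_de <- intersect(c(sponged, induced), mirna_de)
  target_of_perturbed <- unique(
    assignment$transcript_id[assignment$mirna_id %in% perturbed_de &
                               assignment$transcript_id != lncrna_id])
  explained <- intersect(coding_reg, target_of_perturbed)

  truth <- list(
    sponged = sponged, induced = induced, nulls = nulls,
    site_counts = N, planted_sites = seqs$planted_sites,
    assignment = assignment,
    expected_mrna = E_mrna, expected_mirna = E_mirna,
    true_signed_fc_mrna = fc_mrna, true_signed_fc_mirna = fc_mirna,
    L0 = L0, M = M, T0 = T0,
    sponge_pool = sponge_pool, induced_pool = induced_pool,
    null_pool = null_pool, direct_coding = direct_coding,
    direct_noncoding = direct_nc,
    regulated_coding = coding_reg,
    explained_coding = explained,
    explained_fraction = length(explained) / max(length(coding_reg), 1L))

  structure(list(mrna = mrna, mirna = mirna, design = design,
                 sequences = list(lncrna = seqs$lncrna,
                                  mirnas = seqs$mirnas, utrs = seqs$utrs),
                 lncrna_id = lncrna_id, truth = truth, config = config),
            class = "sponge_simulation")
}

#' @export
print.sponge_simulation <- function(x, ...) {
  cat(sprintf(paste0("sponge_simulation: %d mRNA-level features x %d ",
                     "samples; %d miRNAs (%d sponged, %d induced); ",
                     "true explained fraction %.2f\n"),
              nrow(x$mrna$values), ncol(x$mrna$values),
              nrow(x$mirna$values), length(x$truth$sponged),
              length(x$truth$induced), x$truth$explained_fraction))
  invisible(x)
}

.DATASET_MANIFEST <- c("mrna_expression.tsv", "mirna_expression.tsv",
                       "feature_annotations.tsv", "sample_design.tsv",
                       "sequences_mirna.fa", "sequences_transcripts.fa",
                       "ground_truth.json")

#' Write a simulated dataset to disk
#'
#' Emits the fixed seven-file manifest: two expression TSVs, a shared
#' feature annotation TSV, the sample design, a mature-miRNA FASTA, a
#' transcripts FASTA (the lncRNA record followed by the 3'UTRs), and the
#' ground-truth JSON. Re-reading with [read_dataset()] reproduces the
#' matrices bit-identically.
#'
#' @param sim A `sponge_simulation`.
#' @param dir Output directory.
#' @param force Overwrite a non-empty directory (default `FALSE`; an
#'   existing non-empty directory without `force` is an error).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir, force = FALSE) {
  stopifnot(inherits(sim, "sponge_simulation"))
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("output directory exists and is not empty; use force = TRUE",
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_expression(sim$mrna, fp("mrna_expression.tsv"))
  write_expression(sim$mirna, fp("mirna_expression.tsv"))
  write_annotations(rbind(sim$mrna$annotations, sim$mirna$annotations),
                    fp("feature_annotations.tsv"))
  write_sample_design(sim$design, fp("sample_design.tsv"))
  write_fasta(sim$sequences$mirnas, fp("sequences_mirna.fa"))
  write_fasta(c(stats::setNames(unclass(sim$sequences$lncrna),
                                names(sim$sequences$lncrna)),
                stats::setNames(unclass(sim$sequences$utrs),
                                names(sim$sequences$utrs))),
              fp("sequences_transcripts.fa"))
  tr <- sim$truth
  gt <- list(
    lncrna_id = sim$lncrna_id,
    sponged = tr$sponged, induced = tr$induced,
    site_counts = tr$assignment,
    planted_sites = tr$planted_sites,
    regulated_coding = tr$regulated_coding,
    explained_coding = tr$explained_coding,
    explained_fraction = tr$explained_fraction,
    direct_coding = tr$direct_coding,
    direct_noncoding = tr$direct_noncoding,
    seed = sim$config$seed)
  jsonlite::write_json(gt, fp("ground_truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the seven-file manifest.
#' @return A list with the same analysis-facing fields as a
#'   `sponge_simulation` (`mrna`, `mirna`, `design`, `sequences`,
#'   `lncrna_id`, `truth`); the truth carries the serialized ground-truth
#'   fields only.
#' @export
read_dataset <- function(dir) {
  fp <- function(f) file.path(dir, f)
  missing <- .DATASET_MANIFEST[!file.exists(fp(.DATASET_MANIFEST))]
  if (length(missing))
    stop("dataset directory is missing file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ann <- fp("feature_annotations.tsv")
  mrna <- read_expression(fp("mrna_expression.tsv"), ann)
  mirna <- read_expression(fp("mirna_expression.tsv"), ann)
  design <- read_sample_design(fp("sample_design.tsv"))
  truth <- jsonlite::read_json(fp("ground_truth.json"), simplifyVector = TRUE)
  transcripts <- read_fasta(fp("sequences_transcripts.fa"), "utr3")
  lnc_id <- truth$lncrna_id
  lncrna <- sequence_set(stats::setNames(unclass(transcripts[lnc_id]),
                                         lnc_id), "lncRNA")
  utrs <- transcripts[setdiff(names(transcripts), lnc_id)]
  list(mrna = mrna, mirna = mirna, design = design,
       sequences = list(lncrna = lncrna,
                        mirnas = read_fasta(fp("sequences_mirna.fa"),
                                            "mature_miRNA"),
                        utrs = utrs),
       lncrna_id = lnc_id, truth = truth)
}
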