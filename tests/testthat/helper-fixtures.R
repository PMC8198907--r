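# shared fixture builders; everything is generated in code at test time

rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# small random ExpressionMatrix with annotated biotypes
rand_expression <- function(n_feat = 10, n_samp = 4, biotype = "protein_coding") {
  v <- matrix(abs(rnorm(n_feat * n_samp, 100, 30)), n_feat,
              dimnames = list(sprintf("f%03d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  ann <- data.frame(feature_id = rownames(v),
                    biotype = rep_len(biotype, n_feat),
                    symbol = toupper(rownames(v)))
  expression_matrix(v, ann)
}

# 3-arm x n-replicate design matching column names ctrl_i / kd1_i / kd2_i
three_arm_design <- function(reps = 3) {
  arms <- c("control", "kd1", "kd2")
  sample_design(as.vector(sapply(arms, function(a) paste0(a, "_", 1:reps))),
                rep(arms, each = reps), rep(1:reps, 3))
}

# expression matrix whose per-arm means are set exactly; zero within-arm
# noise is avoided with a tiny jitter unless sigma = 0
matrix_with_means <- function(means_ctrl, means_kd1, means_kd2 = NULL,
                              reps = 3, sigma = 0.02,
                              biotype = "protein_coding") {
  n <- length(means_ctrl)
  arms <- list(control = means_ctrl, kd1 = means_kd1)
  if (!is.null(means_kd2)) arms$kd2 <- means_kd2
  cols <- list()
  for (a in names(arms))
    for (r in 1:reps)
      cols[[paste0(a, "_", r)]] <- arms[[a]] * 2^rnorm(n, 0, sigma)
  v <- do.call(cbind, cols)
  rownames(v) <- sprintf("f%03d", seq_len(n))
  ann <- data.frame(feature_id = rownames(v),
                    biotype = rep_len(biotype, n),
                    symbol = rownames(v))
  expression_matrix(v, ann)
}

design_for <- function(x) {
  ids <- sample_ids(x)
  arm <- sub("_[0-9]+$", "", ids)
  arm[arm == "ctrl"] <- "control"
  sample_design(ids, arm, as.integer(sub("^.*_", "", ids)))
}

# brute-force seed-site oracle: tests all four patterns at every offset by
# string equality, independently of the packaged scanner
oracle_sites <- function(target, mature) {
  target <- chartr("T", "U", toupper(target))
  seed7 <- substr(chartr("T", "U", toupper(mature)), 2, 8)
  rc <- function(s) spongenet::reverse_complement(s)
  pats <- list("8mer"    = paste0(rc(substr(seed7, 1, 7)), "A"),
               "7mer-m8" = rc(substr(seed7, 1, 7)),
               "7mer-A1" = paste0(rc(substr(seed7, 1, 6)), "A"),
               "6mer"    = rc(substr(seed7, 1, 6)))
  found <- list()
  claimed <- logical(nchar(target))   # positions consumed by a stronger type
  n <- nchar(target)
  for (ty in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
    p <- pats[[ty]]
    w <- nchar(p)
    if (n < w) next
    starts <- seq_len(n - w + 1)
    for (s in starts[substring(target, starts, starts + w - 1) == p]) {
      # locate this window's core so overlapping readings of the same core
      # merge into the longest type, as the scanner specifies
      core_at <- if (ty %in% c("8mer", "7mer-m8")) s + 1L else s
      if (claimed[core_at]) next
      claimed[core_at] <- TRUE
      found[[length(found) + 1L]] <- data.frame(
        site_type = ty, start = s - 1L, end = s - 1L + w)
    }
  }
  if (!length(found))
    return(data.frame(site_type = character(0), start = integer(0),
                      end = integer(0)))
  out <- do.call(rbind, found)
  out[order(out$start), , drop = FALSE]
}

# independent scalar fixed-point solver for the one-miRNA / one-mRNA /
# one-lncRNA titration system
oracle_steady_scalar <- function(M, T0, n_t, L, n_l, K, rho,
                                 iters = 100000, tol = 1e-14) {
  Tt <- T0
  for (i in seq_len(iters)) {
    Fm <- M / (1 + (n_t * Tt + n_l * L) / K)
    Tn <- T0 / (1 + rho * n_t * Fm / K)
    if (abs(Tn - Tt) < tol * T0) { Tt <- Tn; break }
    Tt <- Tn
  }
  list(T = Tt, F = M / (1 + (n_t * Tt + n_l * L) / K))
}

# textbook Welch statistic on the log2(x + pc) scale
oracle_welch_p <- function(ctrl, trt, pc = 1) {
  x <- log2(ctrl + pc); y <- log2(trt + pc)
  nx <- length(x); ny <- length(y)
  sx <- var(x) / nx; sy <- var(y) / ny
  t_stat <- (mean(y) - mean(x)) / sqrt(sx + sy)
  df <- (sx + sy)^2 / (sx^2 / (nx - 1) + sy^2 / (ny - 1))
  2 * pt(-abs(t_stat), df)
}

tiny_sim_config <- function(seed = 1, ...) {
  args <- list(n_mrna = 60, n_mirna = 12, n_sponged = 2, n_induced = 2,
               lncrna_length = 600, utr_length = 300,
               n_sponge_pool = 6, mirnas_per_sponge_gene = 2,
               n_induced_pool = 6, mirnas_per_induced_gene = 2,
               n_null_pool = 8, null_targets_per_mirna = 2,
               n_direct_coding = 4, n_direct_noncoding = 2,
               seed = seed)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}
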