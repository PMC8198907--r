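test_that("steady state: closed forms, dilute limit, and the scalar oracle", {
  # rho = 0 with no lncRNA sites: T = T0, F in closed form
  N <- matrix(c(1, 0, 2, 1, 0, 0), nrow = 2)   # 2 miRNAs x (2 mRNA + lnc)
  M <- c(100, 50)
  T0 <- c(40, 80)
  ss <- steady_state(M, T0, L = 0, N, K = 100, rho = 0)
  expect_equal(ss$T, T0)
  expect_equal(ss$F, M / (1 + as.vector(N %*% c(T0, 0)) / 100))

  # dilute limit: K enormous -> no binding, F -> M and T -> T0
  ss_d <- steady_state(M, T0, L = 500, N, K = 1e12, rho = 1)
  expect_equal(ss_d$F, M, tolerance = 1e-6)
  expect_equal(ss_d$T, T0, tolerance = 1e-6)

  # 1 miRNA (M=100), 1 mRNA (T0=50, n=1), lncRNA (L=200, n=2), K=100
  N1 <- matrix(c(1, 2), nrow = 1)
  got <- steady_state(100, 50, L = 200, N1, K = 100, rho = 1)
  want <- oracle_steady_scalar(100, 50, 1, 200, 2, 100, 1)
  expect_equal(got$T, want$T, tolerance = 1e-8)
  expect_equal(got$F, want$F, tolerance = 1e-8)
})

test_that("simulator physics hold across random configurations", {
  set.seed(73)
  for (rep in 1:60) {
    n_mi <- sample(2:5, 1)
    n_t <- sample(3:8, 1)
    M <- 2^runif(n_mi, 5, 11)
    T0 <- 2^runif(n_t, 4, 9)
    L0 <- 2^runif(1, 7, 11)
    N <- matrix(rpois(n_mi * (n_t + 1), 0.8), n_mi)
    sponged_idx <- which(N[, n_t + 1] > 0)

    prev_F <- NULL
    for (e in c(0, 0.3, 0.6, 0.9)) {
      ss <- steady_state(M, T0, L = L0 * (1 - e), N, K = 100, rho = 1)
      # conservation: 0 < F <= M
      expect_true(all(ss$F > 0))
      expect_true(all(ss$F <= M + 1e-12))
      # knockdown releases sponged miRNAs monotonically
      if (!is.null(prev_F) && length(sponged_idx))
        expect_true(all(ss$F[sponged_idx] >= prev_F[sponged_idx] - 1e-9))
      prev_F <- ss$F
    }

    # dilute limit reproduces basal levels
    ss_d <- steady_state(M, T0, L = L0, N, K = 1e12, rho = 1)
    expect_equal(ss_d$T, T0, tolerance = 1e-6)
    expect_equal(ss_d$F, M, tolerance = 1e-6)
  }
})

test_that("planted sites are recovered exactly by scanning", {
  sim <- simulate_dataset(tiny_sim_config(seed = 5))
  planted <- sim$truth$planted_sites
  mirnas <- sim$sequences$mirnas
  all_seqs <- c(as.character(sim$sequences$lncrna),
                as.character(sim$sequences$utrs))
  names(all_seqs) <- c(names(sim$sequences$lncrna),
                       names(sim$sequences$utrs))

  # every planted site is found at its recorded position with its type
  for (r in seq_len(nrow(planted))) {
    found <- find_seed_sites(all_seqs[[planted$transcript_id[r]]],
                             mirnas[[planted$mirna_id[r]]])
    hit <- found[found$start == planted$start[r], , drop = FALSE]
    expect_equal(nrow(hit), 1)
    expect_identical(hit$site_type, planted$site_type[r])
  }

  # and scanning finds nothing beyond the planted map (backgrounds are
  # scrubbed): per-miRNA, per-transcript tallies agree with ground truth
  for (m in names(mirnas)) {
    for (t in names(all_seqs)) {
      n_found <- nrow(oracle_sites(all_seqs[[t]], mirnas[[m]]))
      n_truth <- sum(planted$mirna_id == m & planted$transcript_id == t)
      expect_equal(n_found, n_truth)
    }
  }

  # sponged miRNAs have lncRNA sites scoring past the binding threshold;
  # all other miRNAs have none
  lnc <- as.character(sim$sequences$lncrna)[[1]]
  for (m in names(mirnas)) {
    sc <- score_lncrna_binding(lnc, mirnas[[m]])
    if (m %in% sim$truth$sponged) expect_gte(sc$score, 0.7)
    else expect_equal(sc$score, 0)
  }
})

test_that("no sponged miRNAs means no planted lncRNA sites", {
  cfg <- tiny_sim_config(seed = 9, n_sponged = 0,
                         n_sponge_pool = 0, mirnas_per_sponge_gene = 0)
  sim <- simulate_dataset(cfg)
  expect_equal(sum(sim$truth$planted_sites$transcript_id == sim$lncrna_id), 0)
})

test_that("noise-free construction identities hold", {
  # sigma = 0: measured knockdown lncRNA level / control = 1 - e exactly
  cfg <- tiny_sim_config(seed = 13, sigma = 0)
  sim <- simulate_dataset(cfg)
  v <- sim$mrna$values[sim$lncrna_id, ]
  des <- sim$design
  ctrl <- mean(v[des$sample_id[des$arm == "control"]])
  expect_equal(mean(v[des$sample_id[des$arm == "kd1"]]) / ctrl, 1 - 0.6,
               tolerance = 1e-12)
  expect_equal(mean(v[des$sample_id[des$arm == "kd2"]]) / ctrl, 1 - 0.5,
               tolerance = 1e-12)

  # replicates within an arm are identical without noise
  kd1 <- sim$mrna$values[, des$sample_id[des$arm == "kd1"]]
  expect_equal(kd1[, 1], kd1[, 2])

  # sponged free levels strictly rise in knockdown arms (before noise)
  E <- sim$truth$expected_mirna
  for (m in sim$truth$sponged) {
    expect_gt(E[m, "kd1"], E[m, "control"])
    expect_gt(E[m, "kd2"], E[m, "control"])
  }
  # null miRNAs are exactly arm-invariant (no-site neutrality)
  for (m in sim$truth$nulls)
    expect_equal(E[m, "kd1"], E[m, "control"], tolerance = 1e-9)
})

test_that("a null simulation produces no selections at any threshold > 1", {
  cfg <- tiny_sim_config(seed = 17, sigma = 0, e_kd1 = 0, e_kd2 = 0)
  sim <- simulate_dataset(cfg)
  res <- select_regulated(sim$mrna, sim$design, 1.0001, 0.999)
  expect_equal(sum(res$selected), 0)
})

test_that("datasets emit a fixed manifest and round-trip through disk", {
  sim <- simulate_dataset(tiny_sim_config(seed = 19))
  dir <- file.path(withr::local_tempdir(), "ds")
  write_dataset(sim, dir)
  expect_setequal(list.files(dir),
                  c("mrna_expression.tsv", "mirna_expression.tsv",
                    "feature_annotations.tsv", "sample_design.tsv",
                    "sequences_mirna.fa", "sequences_transcripts.fa",
                    "ground_truth.json"))
  expect_length(list.files(dir), 7)

  expect_error(write_dataset(sim, dir), "force")
  expect_silent(write_dataset(sim, dir, force = TRUE))

  back <- read_dataset(dir)
  expect_identical(back$mrna$values, sim$mrna$values)
  expect_identical(back$mirna$values, sim$mirna$values)
  expect_identical(as.character(back$sequences$utrs),
                   as.character(sim$sequences$utrs))
  expect_identical(back$truth$sponged, sim$truth$sponged)
  expect_equal(back$truth$explained_fraction,
               sim$truth$explained_fraction)

  # ground truth JSON is schema-valid for the fields the pipeline consumes
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_true(all(c("lncrna_id", "sponged", "induced", "site_counts",
                    "regulated_coding", "explained_fraction") %in% names(gt)))
})

test_that("the same seed reproduces byte-identical emitted files", {
  base <- withr::local_tempdir()
  d1 <- file.path(base, "a")
  d2 <- file.path(base, "b")
  write_dataset(simulate_dataset(tiny_sim_config(seed = 23)), d1)
  write_dataset(simulate_dataset(tiny_sim_config(seed = 23)), d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})
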