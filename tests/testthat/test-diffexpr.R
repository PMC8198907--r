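test_that("fold change and its signed convention behave symmetrically", {
  expect_equal(fold_change(c(1, 1), c(2, 2), 0), list(fc = 2, signed = 2))
  expect_equal(fold_change(c(2, 2), c(1, 1), 0), list(fc = 0.5, signed = -2))
  expect_equal(fold_change(c(3, 3), c(3, 3), 0), list(fc = 1, signed = 1))
  expect_error(fold_change(c(0, 0), c(1, 1), 0), "zero")
  # pseudocount shrinks the ratio toward 1
  expect_lt(fold_change(c(1, 1), c(2, 2), 1)$fc, 2)
})

test_that("group tests match textbook computations and define degeneracies", {
  expect_equal(group_test(c(5, 5, 5), c(5, 5, 5)), 1.0)
  expect_equal(group_test(c(1, 1, 1), c(8, 8, 8)), 0.0)
  ctrl <- c(1.0, 1.2, 0.9)
  trt <- c(2.1, 2.0, 2.3)
  expect_equal(group_test(ctrl, trt, method = "welch"),
               oracle_welch_p(ctrl, trt), tolerance = 1e-10)
  # random cases: Welch path against the independent Welch formula, and the
  # default pooled path against a textbook pooled computation
  set.seed(41)
  for (i in 1:20) {
    a <- abs(rnorm(sample(3:6, 1), 50, 20))
    b <- abs(rnorm(sample(3:6, 1), 70, 25))
    expect_equal(group_test(a, b, method = "welch"), oracle_welch_p(a, b),
                 tolerance = 1e-10)
    x <- log2(a + 1); y <- log2(b + 1)
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    t_stat <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / nx + 1 / ny))
    p_pool <- 2 * pt(-abs(t_stat), nx + ny - 2)
    expect_equal(group_test(a, b), p_pool, tolerance = 1e-10)
  }
})

test_that("the regulation gate applies the printed inequalities exactly", {
  # five features realizing the signed fold changes of the reference
  # fixture, FC (+2.0, +1.5, -1.7, -3.0, +1.8), with p below 0.05 for all
  # but feature 3. Features 1, 2, 4, 5 use exactly replicated means, so the
  # zero-variance/unequal-means convention pins their p at 0; feature 3 is
  # noisy enough that its p stays above the gate.
  set.seed(5)
  ctrl_means <- c(100, 100, 170, 300, 100)
  kd_means <- c(200, 150, 100, 100, 180)
  reps <- 3
  cols <- list()
  for (r in 1:reps) cols[[paste0("control_", r)]] <- ctrl_means
  for (r in 1:reps) {
    kd <- kd_means
    kd[3] <- kd[3] * 2^rnorm(1, 0, 0.6)
    cols[[paste0("kd1_", r)]] <- kd
  }
  v <- do.call(cbind, cols)
  rownames(v) <- paste0("f", 1:5)
  em <- expression_matrix(v, data.frame(feature_id = rownames(v),
                                        biotype = "protein_coding",
                                        symbol = rownames(v)))
  des <- design_for(em)

  res <- select_regulated(em, des, 1.6, 0.05, ge = FALSE, pseudocount = 0)
  expect_equal(res$signed_fc_kd1[c(1, 2, 4, 5)], c(2.0, 1.5, -3.0, 1.8))
  expect_equal(res$p_kd1[c(1, 2, 4, 5)], rep(0, 4))
  # realized feature 3 must sit on the intended side of the p gate
  expect_lt(res$signed_fc_kd1[3], -1)
  expect_gte(res$p_kd1[3], 0.05)
  expect_identical(which(res$selected), c(1L, 4L, 5L))

  # miRNA gate: inclusive fold-change comparison admits feature 2 (+1.5)
  res2 <- select_regulated(em, des, 1.3, 0.05, ge = TRUE, pseudocount = 0)
  expect_identical(which(res2$selected), c(1L, 2L, 4L, 5L))
})

test_that("a fold change exactly at the strict threshold is not selected", {
  set.seed(8)
  # zero within-arm variance would give p = 0 by convention, so use exact
  # means with noise-free replicates: FC exactly 1.6, p = 0 -> the FC gate
  # alone must reject under strict inequality
  v <- cbind(control_1 = c(100), control_2 = c(100), control_3 = c(100),
             kd1_1 = c(160), kd1_2 = c(160), kd1_3 = c(160))
  rownames(v) <- "f1"
  em <- expression_matrix(v, data.frame(feature_id = "f1",
                                        biotype = "protein_coding",
                                        symbol = "f1"))
  res <- select_regulated(em, design_for(em), 1.6, 0.05, ge = FALSE,
                          pseudocount = 0)
  expect_equal(res$signed_fc_kd1, 1.6)
  expect_false(res$selected)
  # inclusive comparison selects it
  res_ge <- select_regulated(em, design_for(em), 1.6, 0.05, ge = TRUE,
                             pseudocount = 0)
  expect_true(res_ge$selected)
})

test_that("selection equals a brute-force per-feature gate and is monotone", {
  set.seed(12)
  em <- rand_expression(n_feat = 80, n_samp = 9)
  colnames(em$values) <- as.vector(sapply(c("control", "kd1", "kd2"),
                                          paste0, "_", 1:3))
  # plant some real effects
  em$values[1:20, 4:9] <- em$values[1:20, 4:9] * rep(runif(20, 1.5, 4), 6)
  des <- design_for(em)
  res <- select_regulated(em, des, 1.6, 0.05)

  brute <- vapply(seq_len(nrow(em$values)), function(i) {
    ctrl <- em$values[i, 1:3]
    any(vapply(list(4:6, 7:9), function(cols) {
      trt <- em$values[i, cols]
      fc <- fold_change(ctrl, trt, 1)
      abs(fc$signed) > 1.6 && group_test(ctrl, trt, 1) < 0.05
    }, logical(1)))
  }, logical(1))
  expect_identical(res$selected, brute)

  # monotonicity: tightening either threshold never adds a selection
  for (fc_thr in c(1.8, 2.5)) {
    tighter <- select_regulated(em, des, fc_thr, 0.05)
    expect_true(all(which(tighter$selected) %in% which(res$selected)))
  }
  for (p_thr in c(0.01, 0.001)) {
    tighter <- select_regulated(em, des, 1.6, p_thr)
    expect_true(all(which(tighter$selected) %in% which(res$selected)))
  }
})

test_that("arms with fewer than 2 replicates are rejected", {
  em <- rand_expression(n_feat = 4, n_samp = 4)
  colnames(em$values) <- c("control_1", "control_2", "kd1_1", "kd1_2")
  des <- sample_design(sample_ids(em), c("control", "control", "kd1", "kd1"),
                       c(1, 2, 1, 2))
  expect_silent(select_regulated(em, des))
  des_bad <- sample_design(sample_ids(em)[1:3],
                           c("control", "control", "kd1"), c(1, 2, 1))
  expect_error(select_regulated(em, des_bad), "2 replicates")
})

test_that("biotype partition tallies and rolls up correctly", {
  ann <- data.frame(feature_id = paste0("f", 1:4),
                    biotype = c("protein_coding", "protein_coding",
                                "lncRNA", "snoRNA"),
                    symbol = paste0("F", 1:4))
  p <- partition_biotypes(paste0("f", 1:4), ann)
  expect_equal(p$coding_fraction, 0.5)
  expect_equal(p$total, 4L)
  expect_equal(sum(p$fractions), 1, tolerance = 1e-12)

  empty <- partition_biotypes(character(0), ann)
  expect_equal(empty$total, 0L)

  ann_bad <- ann
  ann_bad$biotype[3] <- "intergenic"
  expect_error(partition_biotypes(paste0("f", 1:4), ann_bad), "intergenic")

  # randomized fixture against an independent tally loop
  set.seed(31)
  ann2 <- data.frame(feature_id = sprintf("g%03d", 1:200),
                     biotype = sample(BIOTYPES, 200, replace = TRUE),
                     symbol = sprintf("G%03d", 1:200))
  sel <- sample(ann2$feature_id, 120)
  p2 <- partition_biotypes(sel, ann2)
  manual <- integer(0)
  for (id in sel) {
    b <- ann2$biotype[ann2$feature_id == id]
    manual[b] <- if (is.na(manual[b])) 1L else manual[b] + 1L
  }
  expect_equal(p2$counts[sort(names(p2$counts))],
               manual[sort(names(manual))])
})

test_that("null data yield a calibrated type-I error rate", {
  set.seed(2026)
  n <- 2000
  base <- 2^rnorm(n, 7.5, 0.5)
  v <- base * 2^matrix(rnorm(n * 6, 0, 0.15), n)
  colnames(v) <- c(paste0("control_", 1:3), paste0("kd1_", 1:3))
  rownames(v) <- sprintf("f%04d", 1:n)
  em <- expression_matrix(v, data.frame(feature_id = rownames(v),
                                        biotype = "protein_coding",
                                        symbol = rownames(v)))
  res <- select_regulated(em, design_for(em), 1.6, 0.05)
  frac <- mean(res$p_kd1 < 0.05)
  ci <- qbinom(c(0.005, 0.995), n, 0.05) / n
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
  expect_equal(sum(res$selected), 0L)
})
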