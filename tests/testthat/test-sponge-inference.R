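cand_frame <- function(counts) {
  data.frame(mirna_id = sprintf("m%02d", seq_along(counts)),
             common_target_count = counts, stringsAsFactors = FALSE)
}

test_that("percentile filter uses the nearest-rank convention", {
  out <- percentile_filter(cand_frame(1:8), 75)
  expect_equal(attr(out, "min_count"), 6)    # ceil(0.75 * 8) = 6th smallest
  expect_equal(nrow(out), 3)
  expect_identical(out$common_target_count, 6:8)

  tied <- percentile_filter(cand_frame(rep(4, 5)), 75)
  expect_equal(nrow(tied), 5)                # fully tied -> all kept

  single <- percentile_filter(cand_frame(7), 75)
  expect_equal(nrow(single), 1)

  none <- percentile_filter(cand_frame(integer(0)), 75)
  expect_equal(nrow(none), 0)

  # zero-count candidates are excluded from the percentile population
  mixed <- percentile_filter(cand_frame(c(0, 0, 2, 3, 4, 5)), 75)
  expect_equal(attr(mixed, "min_count"), 4)  # percentile over (2,3,4,5)
  expect_equal(mixed$common_target_count, c(4, 5))
})

test_that("abundance ratio and the inclusive stoichiometry band", {
  r <- abundance_ratio(50, 200)
  expect_equal(r$ratio, 0.25)
  expect_true(r$in_band)                     # inclusive lower edge
  r <- abundance_ratio(c(100, 100), c(100, 100))
  expect_equal(r$ratio, 1)
  expect_true(r$in_band)                     # inclusive upper edge
  r <- abundance_ratio(300, 100)
  expect_equal(r$ratio, 3)
  expect_false(r$in_band)
  expect_error(abundance_ratio(10, 0), "zero")
})

test_that("classification implements the sponged/induced dichotomy", {
  expect_identical(classify_mirna("up", 0.8), "sponged")
  expect_identical(classify_mirna("up", 0.7), "sponged")     # inclusive
  expect_identical(classify_mirna("up", 0.1), "unclassified")
  expect_identical(classify_mirna("down", 0.1), "induced")
  expect_identical(classify_mirna("down", 0.9), "induced")
  expect_identical(classify_mirna("mixed", 0.9), "unclassified")
})

test_that("network assembly counts edges and deduplicates gene nodes", {
  cand <- data.frame(
    mirna_id = c("mA", "mB"),
    classification = c("sponged", "induced"),
    signed_fc_kd1 = c(1.9, -2.0), signed_fc_kd2 = c(1.7, -1.8),
    binding_score = c(0.8, 0.0), common_target_count = c(3, 3),
    stringsAsFactors = FALSE)
  tmap <- list(mA = c("g1", "g2", "g3"), mB = c("g4", "g5", "g6"))
  reg <- paste0("g", 1:6)

  net <- build_network("lnc1", cand, reg, tmap)
  expect_equal(nrow(net$edges), 8)   # 2 lncRNA edges + 6 target edges
  expect_identical(sort(unique(net$edges$interaction)),
                   c("binds", "induces", "targets"))

  # shared target appears once with degree 2
  tmap2 <- list(mA = c("g1", "g2", "g3"), mB = c("g1", "g5", "g6"))
  net2 <- build_network("lnc1", cand, reg, tmap2)
  expect_equal(sum(net2$nodes$id == "g1"), 1)
  expect_equal(sum(net2$edges$to == "g1"), 2)

  # no candidates -> lncRNA-only network
  none <- build_network("lnc1", cand[0, ], reg, tmap)
  expect_equal(nrow(none$nodes), 1)
  expect_equal(nrow(none$edges), 0)

  # candidate missing from the target map is an error
  expect_error(build_network("lnc1", cand, reg, tmap["mA"]), "mB")
})

test_that("explained fraction counts connected regulated genes", {
  cand <- data.frame(mirna_id = "mA", classification = "sponged",
                     signed_fc_kd1 = 2, signed_fc_kd2 = 2,
                     binding_score = 0.8, common_target_count = 6,
                     stringsAsFactors = FALSE)
  reg <- paste0("g", 1:10)
  net <- build_network("lnc1", cand, reg, list(mA = paste0("g", 1:6)))
  ef <- explained_fraction(net, reg)
  expect_equal(ef$fraction, 0.6)
  expect_equal(ef$n_explained, 6)
  expect_equal(ef$fraction + ef$independent_fraction, 1, tolerance = 1e-12)

  all_net <- build_network("lnc1", cand, reg, list(mA = reg))
  expect_equal(explained_fraction(all_net, reg)$fraction, 1)

  empty_net <- build_network("lnc1", cand[0, ], reg, list(mA = reg))
  expect_equal(explained_fraction(empty_net, reg)$fraction, 0)

  expect_error(explained_fraction(net, character(0)), "empty")
})

test_that("explained fraction is monotone in added candidates", {
  set.seed(53)
  reg <- sprintf("g%02d", 1:30)
  tmap <- lapply(1:5, function(i) sample(reg, sample(3:12, 1)))
  names(tmap) <- paste0("m", 1:5)
  fracs <- numeric(5)
  for (k in 1:5) {
    cand <- data.frame(mirna_id = paste0("m", 1:k),
                       classification = "sponged",
                       signed_fc_kd1 = 2, signed_fc_kd2 = 2,
                       binding_score = 0.9,
                       common_target_count = lengths(tmap)[1:k],
                       stringsAsFactors = FALSE)
    net <- build_network("lnc1", cand, reg, tmap)
    fracs[k] <- explained_fraction(net, reg)$fraction
  }
  expect_true(all(diff(fracs) >= 0))
})

test_that("raising the binding threshold never increases the sponged count", {
  set.seed(59)
  scores <- runif(20)
  dirs <- sample(c("up", "down"), 20, replace = TRUE)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(thr)
    sum(mapply(classify_mirna, dirs, scores,
               MoreArgs = list(binding_threshold = thr)) == "sponged"),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("venn region counts enumerate intersections exhaustively", {
  reg <- letters[1:26]
  two <- venn_counts(list(A = letters[1:3], B = letters[4:7]), reg)
  expect_equal(two$count[two$region == "A"], 3)
  expect_equal(two$count[two$region == "B"], 4)
  expect_equal(two$count[two$region == "A&B"], 0)

  same <- venn_counts(list(A = letters[1:5], B = letters[1:5]), reg)
  expect_equal(same$count[same$region == "A&B"], 5)
  expect_equal(sum(same$count), 5)

  set.seed(61)
  sets <- lapply(1:3, function(i) sample(letters, sample(5:15, 1)))
  names(sets) <- c("A", "B", "C")
  vc <- venn_counts(sets, letters)
  # brute-force membership-vector tally
  manual <- table(vapply(letters, function(g) {
    paste(vapply(sets, function(s) g %in% s, logical(1)), collapse = "")
  }, character(1)))
  for (r in seq_len(nrow(vc))) {
    key <- paste(unlist(vc[r, c("A", "B", "C")]), collapse = "")
    want <- if (key %in% names(manual)) as.integer(manual[[key]]) else 0L
    expect_equal(vc$count[r], want)
  }
  expect_equal(sum(vc$count), length(Reduce(union, sets)))

  expect_error(venn_counts(rep(list(letters[1:2]), 7), letters), "6")
})
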