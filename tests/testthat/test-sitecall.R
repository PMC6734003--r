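test_that("motif scanning finds RRACH centers and flags multi-A 5-mers", {
  one <- scan_motif(c(x = "GGACT"))
  expect_equal(one$pos, 3)
  expect_false(one$multi_A)
  # AGACT matches RRACH (R = A) but holds two A's
  two <- scan_motif(c(x = "AGACT"))
  expect_equal(nrow(two), 1)
  expect_true(two$multi_A)
  expect_error(scan_motif("ACGT", motif = "RRAC"), "5-mer")
  # random sequence vs an exhaustive regular-expression oracle
  set.seed(21)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
             collapse = "")
  got <- scan_motif(c(chr = s))
  rx <- "(?=[AG][AG]AC[ACT])"
  starts <- as.integer(gregexpr(rx, s, perl = TRUE)[[1]])
  expect_equal(got$pos, starts + 2L)
  kmers <- substring(s, starts, starts + 4)
  expect_equal(got$kmer, kmers)
  expect_equal(got$multi_A,
               vapply(strsplit(kmers, ""), function(v) sum(v == "A") > 1,
                      logical(1)))
})

test_that("coverage filter requires the minimum in every sample", {
  mk <- function(covs) data.frame(ref = rep("r", length(covs)),
                                  pos = seq_along(covs), cov = covs)
  tabs <- list(mk(c(10, 4, 10)), mk(c(10, 10, 10)), mk(c(5, 10, 0)))
  kept <- coverage_filter(tabs, min_coverage = 5)
  expect_equal(kept$pos, 1L)  # pos 2 fails sample 1, pos 3 fails sample 3
  expect_equal(coverage_filter(tabs, min_coverage = 1)$pos, c(1L, 2L))
  empty <- coverage_filter(list(mk(integer(0))), 5)
  expect_equal(nrow(empty), 0)
})

test_that("replicate score merging follows the all-or-mean rule", {
  expect_equal(merge_replicate_scores(0.6, 0.7, 0.9), 1.0)
  expect_equal(merge_replicate_scores(0.9, 0.9, 0.3), 0.7)
  expect_equal(merge_replicate_scores(0.5, 0.5, 0.5), 1.0)  # boundary: >=
  expect_error(merge_replicate_scores(0.5, 0.5), "replicates")
  expect_error(merge_replicate_scores(0.5, 0.5, 1.2), "0, 1")
  # permutation invariance and monotonicity
  set.seed(31)
  for (i in 1:50) {
    s <- runif(3)
    perm <- sample(3)
    expect_equal(merge_replicate_scores(s[1], s[2], s[3]),
                 merge_replicate_scores(s[perm[1]], s[perm[2]], s[perm[3]]))
    bump <- pmin(s + c(runif(1, 0, 1 - s[1]), 0, 0), 1)
    expect_gte(merge_replicate_scores(bump[1], bump[2], bump[3]),
               merge_replicate_scores(s[1], s[2], s[3]))
  }
  # vectorized over sites, matrix interface
  m <- rbind(c(0.6, 0.7, 0.9), c(0.9, 0.9, 0.3))
  expect_equal(merge_replicate_scores(m), c(1.0, 0.7))
})

test_that("differential calling applies strict ratio and score thresholds", {
  expect_equal(call_modification(0.9, 0.5)$status, "modified")    # ratio 1.8
  expect_equal(call_modification(0.6, 0.5)$status, "unmodified")  # ratio 1.2
  expect_equal(call_modification(0.9, 0.0)$ratio, Inf)
  expect_equal(call_modification(0.9, 0.0)$status, "modified")
  # strictness at the boundaries
  expect_equal(call_modification(0.75, 0.5)$status, "unmodified")  # ratio = 1.5
  expect_equal(call_modification(0.5, 0.1)$status, "unmodified")   # M_wt = 0.5
  # monotone in M_wt at fixed M_ko
  for (mko in c(0.1, 0.4)) {
    st <- call_modification(seq(0, 1, 0.05), rep(mko, 21))$status
    expect_true(all(diff(st == "modified") >= 0))
  }
})

test_that("performance against known sites counts recovery correctly", {
  # constructed table: 117 of 363 known sites recovered
  n_sites <- 1000
  calls <- data.frame(ref = "r", pos = seq_len(n_sites),
                      status = "unmodified", stringsAsFactors = FALSE)
  known <- data.frame(ref = "r", pos = 1:363)
  calls$status[1:117] <- "modified"     # recovered known sites
  calls$status[400:449] <- "modified"   # false positives
  perf <- performance_vs_known(calls, known)
  expect_equal(perf$TP, 117)
  expect_equal(perf$FN, 246)
  expect_equal(round(100 * perf$recovery, 1), 32.2)
  expect_equal(perf$FP, 50)
  expect_equal(perf$specificity, (637 - 50) / 637)
  # all-correct toy
  toy <- data.frame(ref = "r", pos = 1:10,
                    status = rep(c("modified", "unmodified"), 5))
  perf2 <- performance_vs_known(toy, toy[toy$status == "modified", 1:2])
  expect_equal(perf2$accuracy, 1.0)
  # random tables vs brute-force set intersection
  set.seed(41)
  for (i in 1:20) {
    cl <- data.frame(ref = "r", pos = 1:50,
                     status = sample(c("modified", "unmodified"), 50, TRUE))
    kn <- data.frame(ref = "r", pos = sample(1:50, 12))
    p <- performance_vs_known(cl, kn)
    inmod <- cl$pos[cl$status == "modified"]
    expect_equal(p$TP, length(intersect(kn$pos, inmod)))
    expect_equal(p$FP, length(setdiff(inmod, kn$pos)))
    expect_equal(p$TP + p$FN, 12)
    expect_equal(p$TP + p$TN + p$FP + p$FN, 50)
  }
  expect_error(performance_vs_known(toy, data.frame(ref = "r", pos = 99L)),
               "subset")
  # empty known list: recovery undefined
  expect_true(is.na(performance_vs_known(toy, toy[0, 1:2])$recovery))
})

test_that("stoichiometry interpolation is exact at its anchors", {
  expect_equal(estimate_stoichiometry(0.05, 0.05, 0.15), 0)
  expect_equal(estimate_stoichiometry(0.15, 0.05, 0.15), 1)
  expect_equal(estimate_stoichiometry(0.10, 0.05, 0.15), 0.5)
  expect_equal(estimate_stoichiometry(0.30, 0.05, 0.15), 1)  # clipped
  expect_equal(estimate_stoichiometry(0.01, 0.05, 0.15), 0)  # clipped
  expect_error(estimate_stoichiometry(0.1, 0.2, 0.2), "degenerate")
})
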