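test_that("simulated error frequencies converge to the model probabilities", {
  ref <- substr(fx_ref[[1]], 1, 60)
  mod <- error_model(neighbor_bleed = c(0, 0))
  sim <- simulate_reads(ref, 10000, integer(0), 0, mod, seed = 4,
                        events = FALSE)
  ps <- per_site_features(sim$per_base)
  # per-site rates sit within 3 binomial SDs of nominal (rare chance
  # exceedances allowed at their nominal frequency), and the across-site
  # mean is within 3 SDs of the pooled estimate
  check <- function(obs, p) {
    tol <- 3 * sqrt(p * (1 - p) / 10000)
    expect_lte(sum(abs(obs - p) > tol), 2)
    expect_lt(abs(mean(obs) - p), 3 * sqrt(p * (1 - p) / (10000 * length(obs))))
  }
  check(ps$mis, mod$p_mismatch)
  check(ps$del, mod$p_deletion)
  check(ps$ins, mod$p_insertion)
})

test_that("modified positions show the shifted error model, others do not", {
  ref <- fx_ref[[1]]
  mod <- error_model(neighbor_bleed = c(0, 0))
  mp <- fx_a_pos[seq(1, length(fx_a_pos), by = 4)]
  sim <- simulate_reads(ref, 2000, mp, 1, mod, seed = 5, events = FALSE)
  ps <- per_site_features(sim$per_base)
  at <- ps$pos %in% mp
  p_mod <- mod$p_mismatch + mod$mismatch_delta
  tol <- 3 * sqrt(p_mod * (1 - p_mod) / 2000)
  expect_lte(mean(abs(ps$mis[at] - p_mod) > tol), 0.01)
  expect_lt(abs(mean(ps$mis[at]) - p_mod), 0.005)
  tol0 <- 3 * sqrt(mod$p_mismatch * (1 - mod$p_mismatch) / 2000)
  expect_lte(mean(abs(ps$mis[!at] - mod$p_mismatch) > tol0), 0.01)
  expect_lt(abs(mean(ps$mis[!at]) - mod$p_mismatch), 0.005)
  # quality drops by quality_shift at modified sites
  expect_lt(mean(ps$q_mean[at]), mean(ps$q_mean[!at]) - 2)
})

test_that("reads conserve one row per reference position and are reproducible", {
  ref <- substr(fx_ref[[1]], 1, 100)
  sim <- simulate_reads(ref, 50, fx_a_pos[fx_a_pos <= 100], 0.5, seed = 9)
  per_read <- table(sim$per_base$read_id)
  expect_true(all(per_read == nchar(ref)))
  expect_true(all(table(paste(sim$per_base$read_id, sim$per_base$pos)) == 1))
  sim2 <- simulate_reads(ref, 50, fx_a_pos[fx_a_pos <= 100], 0.5, seed = 9)
  expect_identical(sim$per_base, sim2$per_base)
  expect_identical(sim$events, sim2$events)
  expect_length(sim$modified_reads, 25)  # round(coverage * fraction), exact
  # degenerate inputs
  e <- simulate_reads(ref, 0, integer(0), 0, seed = 1)
  expect_equal(nrow(e$per_base), 0)
  expect_error(simulate_reads("ACGT", 5, modified_positions = 2, 1, seed = 1),
               "adenine")
})

test_that("mixtures draw exactly the requested number of modified reads", {
  ref <- substr(fx_ref[[1]], 1, 80)
  m <- simulate_reads(ref, 600, fx_a_pos[fx_a_pos <= 80], 1, seed = 2,
                      read_prefix = "m", events = FALSE)
  u <- simulate_reads(ref, 900, integer(0), 0, seed = 3, read_prefix = "u",
                      events = FALSE)
  mix <- mix_read_sets(m$per_base, u$per_base, 0.25, 1000, seed = 4)
  ids <- unique(mix$read_id)
  expect_length(ids, 1000)
  expect_equal(sum(startsWith(ids, "m")), 250)
  expect_identical(sort(attr(mix, "read_ids")$modified),
                   sort(ids[startsWith(ids, "m")]))
  # boundary fractions
  all_u <- mix_read_sets(m$per_base, u$per_base, 0, 500, seed = 1)
  expect_true(all(startsWith(unique(all_u$read_id), "u")))
  all_m <- mix_read_sets(m$per_base, u$per_base, 1, 500, seed = 1)
  expect_true(all(startsWith(unique(all_m$read_id), "m")))
  expect_error(mix_read_sets(m$per_base, u$per_base, 1, 2000, seed = 1),
               "available")
})

test_that("replicates reproduce condition-level signal but stay independent", {
  ref <- fx_ref[[1]]
  mp <- fx_a_pos[seq(1, length(fx_a_pos), by = 3)]
  sims <- simulate_replicates(ref, c(wt = 1, ko = 0), mp, n_replicates = 3,
                              coverage = 500, seed = 11, events = FALSE)
  expect_length(sims, 6)
  feats <- lapply(sims, function(s) per_site_features(s$per_base))
  mis_at <- function(f) f$mis[match(mp, f$pos)]
  # ko mismatch at modified positions indistinguishable from the same
  # positions of another unmodified replicate (two-sample proportion test);
  # wt clearly distinguishable from ko at those positions
  x1 <- round(sum(mis_at(feats$ko.rep1)) * 500)
  x2 <- round(sum(mis_at(feats$ko.rep2)) * 500)
  n <- 500 * length(mp)
  expect_gt(stats::prop.test(c(x1, x2), c(n, n))$p.value, 0.01)
  xw <- round(sum(mis_at(feats$wt.rep1)) * 500)
  expect_lt(stats::prop.test(c(xw, x1), c(n, n))$p.value, 1e-6)
  # wt-wt Spearman correlation of per-site mismatch exceeds wt-ko
  # correlation (the modification signal reproduces across replicates of
  # the same condition but not across conditions)
  r_ww <- stats::cor(feats$wt.rep1$mis, feats$wt.rep2$mis,
                     method = "spearman")
  r_wk <- stats::cor(feats$wt.rep1$mis, feats$ko.rep1$mis,
                     method = "spearman")
  expect_gt(r_ww, r_wk)
  # insertions carry no condition signal when insertion_delta = 0
  ins_wt <- mean(feats$wt.rep1$ins[match(mp, feats$wt.rep1$pos)])
  ins_ko <- mean(feats$ko.rep1$ins[match(mp, feats$ko.rep1$pos)])
  expect_lt(abs(ins_wt - ins_ko), 0.01)
})
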