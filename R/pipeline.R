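#' Centers of single-A, A-centered 5-mer windows
#'
#' Positions whose base is A and whose surrounding 5-mer contains no other A.
#' These are the windows a fully methylated construct can label cleanly
#' (multi-A 5-mers carry several modifications at once and are excluded from
#' training and scoring).
#'
#' @param reference Single sequence or named character vector.
#' @return Data frame: ref, pos, kmer.
#' @export
single_a_centers <- function(reference) {
  if (is.null(names(reference)))
    names(reference) <- if (length(reference) == 1) "ref"
                        else sprintf("ref%d", seq_along(reference))
  reference <- normalize_seq(reference)
  out <- lapply(names(reference), function(rn) {
    v <- strsplit(reference[[rn]], "", fixed = TRUE)[[1]]
    L <- length(v)
    if (L < 5) return(NULL)
    centers <- which(v == "A")
    centers <- centers[centers >= 3 & centers <= L - 2]
    if (!length(centers))
      return(NULL)
    km <- vapply(centers, function(p) paste(v[(p - 2):(p + 2)],
                                            collapse = ""), character(1))
    one_a <- vapply(strsplit(km, "", fixed = TRUE),
                    function(z) sum(z == "A") == 1L, logical(1))
    if (!any(one_a)) return(NULL)
    data.frame(ref = rn, pos = centers[one_a], kmer = km[one_a],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate in-vitro-style training windows
#'
#' Emulates the fully modified / unmodified construct pair used to train the
#' classifier: one run with every A methylated, one without, over the same
#' reference. Window features at single-A A-centered positions are labeled
#' by run of origin.
#'
#' @param reference Named character vector of length 1.
#' @param coverage Reads per run.
#' @param model An [error_model()].
#' @param seed Integer RNG seed.
#' @param centers Optional data frame (ref, pos) restricting the labeled
#'   windows (default: all single-A A-centers).
#' @return List with `windows` (labeled feature table), `modified` and
#'   `unmodified` (the two [simulate_reads()] results), and `centers`.
#' @export
simulate_training_windows <- function(reference, coverage = 100L,
                                      model = error_model(), seed = 1L,
                                      centers = NULL) {
  stopifnot(length(reference) == 1)
  if (is.null(names(reference))) names(reference) <- "ref"
  rn <- names(reference)
  a_pos <- which(strsplit(normalize_seq(reference[[1]]), "",
                          fixed = TRUE)[[1]] == "A")
  if (is.null(centers)) centers <- single_a_centers(reference)
  sim_mod <- simulate_reads(reference[[1]], coverage, a_pos, mod_fraction = 1,
                            model = model, seed = seed, ref_name = rn,
                            read_prefix = "mod")
  sim_unm <- simulate_reads(reference[[1]], coverage, integer(0),
                            mod_fraction = 0, model = model, seed = seed + 1L,
                            ref_name = rn, read_prefix = "unm")
  wf <- lapply(list(modified = sim_mod, unmodified = sim_unm), function(s) {
    sites <- per_site_features(s$per_base, reference)
    window_features(sites, current_window_stats(s$events))
  })
  for (lv in names(wf)) {
    wf[[lv]] <- wf[[lv]][wf[[lv]]$center %in% centers$pos, , drop = FALSE]
    wf[[lv]]$label <- lv
  }
  windows <- rbind(wf$modified, wf$unmodified)
  rownames(windows) <- NULL
  list(windows = windows, modified = sim_mod, unmodified = sim_unm,
       centers = centers)
}

#' Simulated wild-type versus knockout calling study
#'
#' A self-contained validation of the differential caller: candidate RRACH
#' sites are scanned on the reference, a subset is designated truly modified,
#' replicated wild-type (partial methylation) and knockout (0%) datasets are
#' simulated, windows are scored by an SVM, per-replicate probabilities are
#' merged and sites are called. The classifier is trained on a dedicated
#' training replicate pair simulated at the same study conditions (train on
#' one replicate, validate on the others), so the decision boundary reflects
#' the stoichiometry actually present in the test data.
#'
#' @param reference Named character vector of length 1.
#' @param wt_fraction Wild-type methylated-read fraction (default 0.5).
#' @param n_replicates Replicates per strain (default 3).
#' @param coverage Reads per replicate (default 100).
#' @param model An [error_model()].
#' @param prop_modified Fraction of candidate sites designated modified
#'   (default 0.5).
#' @param min_coverage Coverage filter threshold across all samples
#'   (default 5).
#' @param feature_set Classifier feature set (default `"combined3"`).
#' @param seed Integer RNG seed.
#' @return List: `calls` (site table with truth + status), `performance`
#'   (vs the designated modified sites), `recovery`, `fpr`, `model`,
#'   `modified_sites`.
#' @export
wtko_study <- function(reference, wt_fraction = 0.5, n_replicates = 3L,
                       coverage = 100L, model = error_model(),
                       prop_modified = 0.5, min_coverage = 5L,
                       feature_set = "combined3", seed = 1L) {
  stopifnot(length(reference) == 1)
  if (is.null(names(reference))) names(reference) <- "ref"
  rn <- names(reference)
  cand <- scan_motif(reference)
  cand <- cand[!cand$multi_A, , drop = FALSE]
  if (nrow(cand) < 4)
    stop("reference contains too few single-A RRACH sites for a study")
  set.seed(seed)
  n_mod <- max(1L, round(nrow(cand) * prop_modified))
  mod_sites <- sort(sample(cand$pos, n_mod))

  # training replicate pair at study conditions
  train_wt <- simulate_reads(reference[[1]], coverage, mod_sites,
                             mod_fraction = wt_fraction, model = model,
                             seed = .sub_seed(seed, 99L, 1L), ref_name = rn,
                             read_prefix = "trainwt")
  sites_tr <- per_site_features(train_wt$per_base, reference)
  wf_tr <- window_features(sites_tr, current_window_stats(train_wt$events))
  wf_tr <- wf_tr[wf_tr$center %in% cand$pos, , drop = FALSE]
  wf_tr$label <- ifelse(wf_tr$center %in% mod_sites, "modified",
                        "unmodified")
  fit <- train_svm(wf_tr, feature_set = feature_set, seed = seed)

  sims <- simulate_replicates(reference[[1]],
                              design = c(wt = wt_fraction, ko = 0),
                              modified_positions = mod_sites,
                              n_replicates = n_replicates,
                              coverage = coverage, model = model, seed = seed)
  site_tables <- lapply(sims, function(s)
    per_site_features(s$per_base, reference))
  kept <- coverage_filter(site_tables, min_coverage)
  cand <- cand[cand$pos %in% kept$pos, , drop = FALSE]

  probs <- lapply(names(sims), function(nm) {
    s <- sims[[nm]]
    wf <- window_features(site_tables[[nm]], current_window_stats(s$events))
    wf <- wf[match(cand$pos, wf$center), , drop = FALSE]
    predict(fit, wf)
  })
  names(probs) <- names(sims)
  wt_probs <- do.call(cbind, probs[grep("^wt\\.", names(probs))])
  ko_probs <- do.call(cbind, probs[grep("^ko\\.", names(probs))])
  calls <- call_sites(cand, wt_probs, ko_probs)
  calls$truly_modified <- calls$pos %in% mod_sites
  known <- data.frame(ref = rn, pos = intersect(mod_sites, cand$pos))
  perf <- performance_vs_known(calls, known)
  n_neg <- sum(!calls$truly_modified)
  list(calls = calls, performance = perf,
       recovery = perf$recovery,
       fpr = if (n_neg > 0) perf$FP / n_neg else NA_real_,
       model = fit, modified_sites = mod_sites)
}

#' Stoichiometry recovery study
#'
#' Simulates calibration runs (0% and 100% methylated) and observation runs
#' at the requested methylated-read fractions, then estimates each fraction
#' from per-site mismatch frequencies by linear interpolation between the
#' calibration levels, averaged over modified sites.
#'
#' @param reference Named character vector of length 1.
#' @param fractions Methylated-read fractions to recover
#'   (default c(0.25, 0.5, 0.75)).
#' @param coverage Reads per run (default 500).
#' @param model An [error_model()].
#' @param seed Integer RNG seed.
#' @return Data frame: fraction, estimate, abs_error, n_sites.
#' @export
stoichiometry_study <- function(reference, fractions = c(0.25, 0.5, 0.75),
                                coverage = 500L, model = error_model(),
                                seed = 1L) {
  stopifnot(length(reference) == 1)
  if (is.null(names(reference))) names(reference) <- "ref"
  centers <- single_a_centers(reference)$pos
  a_pos <- centers  # modify exactly the assayed single-A centers
  site_mis <- function(fraction, sd) {
    s <- simulate_reads(reference[[1]], coverage, a_pos,
                        mod_fraction = fraction, model = model, seed = sd,
                        ref_name = names(reference), events = FALSE)
    tb <- per_site_features(s$per_base, reference)
    tb$mis[match(centers, tb$pos)]
  }
  mis0 <- site_mis(0, seed + 1000L)
  mis1 <- site_mis(1, seed + 2000L)
  out <- data.frame(fraction = fractions, estimate = NA_real_,
                    abs_error = NA_real_, n_sites = length(centers))
  for (i in seq_along(fractions)) {
    obs <- site_mis(fractions[i], seed + i)
    est <- estimate_stoichiometry(obs, mean(mis0), mean(mis1))
    out$estimate[i] <- mean(est)
    out$abs_error[i] <- abs(out$estimate[i] - fractions[i])
  }
  out
}

#' Run the full simulated pipeline end to end
#'
#' Designs a k-mer-complete reference, simulates training constructs, trains
#' the classifier, and runs the wild-type/knockout calling study. Intended
#' as a quick smoke run (a couple of minutes at the default sizes).
#'
#' @param seed Integer RNG seed.
#' @param multiplicity Designer edge multiplicity (default 3, ~3 kb).
#' @param coverage Reads per simulated run (default 60).
#' @param quiet Suppress progress messages.
#' @return List with the design, trained model and study results.
#' @export
demo_pipeline <- function(seed = 1L, multiplicity = 3L, coverage = 60L,
                          quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  say("designing k-mer-complete reference ...")
  ds <- design_curlcakes(design_config(multiplicity = multiplicity,
                                       n_candidates = 5L, seed = seed))
  ref <- c(ref = ds$superstring)
  say("simulating training constructs and fitting the SVM ...")
  tr <- simulate_training_windows(ref, coverage = coverage, seed = seed)
  fit <- train_svm(tr$windows, seed = seed)
  say(sprintf("  held-out accuracy: %.3f (%s kernel)",
              fit$heldout_accuracy, fit$selected_kernel))
  say("running wild-type vs knockout study ...")
  st <- wtko_study(ref, coverage = coverage, seed = seed)
  say(sprintf("  recovery %.2f, false-positive rate %.2f",
              st$recovery, st$fpr))
  invisible(list(design = ds, training = tr, model = fit, study = st))
}
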