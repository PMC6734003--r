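#' Simulate aligned direct RNA reads with modification error signatures
#'
#' Emits `coverage` full-length reads over the reference as a per-base
#' alignment table (one row per reference position per read: a call or a
#' deletion, plus any trailing insertion) and an event table of per-read
#' 5-mer current statistics. Exactly `round(coverage * mod_fraction)` reads
#' carry the modified error model at `modified_positions`; which reads is
#' drawn under `seed`, so identical arguments reproduce identical tables.
#'
#' @param reference Single reference sequence (character; U normalized to T).
#' @param coverage Number of reads (>= 0).
#' @param modified_positions 1-based A positions carrying m6A in modified
#'   reads (may be empty).
#' @param mod_fraction Fraction of reads carrying the modification, in
#'   \[0, 1\].
#' @param model An [error_model()].
#' @param seed Integer RNG seed.
#' @param ref_name Reference name used in the tables.
#' @param read_prefix Prefix for read identifiers (keep distinct when tables
#'   will be mixed).
#' @param events If `FALSE`, skip the event table.
#' @return List with `per_base` (data frame: read_id, ref, pos, ref_base,
#'   call, qual, ins), `events` (read_id, ref, window_start, mean_pA, sd_pA or
#'   NULL), and `modified_reads` (character vector of modified read ids).
#' @export
simulate_reads <- function(reference, coverage, modified_positions = integer(0),
                           mod_fraction = 0, model = error_model(), seed = 1L,
                           ref_name = "ref", read_prefix = "read",
                           events = TRUE) {
  stopifnot(inherits(model, "error_model"), coverage >= 0,
            mod_fraction >= 0, mod_fraction <= 1)
  reference <- normalize_seq(reference)
  L <- nchar(reference)
  ref_bases <- strsplit(reference, "", fixed = TRUE)[[1]]
  modified_positions <- sort(unique(as.integer(modified_positions)))
  if (length(modified_positions)) {
    if (any(modified_positions < 1 | modified_positions > L))
      stop("modified positions outside reference")
    bad <- ref_bases[modified_positions] != "A"
    if (any(bad))
      stop("modified positions must be A (m6A replaces adenine only): ",
           paste(modified_positions[bad], collapse = ","))
  }
  empty_pb <- data.frame(read_id = character(0), ref = character(0),
                         pos = integer(0), ref_base = character(0),
                         call = character(0), qual = integer(0),
                         ins = character(0), stringsAsFactors = FALSE)
  empty_ev <- data.frame(read_id = character(0), ref = character(0),
                         window_start = integer(0), mean_pA = numeric(0),
                         sd_pA = numeric(0), stringsAsFactors = FALSE)
  if (coverage == 0)
    return(list(per_base = empty_pb,
                events = if (events) empty_ev else NULL,
                modified_reads = character(0)))
  set.seed(seed)
  n_mod <- round(coverage * mod_fraction)
  read_ids <- sprintf("%s%05d", read_prefix, seq_len(coverage))
  mod_read <- rep(FALSE, coverage)
  if (n_mod > 0) mod_read[sample.int(coverage, n_mod)] <- TRUE

  w <- .bleed_weights(L, modified_positions, model$neighbor_bleed)
  clamp01 <- function(p) pmin(pmax(p, 0), 1)
  p_del <- list(base = rep(model$p_deletion, L),
                mod = clamp01(model$p_deletion + w * model$deletion_delta))
  p_mis <- list(base = rep(model$p_mismatch, L),
                mod = clamp01(model$p_mismatch + w * model$mismatch_delta))
  p_ins <- list(base = rep(model$p_insertion, L),
                mod = clamp01(model$p_insertion + w * model$insertion_delta))
  q_mu <- list(base = rep(model$base_quality_mean, L),
               mod = model$base_quality_mean + w * model$quality_shift)

  # matrices: reads x positions
  pick <- function(lst) {
    m <- matrix(lst$base, nrow = coverage, ncol = L, byrow = TRUE)
    if (any(mod_read)) m[mod_read, ] <- rep(lst$mod, each = sum(mod_read))
    m
  }
  Pd <- pick(p_del); Pm <- pick(p_mis); Pi <- pick(p_ins); Qm <- pick(q_mu)
  # cap mismatch so del + mis <= 1
  Pm <- pmin(Pm, 1 - Pd)

  u <- matrix(stats::runif(coverage * L), coverage, L)
  is_del <- u < Pd
  is_mis <- !is_del & (u < Pd + Pm)
  call <- matrix(rep(ref_bases, each = coverage), coverage, L)
  if (any(is_mis)) {
    idx <- which(is_mis)
    refb <- call[idx]
    for (b in DNA_ALPHABET) {
      sel <- idx[refb == b]
      if (length(sel))
        call[sel] <- sample(setdiff(DNA_ALPHABET, b), length(sel),
                            replace = TRUE, prob = model$substitution_profile)
    }
  }
  call[is_del] <- "DEL"
  qual <- matrix(as.integer(pmin(pmax(round(
    stats::rnorm(coverage * L, mean = Qm, sd = model$base_quality_sd)), 1), 40)),
    coverage, L)
  qual[is_del] <- NA_integer_
  has_ins <- matrix(stats::runif(coverage * L), coverage, L) < Pi
  ins <- matrix("", coverage, L)
  if (any(has_ins))
    ins[has_ins] <- sample(DNA_ALPHABET, sum(has_ins), replace = TRUE)

  per_base <- data.frame(
    read_id = rep(read_ids, times = L),
    ref = ref_name,
    pos = rep(seq_len(L), each = coverage),
    ref_base = rep(ref_bases, each = coverage),
    call = as.vector(call), qual = as.vector(qual), ins = as.vector(ins),
    stringsAsFactors = FALSE)
  ord <- order(match(per_base$read_id, read_ids), per_base$pos)
  per_base <- per_base[ord, , drop = FALSE]
  rownames(per_base) <- NULL

  ev <- NULL
  if (events && L >= 5) {
    nw <- L - 4L
    # window covers a modified base -> shifted mean, for modified reads only
    mod_window <- rep(FALSE, nw)
    for (p in modified_positions) {
      lo <- max(1L, p - 4L); hi <- min(nw, p)
      if (lo <= hi) mod_window[lo:hi] <- TRUE
    }
    mu <- matrix(model$current_mean_baseline, coverage, nw)
    if (any(mod_read) && any(mod_window))
      mu[mod_read, mod_window] <- mu[mod_read, mod_window] + model$current_shift
    cm <- matrix(stats::rnorm(coverage * nw, mean = mu, sd = model$current_sd),
                 coverage, nw)
    cs <- matrix(abs(stats::rnorm(coverage * nw, mean = 2, sd = 0.5)),
                 coverage, nw)
    ev <- data.frame(read_id = rep(read_ids, times = nw),
                     ref = ref_name,
                     window_start = rep(seq_len(nw), each = coverage),
                     mean_pA = as.vector(cm), sd_pA = as.vector(cs),
                     stringsAsFactors = FALSE)
    ord <- order(match(ev$read_id, read_ids), ev$window_start)
    ev <- ev[ord, , drop = FALSE]
    rownames(ev) <- NULL
  } else if (events) {
    ev <- empty_ev
  }
  list(per_base = per_base, events = ev,
       modified_reads = read_ids[mod_read])
}

#' Mix modified and unmodified read sets at a methylation ratio
#'
#' Samples without replacement `floor(n_reads * fraction)` reads from the
#' modified set and the remainder from the unmodified set, preserving read
#' identities, to emulate partial methylation (e.g. ratios 0, 5, 10, 25, 50,
#' 75, 90, 95, 100%).
#'
#' @param modified_table,unmodified_table Per-base tables over the same
#'   reference (as from [simulate_reads()]).
#' @param fraction Methylation ratio in \[0, 1\].
#' @param n_reads Total reads in the mixture.
#' @param seed Integer RNG seed.
#' @return Per-base table of the mixture; attribute `"read_ids"` is a list
#'   with the sampled `modified` and `unmodified` read ids.
#' @export
mix_read_sets <- function(modified_table, unmodified_table, fraction, n_reads,
                          seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1, n_reads >= 0)
  if (!identical(sort(unique(modified_table$ref)),
                 sort(unique(unmodified_table$ref))) &&
      nrow(modified_table) && nrow(unmodified_table))
    stop("read sets cover different references")
  n_mod <- floor(n_reads * fraction)
  n_unm <- n_reads - n_mod
  ids_mod <- unique(modified_table$read_id)
  ids_unm <- unique(unmodified_table$read_id)
  if (n_mod > length(ids_mod))
    stop("requested ", n_mod, " modified reads but only ",
         length(ids_mod), " available")
  if (n_unm > length(ids_unm))
    stop("requested ", n_unm, " unmodified reads but only ",
         length(ids_unm), " available")
  set.seed(seed)
  take_mod <- if (n_mod) sample(ids_mod, n_mod) else character(0)
  take_unm <- if (n_unm) sample(ids_unm, n_unm) else character(0)
  out <- rbind(modified_table[modified_table$read_id %in% take_mod, ,
                              drop = FALSE],
               unmodified_table[unmodified_table$read_id %in% take_unm, ,
                                drop = FALSE])
  rownames(out) <- NULL
  attr(out, "read_ids") <- list(modified = take_mod, unmodified = take_unm)
  out
}

## Deterministic sub-seed below 2^31 from (seed, condition index, replicate).
.sub_seed <- function(seed, cond_i, rep_i) {
  as.integer((as.numeric(seed) + 7919 * cond_i + 104729 * rep_i) %% 2147483647)
}

#' Simulate replicated datasets for several conditions
#'
#' Mirrors a multi-replicate sequencing design (e.g. three biological
#' replicates each of a wild-type strain at 50% methylation and a
#' methyltransferase-knockout strain at 0%). Each replicate uses an
#' independent sub-seed derived deterministically from `(seed, condition,
#' replicate)`.
#'
#' @param reference Reference sequence.
#' @param design Named numeric vector of per-condition `mod_fraction`s, e.g.
#'   `c(wt = 0.5, ko = 0)`.
#' @param modified_positions 1-based A positions modified in modified reads.
#' @param n_replicates Replicates per condition (default 3).
#' @param coverage Reads per replicate.
#' @param model An [error_model()].
#' @param seed Integer RNG seed.
#' @param events Forwarded to [simulate_reads()].
#' @return Named list keyed `"<condition>.rep<i>"`, each a
#'   [simulate_reads()] result plus `condition` and `replicate` fields.
#' @export
simulate_replicates <- function(reference, design, modified_positions,
                                n_replicates = 3L, coverage = 100L,
                                model = error_model(), seed = 1L,
                                events = TRUE) {
  stopifnot(n_replicates >= 1, !is.null(names(design)),
            all(nzchar(names(design))))
  out <- list()
  for (ci in seq_along(design)) {
    cond <- names(design)[ci]
    for (ri in seq_len(n_replicates)) {
      sim <- simulate_reads(reference, coverage, modified_positions,
                            mod_fraction = design[[ci]], model = model,
                            seed = .sub_seed(seed, ci, ri),
                            read_prefix = sprintf("%s_r%d_", cond, ri),
                            events = events)
      sim$condition <- cond
      sim$replicate <- ri
      out[[sprintf("%s.rep%d", cond, ri)]] <- sim
    }
  }
  out
}
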