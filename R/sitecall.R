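IUPAC <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))

#' Scan a reference for candidate m6A motif sites
#'
#' Finds every position whose surrounding 5-mer matches a degenerate IUPAC
#' motif (default RRACH, the canonical m6A context; R = A/G, H = A/C/T). The
#' candidate center is the A at motif position 3. 5-mers containing more than
#' one A are flagged: in a fully methylated training construct every A
#' carries m6A, so multi-A k-mers hold several modifications at once and are
#' excluded from scoring by default.
#'
#' @param reference Single sequence, or named character vector of sequences.
#' @param motif Length-5 IUPAC pattern (default `"RRACH"`; U accepted).
#' @return Data frame: ref, pos (1-based center), kmer, multi_A.
#' @export
scan_motif <- function(reference, motif = "RRACH") {
  motif <- normalize_seq(motif)
  if (nchar(motif) != 5L)
    stop("motif must be a 5-mer (windows are 5-mers); got length ",
         nchar(motif))
  mv <- strsplit(motif, "", fixed = TRUE)[[1]]
  if (!all(mv %in% names(IUPAC)))
    stop("motif contains non-IUPAC letters: ",
         paste(setdiff(mv, names(IUPAC)), collapse = ","))
  if (is.null(names(reference)))
    names(reference) <- if (length(reference) == 1) "ref"
                        else sprintf("ref%d", seq_along(reference))
  reference <- normalize_seq(reference)
  out <- lapply(names(reference), function(rn) {
    subj <- Biostrings::DNAString(reference[[rn]])
    hits <- Biostrings::matchPattern(motif, subj, fixed = FALSE)
    if (length(hits) == 0)
      return(data.frame(ref = character(0), pos = integer(0),
                        kmer = character(0), multi_A = logical(0),
                        stringsAsFactors = FALSE))
    km <- as.character(hits)
    data.frame(ref = rn, pos = Biostrings::start(hits) + 2L, kmer = km,
               multi_A = vapply(strsplit(km, "", fixed = TRUE),
                                function(v) sum(v == "A") > 1L, logical(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Keep sites covered in every sample
#'
#' A site is retained if and only if its coverage reaches `min_coverage` in
#' every supplied per-site table (e.g. 3 wild-type and 3 knockout samples).
#' The default of 5 reads/site is the working minimum; `min_coverage = 1`
#' keeps every site observed in all samples.
#'
#' @param site_tables List of per-site tables from [per_site_features()].
#' @param min_coverage Minimum reads per site per sample (default 5).
#' @return Data frame of retained sites: ref, pos.
#' @export
coverage_filter <- function(site_tables, min_coverage = 5L) {
  stopifnot(length(site_tables) >= 1, min_coverage >= 0)
  keys <- lapply(site_tables, function(tb) {
    paste(tb$ref, tb$pos)[!is.na(tb$cov) & tb$cov >= min_coverage]
  })
  keep <- Reduce(intersect, keys)
  if (length(keep) == 0)
    return(data.frame(ref = character(0), pos = integer(0),
                      stringsAsFactors = FALSE))
  tb1 <- site_tables[[1]]
  m <- match(keep, paste(tb1$ref, tb1$pos))
  out <- data.frame(ref = tb1$ref[m], pos = tb1$pos[m],
                    stringsAsFactors = FALSE)
  out <- out[order(out$ref, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-replicate modification probabilities into a site score
#'
#' The modification score M is 1 when the probability is at or above
#' `score_threshold` in all replicates, and the arithmetic mean of the
#' probabilities otherwise. Vectorized over sites; permutation-invariant and
#' monotone non-decreasing in each replicate.
#'
#' @param ... Equal-length numeric vectors of per-replicate probabilities in
#'   \[0, 1\] (one vector per replicate), or a single numeric matrix with one
#'   column per replicate.
#' @param score_threshold Threshold for the all-replicates branch
#'   (default 0.5, inclusive).
#' @param n_replicates Expected number of replicates (default 3); supplying a
#'   different number is an error.
#' @return Numeric vector of merged scores M in \[0, 1\].
#' @export
merge_replicate_scores <- function(..., score_threshold = 0.5,
                                   n_replicates = 3L) {
  args <- list(...)
  if (length(args) == 1 && is.matrix(args[[1]])) {
    s <- args[[1]]
  } else {
    if (length(unique(lengths(args))) != 1)
      stop("replicate vectors must have equal length")
    s <- do.call(cbind, args)
  }
  if (ncol(s) != n_replicates)
    stop("expected ", n_replicates, " replicates, got ", ncol(s))
  if (any(s < 0 | s > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  all_pass <- rowSums(s >= score_threshold) == ncol(s)
  ifelse(all_pass, 1, rowMeans(s))
}

#' Differential wild-type versus knockout modification call
#'
#' A site is called modified when the modification ratio `M_wt / M_ko`
#' strictly exceeds `ratio_threshold` (default 1.5) and `M_wt` strictly
#' exceeds `score_threshold` (default 0.5). When `M_ko` is 0 the ratio is
#' treated as `+Inf` (the site remains callable on `M_wt` alone); this is the
#' `zero_denominator_policy` and can be set to any substitute value.
#'
#' @param M_wt,M_ko Merged scores in \[0, 1\] (vectors of equal length).
#' @param score_threshold Minimum wild-type score (strict; default 0.5).
#' @param ratio_threshold Minimum wt/ko ratio (strict; default 1.5).
#' @param zero_denominator_policy Ratio value substituted when `M_ko == 0`
#'   (default `Inf`).
#' @return Data frame: M_wt, M_ko, ratio, status (`"modified"` /
#'   `"unmodified"`).
#' @export
call_modification <- function(M_wt, M_ko, score_threshold = 0.5,
                              ratio_threshold = 1.5,
                              zero_denominator_policy = Inf) {
  stopifnot(length(M_wt) == length(M_ko),
            all(M_wt >= 0 & M_wt <= 1, na.rm = TRUE),
            all(M_ko >= 0 & M_ko <= 1, na.rm = TRUE))
  ratio <- ifelse(M_ko == 0, zero_denominator_policy, M_wt / M_ko)
  status <- ifelse(ratio > ratio_threshold & M_wt > score_threshold,
                   "modified", "unmodified")
  data.frame(M_wt = M_wt, M_ko = M_ko, ratio = ratio, status = status,
             stringsAsFactors = FALSE)
}

#' Performance against a known-site list
#'
#' Counts known modified sites that were called modified (TP) or unmodified
#' (FN), and the remaining analyzed sites called modified (FP) or unmodified
#' (TN). Recovery is TP over the number of known sites.
#'
#' @param calls Data frame with `ref`, `pos`, `status` (from
#'   [call_modification()] plus site coordinates).
#' @param known Data frame with `ref`, `pos` of known modified sites; must be
#'   a subset of the analyzed sites.
#' @return A `"performance_report"`; `recovery` is `NA` when `known` is
#'   empty.
#' @export
performance_vs_known <- function(calls, known) {
  key <- paste(calls$ref, calls$pos)
  kk <- paste(known$ref, known$pos)
  if (nrow(known) && !all(kk %in% key))
    stop("known sites must be a subset of the analyzed sites")
  is_known <- key %in% kk
  called <- calls$status == "modified"
  rep_ <- list(TP = sum(is_known & called), FN = sum(is_known & !called),
               FP = sum(!is_known & called), TN = sum(!is_known & !called))
  n <- nrow(calls)
  rep_$accuracy <- (rep_$TP + rep_$TN) / n
  rep_$recovery <- if (nrow(known)) rep_$TP / nrow(known) else NA_real_
  rep_$sensitivity <- rep_$recovery
  rep_$specificity <- if (rep_$TN + rep_$FP > 0)
    rep_$TN / (rep_$TN + rep_$FP) else NA_real_
  rep_$ppv <- if (rep_$TP + rep_$FP > 0)
    rep_$TP / (rep_$TP + rep_$FP) else NA_real_
  class(rep_) <- "performance_report"
  rep_
}

#' Estimate per-site modification stoichiometry
#'
#' Linear interpolation of an observed mismatch frequency between unmodified
#' (0%) and fully modified (100%) calibration levels:
#' `(observed - unmodified) / (fully_modified - unmodified)`, clipped to
#' \[0, 1\]. Vectorized.
#'
#' @param observed_mismatch Observed per-site mismatch frequencies.
#' @param unmodified_mismatch Mismatch level of the 0% calibration.
#' @param fully_modified_mismatch Mismatch level of the 100% calibration;
#'   must strictly exceed `unmodified_mismatch`.
#' @return Estimated modified fraction(s) in \[0, 1\].
#' @export
estimate_stoichiometry <- function(observed_mismatch, unmodified_mismatch,
                                   fully_modified_mismatch) {
  if (any(fully_modified_mismatch <= unmodified_mismatch))
    stop("degenerate calibration: fully modified level must exceed ",
         "the unmodified level")
  est <- (observed_mismatch - unmodified_mismatch) /
    (fully_modified_mismatch - unmodified_mismatch)
  pmin(pmax(est, 0), 1)
}

#' Call m6A sites from per-replicate probability tables
#'
#' Composes replicate merging and differential calling over a site table:
#' per-strain scores are merged with [merge_replicate_scores()] and compared
#' with [call_modification()].
#'
#' @param sites Data frame with `ref`, `pos` (and optionally `kmer`).
#' @param wt_probs,ko_probs Matrices (sites x replicates) of per-replicate
#'   probabilities, rows aligned with `sites`.
#' @param score_threshold,ratio_threshold,zero_denominator_policy See
#'   [call_modification()].
#' @return `sites` with M_wt, M_ko, ratio, status columns appended.
#' @export
call_sites <- function(sites, wt_probs, ko_probs, score_threshold = 0.5,
                       ratio_threshold = 1.5, zero_denominator_policy = Inf) {
  stopifnot(nrow(wt_probs) == nrow(sites), nrow(ko_probs) == nrow(sites))
  M_wt <- merge_replicate_scores(wt_probs, score_threshold = score_threshold,
                                 n_replicates = ncol(wt_probs))
  M_ko <- merge_replicate_scores(ko_probs, score_threshold = score_threshold,
                                 n_replicates = ncol(ko_probs))
  cbind(sites, call_modification(M_wt, M_ko, score_threshold, ratio_threshold,
                                 zero_denominator_policy))
}
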