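# Shared fixtures, built once per test run.

# small k-mer-complete reference (~4 kb) used across module tests
fx_ref <- local({
  s <- build_kmer_superstring(5, seed = 11, multiplicity = 4)
  c(ref = s)
})
fx_a_pos <- which(strsplit(fx_ref[[1]], "", fixed = TRUE)[[1]] == "A")

# brute-force per-site feature oracle: naive per-read loop
oracle_site_features <- function(per_base) {
  keys <- unique(per_base[, c("ref", "pos")])
  keys <- keys[order(keys$ref, keys$pos), , drop = FALSE]
  res <- lapply(seq_len(nrow(keys)), function(i) {
    rows <- per_base[per_base$ref == keys$ref[i] & per_base$pos == keys$pos[i],
                     , drop = FALSE]
    cov <- nrow(rows)
    dels <- sum(rows$call == "DEL")
    mis <- sum(rows$call != "DEL" & rows$call != rows$ref_base)
    insn <- sum(rows$ins != "")
    qs <- rows$qual[rows$call != "DEL"]
    data.frame(ref = keys$ref[i], pos = keys$pos[i],
               base = rows$ref_base[1], cov = cov,
               q_mean = if (length(qs)) mean(qs) else NA_real_,
               mis = mis / cov, ins = insn / cov, del = dels / cov,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# exhaustive O(n^2) pairwise-concordance AUC oracle
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# exhaustive reverse-complement stem-scan oracle
oracle_stem_count <- function(seq, min_stem, min_loop) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  cnt <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i <= min_loop + min_stem) next
    ok <- TRUE
    for (t in 0:(min_stem - 1)) {
      a <- i + t; b <- j - t
      if (a > n || b < 1 || comp[[v[a]]] != v[b]) { ok <- FALSE; break }
    }
    if (ok) cnt <- cnt + 1
  }
  cnt
}

# random per-base table generator for oracle-equivalence tests
random_per_base <- function(n_reads = 8, L = 12, seed = 1) {
  set.seed(seed)
  ref_bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  rows <- list()
  for (r in seq_len(n_reads)) {
    calls <- ifelse(runif(L) < 0.1, "DEL",
                    sample(c("A", "C", "G", "T"), L, replace = TRUE))
    rows[[r]] <- data.frame(
      read_id = sprintf("r%02d", r), ref = "ref", pos = seq_len(L),
      ref_base = ref_bases, call = calls,
      qual = ifelse(calls == "DEL", NA_integer_,
                    sample(1:40, L, replace = TRUE)),
      ins = ifelse(runif(L) < 0.1, "A", ""), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
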