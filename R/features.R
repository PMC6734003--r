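#' Per-site base-called features
#'
#' Aggregates a per-base alignment table into per-reference-position features:
#' spanning coverage, mean Phred quality over non-deleted calls, and mismatch,
#' insertion and deletion frequencies. The denominator of every frequency is
#' the spanning coverage (reads contributing a call or a deletion at the
#' site), so `mismatch + deletion + match = 1` at each site.
#'
#' @param per_base Per-base table (read_id, ref, pos, ref_base, call, qual,
#'   ins), e.g. from [simulate_reads()] or [load_alignment()].
#' @param reference Optional named character vector of reference sequences;
#'   when given, uncovered positions are emitted with coverage 0 and missing
#'   frequencies rather than dropped, and `ref_base` is taken from it.
#' @return Data frame with columns ref, pos, base, cov, q_mean, mis, ins, del.
#' @export
per_site_features <- function(per_base, reference = NULL) {
  if (!is.null(reference)) reference <- normalize_seq(reference)
  refs <- if (!is.null(reference)) names(reference) else unique(per_base$ref)
  out <- lapply(refs, function(rn) {
    tb <- per_base[per_base$ref == rn, , drop = FALSE]
    if (!is.null(reference)) {
      L <- nchar(reference[[rn]])
      bases <- strsplit(reference[[rn]], "", fixed = TRUE)[[1]]
      pos <- seq_len(L)
    } else {
      pos <- sort(unique(tb$pos))
      bases <- tb$ref_base[match(pos, tb$pos)]
    }
    f <- factor(tb$pos, levels = pos)
    cov <- as.integer(tabulate(f, nbins = length(pos)))
    # rowsum drops unused levels; re-expand so uncovered positions keep a row
    sum_by <- function(x) {
      r <- rowsum(x, f)
      out <- numeric(length(pos))
      out[match(rownames(r), levels(f))] <- r[, 1]
      out
    }
    is_del <- tb$call == "DEL"
    is_mis <- !is_del & tb$call != tb$ref_base
    n_del <- as.integer(sum_by(as.numeric(is_del)))
    n_mis <- as.integer(sum_by(as.numeric(is_mis)))
    n_ins <- as.integer(sum_by(as.numeric(nzchar(tb$ins))))
    q_sum <- sum_by(ifelse(is_del, 0, as.numeric(tb$qual)))
    n_call <- cov - n_del
    data.frame(ref = rn, pos = pos, base = bases, cov = cov,
               q_mean = ifelse(n_call > 0, q_sum / n_call, NA_real_),
               mis = ifelse(cov > 0, n_mis / cov, NA_real_),
               ins = ifelse(cov > 0, n_ins / cov, NA_real_),
               del = ifelse(cov > 0, n_del / cov, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Across-read current statistics per 5-mer window
#'
#' Groups an event table by (reference, window start) and reports the mean of
#' the per-read current means and their sample standard deviation (n - 1
#' denominator; 0 when a window is seen in a single read).
#'
#' @param events Event table (read_id, ref, window_start, mean_pA, sd_pA).
#' @return Data frame: ref, window_start, curr_mean, curr_sd, n_reads.
#' @export
current_window_stats <- function(events) {
  if (nrow(events) == 0)
    return(data.frame(ref = character(0), window_start = integer(0),
                      curr_mean = numeric(0), curr_sd = numeric(0),
                      n_reads = integer(0), stringsAsFactors = FALSE))
  key <- interaction(events$ref, events$window_start, drop = TRUE, sep = "\r")
  n <- as.integer(tabulate(key, nbins = nlevels(key)))
  s1 <- rowsum(events$mean_pA, key)[, 1]
  s2 <- rowsum(events$mean_pA^2, key)[, 1]
  mu <- s1 / n
  var <- ifelse(n > 1, pmax(s2 - n * mu^2, 0) / (n - 1), 0)
  parts <- strsplit(levels(key), "\r", fixed = TRUE)
  out <- data.frame(ref = vapply(parts, `[`, "", 1),
                    window_start = as.integer(vapply(parts, `[`, "", 2)),
                    curr_mean = mu, curr_sd = sqrt(var), n_reads = n,
                    stringsAsFactors = FALSE)
  out <- out[order(out$ref, out$window_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble 5-mer window feature vectors
#'
#' One row per center position with full context inside the reference: the
#' 5-mer, the per-position quality / mismatch / deletion features at offsets
#' -2..+2 (15 numbers), window current statistics, and the minimum coverage
#' over the five positions. Rows with any missing positional feature are
#' flagged `complete = FALSE` and carry `NA`s.
#'
#' @param sites Per-site table from [per_site_features()]; positions must be
#'   contiguous per reference.
#' @param current Optional table from [current_window_stats()] (joined on
#'   window start = center - 2).
#' @param k Window size; must be odd (only 5 is used by the m6A model).
#' @return Data frame: ref, center, kmer, q_m2..q_p2, mis_m2..mis_p2,
#'   del_m2..del_p2, curr_mean, curr_sd, cov_min, complete, label.
#' @export
window_features <- function(sites, current = NULL, k = 5L) {
  stopifnot(k %% 2 == 1, k >= 1)
  h <- (k - 1L) %/% 2L
  offs <- -h:h
  off_tag <- function(o) ifelse(o < 0, paste0("m", -o),
                                ifelse(o > 0, paste0("p", o), "0"))
  out <- lapply(unique(sites$ref), function(rn) {
    tb <- sites[sites$ref == rn, , drop = FALSE]
    tb <- tb[order(tb$pos), , drop = FALSE]
    L <- nrow(tb)
    if (L < k) return(NULL)
    if (!all(diff(tb$pos) == 1L))
      stop("per-site table for ", rn, " is not contiguous")
    centers <- (h + 1L):(L - h)
    df <- data.frame(ref = rn, center = tb$pos[centers],
                     stringsAsFactors = FALSE)
    km <- matrix("", length(centers), k)
    for (i in seq_along(offs)) km[, i] <- tb$base[centers + offs[i]]
    df$kmer <- apply(km, 1, paste, collapse = "")
    for (feat in c("q", "mis", "del")) {
      col <- c(q = "q_mean", mis = "mis", del = "del")[[feat]]
      for (i in seq_along(offs))
        df[[paste0(feat, "_", off_tag(offs[i]))]] <- tb[[col]][centers + offs[i]]
    }
    covm <- matrix(0L, length(centers), k)
    for (i in seq_along(offs)) covm[, i] <- tb$cov[centers + offs[i]]
    df$cov_min <- apply(covm, 1, min)
    df
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0)
    stop("no reference long enough for a ", k, "-mer window")
  if (!is.null(current) && nrow(current)) {
    key <- paste(out$ref, out$center - h)
    ck <- paste(current$ref, current$window_start)
    m <- match(key, ck)
    out$curr_mean <- current$curr_mean[m]
    out$curr_sd <- current$curr_sd[m]
  } else {
    out$curr_mean <- NA_real_
    out$curr_sd <- NA_real_
  }
  featcols <- grep("^(q|mis|del)_", names(out), value = TRUE)
  out$complete <- stats::complete.cases(out[, featcols, drop = FALSE])
  out$label <- NA_character_
  rownames(out) <- NULL
  out
}

## Feature column sets used by the classifier.
feature_columns <- function(feature_set) {
  switch(feature_set,
    q0 = "q_0", mis0 = "mis_0", del0 = "del_0",
    curr_mean = "curr_mean", curr_sd = "curr_sd",
    curr2 = c("curr_mean", "curr_sd"),
    combined3 = c("q_0", "mis_0", "del_0"),
    extended15 = c(paste0("q_", c("m2", "m1", "0", "p1", "p2")),
                   paste0("mis_", c("m2", "m1", "0", "p1", "p2")),
                   paste0("del_", c("m2", "m1", "0", "p1", "p2"))),
    stop("unknown feature set: ", feature_set))
}
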