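PER_BASE_COLS <- c("read_id", "ref", "pos", "ref_base", "call", "qual", "ins")
EVENT_COLS <- c("read_id", "ref", "window_start", "mean_pA", "sd_pA")

#' Load an alignment into the canonical per-base table
#'
#' Accepts SAM/BAM or the package's per-base TSV dialect and returns one row
#' per aligned reference position per read. CIGAR `M`/`=`/`X` expand to
#' calls, `D` to `DEL` rows, `I` to inserted bases attached to the preceding
#' reference position; soft clips are skipped. Mismatch determination uses
#' the MD tag when present, otherwise the reference; a BAM without MD and
#' without `reference` is refused.
#'
#' @param path SAM, BAM, or per-base TSV file.
#' @param reference Optional named character vector of reference sequences.
#' @return Per-base data frame (read_id, ref, pos, ref_base, call, qual, ins).
#' @export
load_alignment <- function(path, reference = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt")) {
    tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(qual = "integer", pos = "integer",
                                           ins = "character"))
    missing_cols <- setdiff(PER_BASE_COLS, names(tb))
    if (length(missing_cols))
      stop("per-base TSV lacks columns: ",
           paste(missing_cols, collapse = ", "))
    tb$ins[is.na(tb$ins)] <- ""
    return(tb[, PER_BASE_COLS])
  }
  if (!ext %in% c("sam", "bam"))
    stop("unsupported alignment extension '", ext, "' (use .bam, .sam, .tsv)")
  bam_path <- if (ext == "sam")
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE) else path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "seq", "qual"),
    tag = "MD",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(bam_path, param = p)[[1]]
  n <- length(b$qname)
  if (n == 0)
    return(data.frame(read_id = character(0), ref = character(0),
                      pos = integer(0), ref_base = character(0),
                      call = character(0), qual = integer(0),
                      ins = character(0), stringsAsFactors = FALSE))
  md <- b$tag$MD
  if (!is.null(reference)) reference <- normalize_seq(reference)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rn <- as.character(b$rname[i])
    ref_seq <- if (!is.null(reference) && rn %in% names(reference))
      reference[[rn]] else NULL
    ref_from_md <- NULL
    if (is.null(ref_seq)) {
      if (is.null(md) || is.na(md[i]))
        stop("alignment for read ", b$qname[i], " has no MD tag and no ",
             "reference sequence was supplied; pass `reference` or add MD ",
             "tags (samtools calmd)")
      ref_from_md <- .md_reference(md[i])
    }
    rows[[i]] <- .expand_cigar(
      read_id = b$qname[i], ref_name = rn, ref_start = b$pos[i],
      cigar = b$cigar[i], seq = as.character(b$seq[i]),
      qual = utf8ToInt(as.character(b$qual[i])) - 33L,  # Phred+33
      ref_seq = ref_seq, ref_from_md = ref_from_md)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Reconstruct the aligned reference bases (relative to the aligned portion,
## deletions included) from an MD tag: runs of matches are returned as NA
## (take the call), mismatched bases and deleted bases (^) verbatim.
.md_reference <- function(md) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  out <- character(0)
  for (tk in toks) {
    if (grepl("^[0-9]+$", tk)) {
      out <- c(out, rep(NA_character_, as.integer(tk)))
    } else if (startsWith(tk, "^")) {
      out <- c(out, strsplit(substring(tk, 2), "", fixed = TRUE)[[1]])
    } else {
      out <- c(out, tk)
    }
  }
  out
}

.expand_cigar <- function(read_id, ref_name, ref_start, cigar, seq, qual,
                          ref_seq = NULL, ref_from_md = NULL) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]", "", ops))
  type <- sub("[0-9]+", "", ops)
  qpos <- 1L; rpos <- ref_start; mdpos <- 1L
  pos <- integer(0); call <- character(0); quals <- integer(0)
  ins_at <- integer(0); ins_seq <- character(0)
  read_bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_along(ops)) {
    l <- lens[i]
    switch(type[i],
      "M" = , "=" = , "X" = {
        pos <- c(pos, rpos:(rpos + l - 1L))
        call <- c(call, read_bases[qpos:(qpos + l - 1L)])
        quals <- c(quals, qual[qpos:(qpos + l - 1L)])
        qpos <- qpos + l; rpos <- rpos + l; mdpos <- mdpos + l
      },
      "D" = {
        pos <- c(pos, rpos:(rpos + l - 1L))
        call <- c(call, rep("DEL", l))
        quals <- c(quals, rep(NA_integer_, l))
        rpos <- rpos + l; mdpos <- mdpos + l
      },
      "I" = {
        # attach to the preceding reference position (left-anchored)
        ins_at <- c(ins_at, rpos - 1L)
        ins_seq <- c(ins_seq, paste(read_bases[qpos:(qpos + l - 1L)],
                                    collapse = ""))
        qpos <- qpos + l
      },
      "S" = { qpos <- qpos + l },
      "N" = { rpos <- rpos + l; mdpos <- mdpos + l },
      "H" = , "P" = { }
    )
  }
  ord <- order(pos)
  pos <- pos[ord]; call <- call[ord]; quals <- quals[ord]
  if (!is.null(ref_seq)) {
    rb <- substring(ref_seq, pos, pos)
  } else {
    # MD-derived reference, indexed along aligned reference positions
    rel <- pos - ref_start + 1L
    rb <- ref_from_md[rel]
    rb[is.na(rb)] <- call[is.na(rb)]  # matches: reference equals the call
  }
  ins <- character(length(pos))
  m <- match(ins_at, pos)
  ok <- !is.na(m)
  ins[m[ok]] <- ins_seq[ok]
  data.frame(read_id = read_id, ref = ref_name, pos = pos, ref_base = rb,
             call = call, qual = quals, ins = ins, stringsAsFactors = FALSE)
}

#' Write / read the package's tabular formats
#'
#' Writers emit fixed headers and column orders; frequencies and
#' probabilities are serialized with 6 decimals. BED output is 0-based
#' half-open; FASTA is wrapped at 60 columns.
#'
#' @param x Table (or named character vector of sequences for FASTA).
#' @param path Output file.
#' @return `path`, invisibly (writers); a data frame (readers).
#' @name io_formats
NULL

round6 <- function(x) formatC(x, digits = 6, format = "f")

#' @rdname io_formats
#' @export
write_per_base_tsv <- function(x, path) {
  x <- x[, PER_BASE_COLS]
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io_formats
#' @export
read_per_base_tsv <- function(path) load_alignment(path)

#' @rdname io_formats
#' @export
write_event_tsv <- function(x, path) {
  x <- x[, EVENT_COLS]
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io_formats
#' @export
read_event_tsv <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(EVENT_COLS, names(tb))
  if (length(missing_cols))
    stop("event TSV lacks columns: ", paste(missing_cols, collapse = ", "))
  tb[, EVENT_COLS]
}

#' @rdname io_formats
#' @export
write_site_csv <- function(x, path) {
  y <- x[, c("ref", "pos", "base", "cov", "q_mean", "mis", "ins", "del")]
  for (cc in c("q_mean", "mis", "ins", "del"))
    y[[cc]] <- ifelse(is.na(y[[cc]]), "NA", round6(y[[cc]]))
  utils::write.csv(y, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io_formats
#' @export
read_site_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(pos = "integer", cov = "integer"))
}

#' @rdname io_formats
#' @export
write_window_csv <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1)) & names(x) != "center" &
    names(x) != "cov_min"
  y <- x
  for (cc in names(x)[num]) y[[cc]] <- ifelse(is.na(x[[cc]]), "NA",
                                              round6(x[[cc]]))
  utils::write.csv(y, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io_formats
#' @export
read_window_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(center = "integer"))
}

#' @rdname io_formats
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "sequence_set")) x <- x$records
  ss <- Biostrings::DNAStringSet(normalize_seq(x))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' @rdname io_formats
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Write modified-site calls as BED6
#'
#' 1-based site positions become 0-based half-open intervals; the BED score
#' is `round(1000 * M_wt)`.
#'
#' @param calls Call table with ref, pos, M_wt, status.
#' @param path Output file.
#' @param modified_only Keep only sites with status `"modified"`
#'   (default TRUE).
#' @export
write_calls_bed <- function(calls, path, modified_only = TRUE) {
  if (modified_only) calls <- calls[calls$status == "modified", , drop = FALSE]
  bed <- data.frame(chrom = calls$ref, start = calls$pos - 1L,
                    end = calls$pos, name = sprintf("m6A_%d", calls$pos),
                    score = round(1000 * calls$M_wt), strand = "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a provenance record for a pipeline run
#'
#' @param path Output JSON file.
#' @param config Named list of parameters (snapshot of the run's config).
#' @param seed Seed(s) used.
#' @export
write_provenance <- function(path, config, seed) {
  rec <- list(tool = "epierr",
              version = as.character(utils::packageVersion("epierr")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, config = config)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
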