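#' @useDynLib epierr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

## Normalize a character vector of sequences: uppercase, U -> T.
normalize_seq <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

seq_to_code <- function(s) {
  # A=0, C=1, G=2, T=3; anything else is an error
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  code <- match(v, DNA_ALPHABET) - 1L
  if (anyNA(code)) stop("sequence contains letters outside A/C/G/T: ",
                        paste(unique(v[is.na(code)]), collapse = ","))
  code
}

#' Design configuration for k-mer-complete synthetic sequences
#'
#' Bundles the parameters of the "curlcake"-style designer: constructs that
#' contain every k-mer (for current-intensity profiling of all 5-mer contexts)
#' while keeping self-complementary secondary structure low.
#'
#' @param k Motif length covered exhaustively (default 5; there are `4^k`
#'   k-mers, 1024 for k = 5).
#' @param n_parts Number of sequences the construct is split into for
#'   synthesis (default 4).
#' @param multiplicity How many times each k-mer is traversed by the Eulerian
#'   walk; total length is about `multiplicity * 4^k`. Default 1 (minimal
#'   superstring); 10 gives a ~10 kb design for k = 5.
#' @param part_length_tolerance Maximum relative deviation between part
#'   lengths (default 0.1).
#' @param min_stem_len Minimum perfect reverse-complement match length counted
#'   as structure by [structure_penalty()] (default 6).
#' @param min_loop_len Minimum unpaired gap between the two arms of a counted
#'   stem (default 3).
#' @param n_candidates Number of candidate superstrings scored per design
#'   (default 20).
#' @param seed Integer RNG seed; the design is fully reproducible from the
#'   config.
#' @param alphabet Ordered nucleotide letters; `U` is normalized to `T`.
#' @return An object of class `"design_config"`.
#' @export
design_config <- function(k = 5L, n_parts = 4L, multiplicity = 1L,
                          part_length_tolerance = 0.1,
                          min_stem_len = 6L, min_loop_len = 3L,
                          n_candidates = 20L, seed = 1L,
                          alphabet = c("A", "C", "G", "T")) {
  alphabet <- normalize_seq(alphabet)
  stopifnot(k >= 1, n_parts >= 1, multiplicity >= 1, min_stem_len >= 2,
            part_length_tolerance >= 0, n_candidates >= 1)
  if (length(unique(alphabet)) != 4L)
    stop("alphabet must have 4 distinct letters")
  structure(list(k = as.integer(k), n_parts = as.integer(n_parts),
                 multiplicity = as.integer(multiplicity),
                 part_length_tolerance = part_length_tolerance,
                 min_stem_len = as.integer(min_stem_len),
                 min_loop_len = as.integer(min_loop_len),
                 n_candidates = as.integer(n_candidates),
                 seed = as.integer(seed), alphabet = alphabet),
            class = "design_config")
}

#' Build a sequence containing every k-mer
#'
#' Constructs a randomized de Bruijn-style superstring by walking an Eulerian
#' circuit on the (k-1)-mer graph whose edges are the k-mers, each with the
#' requested multiplicity. Edge order is shuffled under `seed`, so different
#' seeds give different sequences and the same seed reproduces the output
#' exactly. The linearized walk of length `multiplicity * 4^k + k - 1`
#' contains every k-mer exactly `multiplicity` times.
#'
#' @param k Motif length (k >= 1).
#' @param seed Integer RNG seed.
#' @param multiplicity Copies of each k-mer edge (default 1).
#' @param alphabet Four distinct letters (default A,C,G,T).
#' @param max_kmers Refuse designs with more than this many distinct k-mers
#'   (guards against runaway `4^k`; default 65536, i.e. k <= 8).
#' @return A single character string over the alphabet.
#' @export
build_kmer_superstring <- function(k, seed = 1L, multiplicity = 1L,
                                   alphabet = c("A", "C", "G", "T"),
                                   max_kmers = 65536L) {
  alphabet <- normalize_seq(alphabet)
  stopifnot(k >= 1, multiplicity >= 1, length(unique(alphabet)) == 4L)
  if (4^k > max_kmers)
    stop("4^k = ", 4^k, " k-mers exceeds max_kmers = ", max_kmers,
         "; raise max_kmers explicitly if this design size is intended")
  set.seed(seed)
  if (k == 1L) {
    walk <- unlist(lapply(seq_len(multiplicity),
                          function(i) sample(alphabet, 4L)))
    return(paste(walk, collapse = ""))
  }
  n_nodes <- as.integer(4^(k - 1))
  # node id 1..4^(k-1) encodes a (k-1)-mer base-4; appending letter l moves to
  # node ((id-1) mod 4^(k-2)) * 4 + l
  shift <- as.integer(4^(k - 2))
  # adjacency: for each node, a shuffled stack of outgoing letters
  adj <- vector("list", n_nodes)
  for (v in seq_len(n_nodes))
    adj[[v]] <- sample(rep(1:4, multiplicity))
  nxt <- function(v, l) ((v - 1L) %% shift) * 4L + l
  n_edges <- n_nodes * 4L * multiplicity
  # Hierholzer, iterative
  start <- sample.int(n_nodes, 1L)
  stack_v <- integer(n_edges + 1L); stack_l <- integer(n_edges + 1L)
  top <- 1L; stack_v[1L] <- start; stack_l[1L] <- 0L
  circuit <- integer(n_edges + 1L); cpos <- 0L
  remaining <- lengths(adj)
  while (top > 0L) {
    v <- stack_v[top]
    if (remaining[v] > 0L) {
      l <- adj[[v]][remaining[v]]
      remaining[v] <- remaining[v] - 1L
      top <- top + 1L
      stack_v[top] <- nxt(v, l); stack_l[top] <- l
    } else {
      cpos <- cpos + 1L
      circuit[cpos] <- stack_l[top]
      top <- top - 1L
    }
  }
  letters_out <- rev(circuit[seq_len(cpos - 1L)])  # drop start marker
  # decode start node to its (k-1)-mer
  dec <- integer(k - 1L); rem <- start - 1L
  for (i in (k - 1L):1L) { dec[i] <- rem %% 4L; rem <- rem %/% 4L }
  paste(c(alphabet[dec + 1L], alphabet[letters_out]), collapse = "")
}

#' Self-complementary structure penalty
#'
#' Heuristic secondary-structure score: the number of position pairs `(i, j)`
#' with `j - i > min_loop_len + min_stem_len` at which a perfect
#' reverse-complement (Watson-Crick) match of length `>= min_stem_len` begins,
#' i.e. positions where a hairpin stem could nucleate. Deterministic; an empty
#' sequence scores 0.
#'
#' @param sequence Character string over A/C/G/T (U accepted, normalized).
#' @param min_stem_len Minimum stem length counted (>= 2, default 6).
#' @param min_loop_len Minimum gap between stem arms (default 3).
#' @return Non-negative integer score.
#' @export
structure_penalty <- function(sequence, min_stem_len = 6L, min_loop_len = 3L) {
  stopifnot(min_stem_len >= 2, min_loop_len >= 0)
  sequence <- normalize_seq(sequence)
  if (nchar(sequence) == 0L) return(0L)
  .stem_pair_count(seq_to_code(sequence), as.integer(min_stem_len),
                   as.integer(min_loop_len))
}

#' Design a k-mer-complete sequence set ("curlcakes")
#'
#' Generates `n_candidates` superstrings (seeds derived from the config seed),
#' selects the one with minimal [structure_penalty()] (ties broken by first
#' generated), and splits it into `n_parts` contiguous parts of near-equal
#' length. Consecutive parts share `k - 1` boundary letters so that every
#' k-mer of the superstring lies wholly inside at least one part.
#'
#' @param config A [design_config()].
#' @return An object of class `"sequence_set"`: list with `records` (named
#'   character vector of sequences), `superstring`, `penalty`, `config`.
#' @export
design_curlcakes <- function(config = design_config()) {
  stopifnot(inherits(config, "design_config"))
  k <- config$k
  cands <- lapply(seq_len(config$n_candidates), function(i) {
    build_kmer_superstring(k, seed = config$seed + i - 1L,
                           multiplicity = config$multiplicity,
                           alphabet = config$alphabet)
  })
  pens <- vapply(cands, structure_penalty, integer(1),
                 min_stem_len = config$min_stem_len,
                 min_loop_len = config$min_loop_len)
  best <- which.min(pens)  # first minimum wins
  s <- cands[[best]]
  L <- nchar(s)
  n <- config$n_parts
  # contiguous cover with k-1 overlap at each junction
  total <- L + (n - 1L) * (k - 1L)
  base_len <- total %/% n
  if (base_len < k)
    stop("infeasible split: part length ", base_len,
         " is shorter than k = ", k)
  lens <- rep(base_len, n)
  extra <- total - base_len * n
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  if ((max(lens) - min(lens)) / min(lens) > config$part_length_tolerance)
    stop("infeasible split: part lengths deviate by more than ",
         "part_length_tolerance = ", config$part_length_tolerance)
  parts <- character(n); a <- 1L
  for (i in seq_len(n)) {
    b <- a + lens[i] - 1L
    parts[i] <- substr(s, a, b)
    a <- b - (k - 1L) + 1L
  }
  names(parts) <- sprintf("curlcake_%d", seq_len(n))
  structure(list(records = parts, superstring = s,
                 penalty = pens[best], candidate_penalties = pens,
                 config = config),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("k-mer-complete sequence set:", length(x$records), "part(s), k =",
      x$config$k, "\n")
  cat("  part lengths:", paste(nchar(x$records), collapse = ", "), "\n")
  cat("  structure penalty of selected superstring:", x$penalty, "\n")
  invisible(x)
}

#' Count k-mer occurrences across sequences
#'
#' Sliding-window (step 1) k-mer counts within each sequence; windows never
#' span sequence boundaries. The summary is over the k-mers present.
#'
#' @param sequences Character vector of sequences, or a `sequence_set`.
#' @param k Motif length (default 5).
#' @return A data frame with columns `kmer`, `count` (sorted by kmer), with
#'   attribute `summary` = c(min, median, max) over present k-mers.
#' @export
kmer_occurrence_table <- function(sequences, k = 5L) {
  if (inherits(sequences, "sequence_set")) sequences <- sequences$records
  stopifnot(k >= 1)
  sequences <- normalize_seq(sequences)
  kmers <- unlist(lapply(sequences, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1), k:L)
  }))
  tab <- table(kmers)
  out <- data.frame(kmer = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- c(min = min(out$count),
                            median = stats::median(out$count),
                            max = max(out$count))
  out
}
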