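#' Generative error model for simulated direct RNA reads
#'
#' Parameterizes how base-called reads behave at unmodified positions and how
#' that behavior shifts when the transcribed base carries m6A: modified
#' positions are base-called with lower quality and higher mismatch and
#' deletion frequencies, and the ionic-current level of 5-mer windows covering
#' them shifts. Insertion rates are, by default, identical between conditions
#' (insertions carry no modification signal).
#'
#' @param base_quality_mean,base_quality_sd Phred quality of unmodified calls
#'   (normal draw, rounded, clamped to \[1, 40\]).
#' @param p_mismatch,p_deletion,p_insertion Per-base baseline probabilities.
#' @param quality_shift Phred delta applied at modified positions (negative
#'   lowers quality; default -3).
#' @param mismatch_delta,deletion_delta,insertion_delta Probability increments
#'   at modified positions (defaults +0.10, +0.05, 0; the zero insertion delta
#'   keeps insertions condition-independent).
#' @param substitution_profile Probabilities of the 3 non-reference letters
#'   for a mismatching call (alphabetical order among the remaining letters).
#' @param current_mean_baseline,current_sd Window current level and
#'   between-read spread, in pA.
#' @param current_shift pA delta for windows covering a modified base of a
#'   modified read (default +3).
#' @param neighbor_bleed Fractions of each delta applied at positions +/-1 and
#'   +/-2 from a modified base (default c(0.25, 0.10)); set c(0, 0) to confine
#'   the signal to the modified base.
#' @return An object of class `"error_model"`.
#' @export
error_model <- function(base_quality_mean = 12, base_quality_sd = 3,
                        p_mismatch = 0.05, p_deletion = 0.04,
                        p_insertion = 0.03,
                        quality_shift = -3,
                        mismatch_delta = 0.10, deletion_delta = 0.05,
                        insertion_delta = 0,
                        substitution_profile = c(1, 1, 1) / 3,
                        current_mean_baseline = 100, current_sd = 10,
                        current_shift = 3,
                        neighbor_bleed = c(0.25, 0.10)) {
  stopifnot(p_mismatch >= 0, p_mismatch <= 1,
            p_deletion >= 0, p_deletion <= 1,
            p_insertion >= 0, p_insertion <= 1,
            base_quality_sd >= 0, current_sd >= 0,
            length(substitution_profile) == 3,
            all(substitution_profile >= 0),
            length(neighbor_bleed) == 2, all(neighbor_bleed >= 0))
  substitution_profile <- substitution_profile / sum(substitution_profile)
  structure(list(base_quality_mean = base_quality_mean,
                 base_quality_sd = base_quality_sd,
                 p_mismatch = p_mismatch, p_deletion = p_deletion,
                 p_insertion = p_insertion,
                 quality_shift = quality_shift,
                 mismatch_delta = mismatch_delta,
                 deletion_delta = deletion_delta,
                 insertion_delta = insertion_delta,
                 substitution_profile = substitution_profile,
                 current_mean_baseline = current_mean_baseline,
                 current_sd = current_sd, current_shift = current_shift,
                 neighbor_bleed = neighbor_bleed),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("error model (unmodified baseline -> modified shift):\n")
  cat(sprintf("  quality : %g (sd %g) %+g Phred\n", x$base_quality_mean,
              x$base_quality_sd, x$quality_shift))
  cat(sprintf("  mismatch: %.3f %+.3f\n", x$p_mismatch, x$mismatch_delta))
  cat(sprintf("  deletion: %.3f %+.3f\n", x$p_deletion, x$deletion_delta))
  cat(sprintf("  insertion: %.3f %+.3f\n", x$p_insertion, x$insertion_delta))
  cat(sprintf("  current : %g pA (sd %g) %+g pA\n", x$current_mean_baseline,
              x$current_sd, x$current_shift))
  cat(sprintf("  neighbor bleed: %.2f at +/-1, %.2f at +/-2\n",
              x$neighbor_bleed[1], x$neighbor_bleed[2]))
  invisible(x)
}

## Per-position effective delta weights for a set of modified positions:
## 1 at the position, neighbor_bleed[1] at +/-1, neighbor_bleed[2] at +/-2
## (maximum over overlapping modified positions).
.bleed_weights <- function(L, modified_positions, neighbor_bleed) {
  w <- numeric(L)
  if (length(modified_positions) == 0) return(w)
  for (off in -2:2) {
    p <- modified_positions + off
    p <- p[p >= 1 & p <= L]
    val <- if (off == 0) 1 else neighbor_bleed[abs(off)]
    w[p] <- pmax(w[p], val)
  }
  w
}
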