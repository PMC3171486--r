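# Motif-level accuracy measures: CompareACE similarity with length-adjusted
# sensitivity (mSN) and specificity (mSP), and the top-3 success rate.

#' Motif-level accuracy of an identified motif against an expected motif
#'
#' The two PWMs are aligned with [compare_ace()]. From the best alignment,
#' TP is the number of overlapping columns, FP the identified-only columns
#' and FN the expected-only columns, so TP + FN equals the expected width
#' and TP + FP the identified width. With m the CompareACE similarity
#' (negative values clamped to 0), the motif-level sensitivity and
#' specificity are mSN = m * TP / (TP + FN) and mSP = m * TP / (TP + FP).
#' If no admissible alignment exists all scores are 0.
#'
#' @param expected,identified PWMs (matrices, columns A,C,G,T) or
#'   `refined_motif` objects.
#' @param min_overlap Minimum alignment overlap (default 6).
#' @return One-row tibble with columns `m`, `TP`, `FP`, `FN`, `mSN`, `mSP`.
#' @export
accuracy_scores <- function(expected, identified, min_overlap = 6) {
  pe <- as_pwm(expected)
  pi_ <- as_pwm(identified)
  al <- tryCatch(compare_ace(pe, pi_, min_overlap), error = function(e) NULL)
  if (is.null(al) || is.na(al$offset)) {
    return(tibble::tibble(m = 0, TP = 0L, FP = 0L, FN = 0L, mSN = 0, mSP = 0))
  }
  TP <- al$overlap
  FP <- nrow(pi_) - TP
  FN <- nrow(pe) - TP
  m <- max(0, al$m)
  tibble::tibble(m = al$m, TP = TP, FP = FP, FN = FN,
                 mSN = m * TP / (TP + FN), mSP = m * TP / (TP + FP))
}

#' Top-3 success rate over a collection of benchmark cases
#'
#' For each case, up to three candidate motifs are compared to the expected
#' motif and the best-scoring one is taken as the identified motif; the case
#' is a success when that best similarity reaches `cutoff`. Accuracy scores
#' of the identified motifs are averaged over the cases.
#'
#' @param cases List of cases; each case is a list with elements `expected`
#'   (PWM) and `found` (list of up to 3 PWMs).
#' @param cutoff CompareACE similarity required for success.
#' @param min_overlap Minimum alignment overlap (default 6).
#' @return List with `success_rate` (fraction of successes), `per_case`
#'   (tibble: case, best_m, success, mSN, mSP) and `mean_mSN`/`mean_mSP`.
#' @export
success_rate <- function(cases, cutoff, min_overlap = 6) {
  if (length(cases) == 0) stop("no cases supplied")
  per_case <- dplyr::bind_rows(lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    found <- cs$found
    if (length(found) == 0) {
      return(tibble::tibble(case = i, best_m = -Inf, success = FALSE,
                            mSN = 0, mSP = 0))
    }
    scores <- lapply(found, function(f) {
      accuracy_scores(cs$expected, f, min_overlap)
    })
    ms <- vapply(scores, function(s) s$m, numeric(1))
    best <- which.max(ms)
    tibble::tibble(case = i, best_m = ms[best],
                   success = ms[best] >= cutoff,
                   mSN = scores[[best]]$mSN, mSP = scores[[best]]$mSP)
  }))
  list(success_rate = mean(per_case$success), per_case = per_case,
       mean_mSN = mean(per_case$mSN), mean_mSP = mean(per_case$mSP))
}
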