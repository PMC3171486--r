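# Stage 5: PWM-PWM similarity (CompareACE-style) and greedy redundancy
# removal.

#' CompareACE-style similarity between two PWMs
#'
#' For every ungapped offset of `b` relative to `a` with at least
#' `min_overlap` overlapping columns, and for `b` in both orientations
#' (as given and reverse-complemented), the Pearson correlation between the
#' two aligned probability blocks (flattened 4 x overlap vectors) is
#' computed; the maximum over all alignments is returned. A zero-variance
#' block scores 0. Ties are resolved deterministically (same orientation
#' before reverse complement, offsets in increasing order).
#'
#' @param a,b PWMs (row-stochastic matrices, columns A,C,G,T) or
#'   `refined_motif` objects.
#' @param min_overlap Minimum overlapping columns (default 6).
#' @return Tibble with columns `m` (similarity in \[-1, 1\]), `offset`
#'   (start of `b` relative to `a`, in columns), `orientation`
#'   (`"same"`/`"revcomp"`) and `overlap`.
#' @export
compare_ace <- function(a, b, min_overlap = 6) {
  pa <- as_pwm(a)
  pb <- as_pwm(b)
  wa <- nrow(pa)
  wb <- nrow(pb)
  if (wa < min_overlap || wb < min_overlap) {
    stop("PWM width below the minimum overlap of ", min_overlap)
  }
  best <- NULL
  for (orient in c("same", "revcomp")) {
    pbb <- if (orient == "same") pb else pwm_revcomp(pb)
    for (d in seq(-(wb - min_overlap), wa - min_overlap)) {
      a0 <- max(1L, 1L + d)
      a1 <- min(wa, wb + d)
      ov <- a1 - a0 + 1L
      if (ov < min_overlap) next
      blk_a <- as.vector(pa[a0:a1, , drop = FALSE])
      blk_b <- as.vector(pbb[(a0 - d):(a1 - d), , drop = FALSE])
      r <- if (stats::sd(blk_a) == 0 || stats::sd(blk_b) == 0) 0
      else stats::cor(blk_a, blk_b)
      if (is.null(best) || r > best$m) {
        best <- list(m = r, offset = d, orientation = orient, overlap = ov)
      }
    }
  }
  if (is.null(best)) {
    return(tibble::tibble(m = 0, offset = NA_integer_,
                          orientation = NA_character_, overlap = 0L))
  }
  tibble::tibble(m = best$m, offset = best$offset,
                 orientation = best$orientation, overlap = best$overlap)
}

as_pwm <- function(x) {
  if (inherits(x, "refined_motif")) return(x$pwm)
  if (is.matrix(x) && ncol(x) == 4) return(x)
  stop("expected a PWM matrix (4 columns) or a refined_motif")
}

#' Reverse complement of a PWM
#'
#' Reverses the position order and swaps complementary columns
#' (A with T, C with G).
#'
#' @param pwm Row-stochastic matrix with columns A,C,G,T.
#' @return The reverse-complemented PWM.
#' @export
pwm_revcomp <- function(pwm) {
  out <- pwm[rev(seq_len(nrow(pwm))), 4:1, drop = FALSE]
  colnames(out) <- BASES
  out
}

#' Greedy redundancy removal among refined motifs
#'
#' Motifs are sorted by MAP score in descending order (ties broken by
#' lexicographic consensus). The highest-scoring motif is emitted, every
#' remaining motif whose CompareACE similarity to it exceeds `cutoff` is
#' discarded, and the procedure repeats on the remainder until the list is
#' empty. The output therefore keeps the global best motif, is pairwise at
#' most `cutoff` similar and preserves emission (MAP) order.
#'
#' @param motifs List of `refined_motif` objects.
#' @param cutoff Similarity cutoff (default 0.6).
#' @param min_overlap Minimum alignment overlap passed to [compare_ace()].
#' @return Filtered list of `refined_motif` objects.
#' @export
remove_redundant <- function(motifs, cutoff = 0.6, min_overlap = 6) {
  if (length(motifs) == 0) return(motifs)
  maps <- vapply(motifs, function(m) m$map_score, numeric(1))
  cons <- vapply(motifs, function(m) m$source_consensus %||% m$consensus,
                 character(1))
  pool <- motifs[order(-maps, cons)]
  out <- list()
  while (length(pool) > 0) {
    head_m <- pool[[1]]
    out[[length(out) + 1L]] <- head_m
    pool <- pool[-1]
    if (length(pool) > 0) {
      sim <- vapply(pool, function(m) compare_ace(head_m, m, min_overlap)$m,
                    numeric(1))
      pool <- pool[sim <= cutoff]
    }
  }
  out
}
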