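# Stage 1: enumeration of the gapped two-triplet core space, instance
# counting, enrichment statistics and primary core selection.
#
# Core consensuses have the shape UVW-N^g-XYZ (two specified triplets
# separated by g unspecified positions, g = 0..14). Counting for the whole
# space is done from per-gap 64x64 trimer-pair tables built in one pass over
# the encoded sequences, which is equivalent to scanning every core
# separately (property-tested against the brute-force scanner).

#' Enumerate the gapped core-consensus space
#'
#' All consensuses of the form UVW-N^g-XYZ with U..Z in {A,C,G,T} and gap
#' g = 0..`max_gap`, ordered by gap then lexicographically by pattern. With
#' the default `max_gap = 14` this is the full search space of
#' 61,440 (= 4^6 * 15) core motifs, spanning at most 20 nt with 6
#' informative positions.
#'
#' @param max_gap Maximum number of unspecified (N) positions between the
#'   two triplets (default 14).
#' @return Tibble with columns `pattern`, `gap`, `span`.
#' @examples
#' nrow(enumerate_core_space(0))   # 4096 contiguous 6-mers
#' @export
enumerate_core_space <- function(max_gap = 14) {
  stopifnot(max_gap >= 0)
  tri <- trimer_strings()  # already in lexicographic order
  left <- rep(tri, each = 64)
  right <- rep(tri, times = 64)
  dplyr::bind_rows(lapply(0:max_gap, function(g) {
    tibble::tibble(pattern = paste0(left, strrep("N", g), right),
                   gap = g, span = 6L + g)
  }))
}

#' Scan a sequence set for instances of an IUPAC consensus
#'
#' Finds every occurrence of `pattern` in `seqs` with at most `max_mismatch`
#' mismatches at informative (non-N) positions; N positions in the pattern
#' match any base for free, while an N in the sequence never satisfies a
#' specified pattern position. Both strands are scanned unless the pattern is
#' self-reverse-complementary, in which case only the forward strand is used
#' so that palindromic matches are not double counted. Overlapping
#' occurrences are all reported.
#'
#' @param seqs Sequence set tibble.
#' @param pattern IUPAC consensus string.
#' @param max_mismatch Maximum mismatches at informative positions
#'   (default 0).
#' @return Tibble with columns `sequence_id`, `offset` (0-based start on the
#'   forward strand), `strand` (`"+"`/`"-"`), `site` (matched substring in
#'   motif orientation) and `mismatches`.
#' @export
scan_instances <- function(seqs, pattern, max_mismatch = 0) {
  pattern <- toupper(pattern)
  if (nchar(pattern) == 0) stop("motif pattern has zero span")
  stopifnot(max_mismatch >= 0)
  rc <- reverse_complement(pattern)
  both <- pattern != rc
  hits <- scan_iupac_cpp(seqs$seq, pattern, rc, as.integer(max_mismatch), both)
  span <- nchar(pattern)
  seq_chr <- seqs$seq[hits$seq_index]
  sub <- substr(seq_chr, hits$offset + 1L, hits$offset + span)
  minus <- hits$strand_code == 1L
  site <- sub
  if (any(minus)) site[minus] <- reverse_complement(sub[minus])
  tibble::tibble(
    sequence_id = seqs$id[hits$seq_index],
    offset = hits$offset,
    strand = ifelse(minus, "-", "+"),
    site = site,
    mismatches = hits$mismatches
  )
}

#' Count instances of an IUPAC consensus in a sequence set
#'
#' The number of (sequence, offset, strand) matches under the scanning rules
#' of [scan_instances()].
#'
#' @inheritParams scan_instances
#' @return Integer count.
#' @examples
#' s <- seq_set("s1", "ACGTAGACGTAG")
#' count_instances(s, "ACGTAG")  # 2
#' @export
count_instances <- function(seqs, pattern, max_mismatch = 0) {
  nrow(scan_instances(seqs, pattern, max_mismatch))
}

#' Enrichment statistics for foreground vs background counts
#'
#' Given an observed foreground instance count C and a background count N,
#' the expected foreground count under a uniform instance distribution is
#' E = N * L_fg / L_bg, where L_fg and L_bg are the total sequence lengths.
#' Fold enrichment is F = C / E and the significance is scored with a
#' binomial z-approximation Z = (C - E) / sqrt(E * (1 - L_fg / L_bg)).
#' Degenerate cases: when E = 0, F is +Inf if C > 0 and 1 otherwise, and Z
#' is 0; when C = E, Z = 0 exactly.
#'
#' @param C Observed foreground count(s).
#' @param N_bg Background count(s).
#' @param L_fg,L_bg Total foreground/background lengths in nucleotides.
#' @return Tibble with columns `C`, `N_bg`, `E`, `fold`, `zscore`
#'   (vectorized over `C`/`N_bg`).
#' @examples
#' enrichment_stats(10, 20, 1000, 4000)  # E = 5, fold = 2, Z ~ 2.582
#' @export
enrichment_stats <- function(C, N_bg, L_fg, L_bg) {
  if (any(C < 0) || any(N_bg < 0) || L_fg <= 0 || L_bg <= 0) {
    stop("counts must be non-negative and lengths positive")
  }
  E <- N_bg * L_fg / L_bg
  fold <- ifelse(E > 0, C / E, ifelse(C > 0, Inf, 1))
  p <- L_fg / L_bg
  v <- E * (1 - p)
  if (p >= 1 && any(E > 0)) {
    warning("foreground length >= background length: z-scores undefined, set to 0")
  }
  z <- ifelse(E > 0 & v > 0, (C - E) / sqrt(v), 0)
  z[C == E] <- 0
  tibble::tibble(C = C, N_bg = N_bg, E = E, fold = fold, zscore = z)
}

# --- fast whole-space counting via trimer-pair tables ----------------------

# One 64x64 forward-strand count matrix per gap 0..max_gap: entry [t1, t2]
# is the number of positions where trimer t1 is followed, g positions later,
# by trimer t2. Sequences are separated by runs of NA so windows never span
# a boundary; windows containing N drop out as NA.
pair_tables <- function(seqs, gaps = 0:14) {
  sep <- rep(NA_integer_, max(gaps) + 6L)
  enc <- unlist(lapply(seqs$seq, function(s) c(encode_bases(s), sep)),
                use.names = FALSE)
  tc <- trimer_codes(enc)
  n <- length(tc)
  lapply(gaps, function(g) {
    shift <- 3L + g
    if (n <= shift) return(matrix(0, 64, 64))
    a <- tc[1:(n - shift)]
    b <- tc[(1L + shift):n]
    idx <- a * 64L + b + 1L
    idx <- idx[!is.na(idx)]
    matrix(tabulate(idx, nbins = 4096L), nrow = 64, byrow = TRUE)
  })
}

# Both-strand count matrix for all cores of one gap, with palindromic cores
# (t2 == revcomp trimer of t1) counted forward-only.
combine_strands <- function(Tfwd) {
  rcidx <- rc3_perm() + 1L
  Trc <- t(Tfwd)[rcidx, rcidx]
  M <- Tfwd + Trc
  pal <- cbind(1:64, rcidx)  # rows where t2 = rc3(t1)
  M[pal] <- M[pal] / 2
  M
}

# Enrichment table for the complete core space.
core_enrichment <- function(fg, bg, max_gap = 14) {
  core_enrichment_impl(pair_tables(fg, gaps = 0:max_gap),
                       pair_tables(bg, gaps = 0:max_gap),
                       total_length(fg), total_length(bg), max_gap)
}

core_enrichment_impl <- function(tab_fg, tab_bg, L_fg, L_bg, max_gap) {
  tri <- trimer_strings()
  left <- rep(tri, times = 64)   # column-major flatten: t1 varies fastest
  right <- rep(tri, each = 64)
  dplyr::bind_rows(lapply(0:max_gap, function(g) {
    C <- as.vector(combine_strands(tab_fg[[g + 1]]))
    N <- as.vector(combine_strands(tab_bg[[g + 1]]))
    st <- enrichment_stats(C, N, L_fg, L_bg)
    dplyr::bind_cols(
      tibble::tibble(pattern = paste0(left, strrep("N", g), right), gap = g),
      st
    )
  }))
}

#' Select the primary core motifs by enrichment
#'
#' Evaluates fold enrichment and z-score for the entire gapped core space
#' (all UVW-N^g-XYZ consensuses, both strands), keeps cores with fold
#' enrichment at least `min_fold`, ranks them by z-score in descending order
#' (ties broken by lexicographically smaller pattern) and returns the first
#' `top_k`. If fewer than `top_k` cores survive the fold filter, all
#' survivors are returned.
#'
#' @param fg,bg Foreground and background sequence sets (non-empty).
#' @param min_fold Minimal fold enrichment (default 1.2).
#' @param top_k Number of primary cores to retain (default 50).
#' @param max_gap Maximum gap length (default 14).
#' @return Tibble of selected cores with columns `pattern`, `gap`, `C`,
#'   `N_bg`, `E`, `fold`, `zscore`, sorted by decreasing z-score.
#' @export
select_primary_cores <- function(fg, bg, min_fold = 1.2, top_k = 50,
                                 max_gap = 14) {
  if (nrow(fg) == 0 || nrow(bg) == 0) {
    stop("foreground and background sequence sets must be non-empty")
  }
  stats <- core_enrichment(fg, bg, max_gap)
  stats <- dplyr::filter(stats, .data$fold >= min_fold)
  stats <- dplyr::arrange(stats, dplyr::desc(.data$zscore), .data$pattern)
  utils::head(stats, top_k)
}
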