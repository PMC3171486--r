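# Shared fixtures and an independent brute-force oracle for instance
# counting. The oracle deliberately re-derives the IUPAC tables and scanning
# rules from scratch (plain R string operations) so it shares no code with
# the package's counting paths.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", M = "K", R = "Y",
                 W = "W", S = "S", Y = "R", K = "M", V = "B", H = "D",
                 D = "H", B = "V", N = "N")

oracle_revcomp <- function(p) {
  paste(rev(unname(ORACLE_COMP[strsplit(p, "")[[1]]])), collapse = "")
}

# mismatches of pattern against one window; sequence N never matches a
# specified position; pattern N is free
oracle_mismatches <- function(window, pchars) {
  wchars <- strsplit(window, "")[[1]]
  mm <- 0L
  for (j in seq_along(pchars)) {
    if (pchars[j] == "N") next
    if (!(wchars[j] %in% ORACLE_SETS[[pchars[j]]]) || wchars[j] == "N") {
      mm <- mm + 1L
    }
  }
  mm
}

oracle_count_one <- function(seq, pattern, max_mismatch) {
  span <- nchar(pattern)
  n <- nchar(seq)
  if (n < span) return(0L)
  pats <- list(strsplit(pattern, "")[[1]])
  if (pattern != oracle_revcomp(pattern)) {
    pats <- c(pats, list(strsplit(oracle_revcomp(pattern), "")[[1]]))
  }
  cnt <- 0L
  for (i in 1:(n - span + 1L)) {
    window <- substr(seq, i, i + span - 1L)
    for (p in pats) {
      if (oracle_mismatches(window, p) <= max_mismatch) cnt <- cnt + 1L
    }
  }
  cnt
}

oracle_count <- function(seqs, pattern, max_mismatch = 0) {
  sum(vapply(seqs$seq, oracle_count_one, integer(1), pattern, max_mismatch))
}

random_seqs <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

random_seq_set <- function(n, len, seed = NULL, prefix = "s") {
  seq_set(paste0(prefix, seq_len(n)), random_seqs(n, len, seed))
}

# one-hot-by-code PWM of an IUPAC consensus (uniform over the code's bases)
pwm_from_consensus <- function(consensus) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  pwm <- t(vapply(chars, function(cd) {
    v <- as.numeric(c("A", "C", "G", "T") %in% ORACLE_SETS[[cd]])
    v / sum(v)
  }, numeric(4)))
  colnames(pwm) <- c("A", "C", "G", "T")
  rownames(pwm) <- NULL
  pwm
}

# near-deterministic PWM with probability `p` on the consensus base
sharp_pwm <- function(consensus, p = 0.97) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  pwm <- t(vapply(chars, function(b) {
    v <- rep((1 - p) / 3, 4)
    v[match(b, c("A", "C", "G", "T"))] <- p
    v
  }, numeric(4)))
  colnames(pwm) <- c("A", "C", "G", "T")
  rownames(pwm) <- NULL
  pwm
}

# instance tibble for direct MAP-score tests
instance_tbl <- function(sites, context = "") {
  tibble::tibble(site = sites,
                 left_context = rep(context, length(sites)))
}

# minimal refined_motif stand-in for redundancy tests
fake_motif <- function(pwm, map, consensus = "X") {
  structure(list(consensus = consensus, source_consensus = consensus,
                 width = nrow(pwm), pwm = pwm, instances = NULL,
                 x_m = 10L, map_score = map, fold = NA_real_,
                 zscore = NA_real_),
            class = "refined_motif")
}
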