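# IUPAC nucleotide ambiguity codes and low-level sequence encoding shared by
# the consensus enumeration, scanning and refinement stages.

BASES <- c("A", "C", "G", "T")

# Canonical code order: the four bases first, then two-base, three-base codes
# and N. Used wherever a deterministic enumeration over codes is needed.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

IUPAC_ALPHABET <- names(IUPAC_CODES)

NON_N_CODES <- IUPAC_ALPHABET[IUPAC_ALPHABET != "N"]

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
  V = "B", H = "D", D = "H", B = "V", N = "N"
)

# codes consistent with a base = codes whose nucleotide set contains it;
# exactly 8 per base, the base itself listed first.
consistent_codes <- function(base) {
  stopifnot(base %in% BASES)
  codes <- IUPAC_ALPHABET[vapply(IUPAC_CODES, function(s) base %in% s, logical(1))]
  c(base, setdiff(codes, base))
}

# 4 x length(codes) indicator matrix: entry [b, j] is 1 when base b belongs
# to the nucleotide set of codes[j].
code_indicator <- function(codes) {
  m <- vapply(codes, function(cd) as.numeric(BASES %in% IUPAC_CODES[[cd]]),
              numeric(4))
  dimnames(m) <- list(BASES, codes)
  m
}

#' Reverse complement of a DNA or IUPAC consensus string
#'
#' Complements every position using the full IUPAC complement table
#' (`R` <-> `Y`, `S` <-> `S`, `N` <-> `N`, ...) and reverses the result, so it
#' applies equally to plain sequences and to degenerate consensus patterns.
#' Applying it twice returns the input.
#'
#' @param x Character vector of sequences over the 15 IUPAC codes
#'   (case-insensitive).
#' @return Character vector of the same length with each element
#'   reverse-complemented (uppercase).
#' @examples
#' reverse_complement("ACGTAG")
#' reverse_complement("CGGNNNNNNNNNNNCCG")  # self-reverse-complementary
#' @export
reverse_complement <- function(x) {
  x <- toupper(x)
  bad <- grepl(paste0("[^", paste(IUPAC_ALPHABET, collapse = ""), "]"), x)
  if (any(bad)) {
    stop("sequence contains characters outside the IUPAC alphabet: ",
         x[bad][1])
  }
  comp <- chartr(paste(names(IUPAC_COMPLEMENT), collapse = ""),
                 paste(IUPAC_COMPLEMENT, collapse = ""), x)
  vapply(comp, function(s) {
    if (nchar(s) == 0) return("")
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

is_palindromic <- function(pattern) {
  pattern == reverse_complement(pattern)
}

# Encode a sequence as integer base codes 0..3 (A,C,G,T); anything else
# (i.e. N after normalization) becomes NA.
encode_bases <- function(seq) {
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt("A")] <- 0L
  lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L
  lut[utf8ToInt("T")] <- 3L
  if (nchar(seq) == 0) return(integer(0))
  lut[utf8ToInt(seq)]
}

decode_bases <- function(codes) {
  paste(BASES[codes + 1L], collapse = "")
}

# trimer code 0..63 from integer base codes at consecutive positions
trimer_codes <- function(enc) {
  n <- length(enc)
  if (n < 3) return(integer(0))
  16L * enc[1:(n - 2)] + 4L * enc[2:(n - 1)] + enc[3:n]
}

# reverse complement permutation on trimer codes
rc3_perm <- function() {
  t <- 0:63
  b1 <- t %/% 16L
  b2 <- (t %/% 4L) %% 4L
  b3 <- t %% 4L
  16L * (3L - b3) + 4L * (3L - b2) + (3L - b1)
}

# trimer code -> string, in code order (lexicographic)
trimer_strings <- function() {
  t <- 0:63
  paste0(BASES[t %/% 16L + 1L], BASES[(t %/% 4L) %% 4L + 1L], BASES[t %% 4L + 1L])
}
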