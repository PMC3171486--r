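# Stage 4: refinement of extended consensuses into PWMs under a maximum a
# posteriori objective with an order-3 Markov background.
#
# The modified MAP score of a motif with x_m instances of width w is
#   ln(w) * (ln(x_m)/w) * [ sum_ij p_ij ln p_ij - (1/x_m) sum_s ln p0(s) ]
# where p_ij are raw instance frequencies and p0(s) is the probability of a
# site under the background Markov model given its 3 preceding bases.
# Natural logarithms throughout. Instances are scanned with one mismatch and
# pruned by a single leave-one-out pass: an instance is preserved iff the
# score over all instances exceeds the score with that instance removed.

#' Fit a Markov background model from sequences
#'
#' Conditional nucleotide probabilities of each order from 0 to `order`,
#' estimated from k-mer counts over both strands of the background with a
#' pseudocount: p(b | context) = (count(context+b) + pc) /
#' (count(context+any) + 4 pc). Windows containing N are skipped. The
#' lower-order tables serve as back-off near sequence starts.
#'
#' @param bg Background sequence set.
#' @param order Markov order (default 3).
#' @param pseudocount Added per k-mer count (default 1).
#' @return A `markov_background` object.
#' @export
fit_markov_background <- function(bg, order = 3, pseudocount = 1.0) {
  stopifnot(order >= 0)
  enc <- lapply(bg$seq, encode_bases)
  enc <- c(enc, lapply(enc, function(e) rev(3L - e)))  # both strands
  logp <- vector("list", order + 1L)
  any_counts <- FALSE
  for (k in seq_len(order + 1L)) {
    counts <- numeric(4L^k)
    for (e in enc) {
      n <- length(e)
      if (n < k) next
      code <- e[1:(n - k + 1L)]
      if (k > 1) {
        for (j in 2:k) code <- code * 4L + e[j:(n - k + j)]
      }
      code <- code[!is.na(code)]
      if (length(code)) counts <- counts + tabulate(code + 1L, nbins = 4L^k)
    }
    if (sum(counts) > 0) any_counts <- TRUE
    cnt <- matrix(counts, ncol = 4L, byrow = TRUE)  # 4^(k-1) contexts x 4
    denom <- rowSums(cnt) + 4 * pseudocount
    logp[[k]] <- log((cnt + pseudocount) / denom)
  }
  if (!any_counts) stop("background has no A/C/G/T content")
  structure(list(order = as.integer(order), pseudocount = pseudocount,
                 logp = logp),
            class = "markov_background")
}

#' An exactly uniform Markov background
#'
#' Every conditional probability is 1/4 at every order. Useful for synthetic
#' data and for tests where the MAP score has a closed form.
#'
#' @param order Markov order (default 3).
#' @return A `markov_background` object.
#' @export
uniform_background <- function(order = 3) {
  logp <- lapply(seq_len(order + 1L), function(k) {
    matrix(log(0.25), nrow = 4L^(k - 1L), ncol = 4L)
  })
  structure(list(order = as.integer(order), pseudocount = 0, logp = logp),
            class = "markov_background")
}

#' @export
print.markov_background <- function(x, ...) {
  cat("Markov background model, order", x$order,
      "| pseudocount", x$pseudocount, "\n")
  invisible(x)
}

#' Log-probability of a site under the background model
#'
#' Natural log of the probability of generating `site` from the background
#' Markov model, conditioning each base on up to `order` preceding bases.
#' `left_context` supplies the bases preceding the site in its source
#' sequence; when fewer than `order` are available (near a sequence start),
#' the model backs off to the highest available order position by position.
#'
#' @param bgm A `markov_background` object.
#' @param site Site string over A/C/G/T.
#' @param left_context Up to `order` bases preceding the site (default
#'   `""`).
#' @return Log-probability (natural log).
#' @examples
#' log_p0(uniform_background(), "ACGTA")  # 5 * log(0.25)
#' @export
log_p0 <- function(bgm, site, left_context = "") {
  if (grepl("N", site, fixed = TRUE)) {
    stop("site contains N; such instances are excluded before scoring")
  }
  full <- encode_bases(paste0(left_context, site))
  if (anyNA(full)) stop("site/context contain non-ACGT characters")
  cl <- nchar(left_context)
  w <- nchar(site)
  o <- bgm$order
  lp <- 0
  for (i in seq_len(w)) {
    avail <- min(o, cl + i - 1L)
    pos <- cl + i
    ctx <- 0L
    if (avail > 0) {
      for (j in (pos - avail):(pos - 1L)) ctx <- ctx * 4L + full[j]
    }
    lp <- lp + bgm$logp[[avail + 1L]][ctx + 1L, full[pos] + 1L]
  }
  lp
}

# vectorized log_p0 for many instances; falls back to the scalar version for
# instances whose left context is shorter than the model order
log_p0_batch <- function(bgm, sites, contexts) {
  n <- length(sites)
  if (n == 0) return(numeric(0))
  o <- bgm$order
  out <- numeric(n)
  cl <- nchar(contexts)
  short <- which(cl < o)
  for (i in short) out[i] <- log_p0(bgm, sites[i], contexts[i])
  full <- which(cl == o)
  if (length(full)) {
    w <- nchar(sites[full][1])
    M <- site_code_matrix(paste0(contexts[full], sites[full]), seq_len(o + w)) - 1L
    if (any(M < 0)) stop("sites/contexts contain non-ACGT characters")
    LP <- bgm$logp[[o + 1L]]
    lp <- numeric(length(full))
    for (i in seq_len(w)) {
      pos <- o + i
      ctx <- 0L
      if (o > 0) for (j in (pos - o):(pos - 1L)) ctx <- ctx * 4L + M[, j]
      lp <- lp + LP[cbind(ctx + 1L, M[, pos] + 1L)]
    }
    out[full] <- lp
  }
  out
}

#' Modified MAP score of a motif instance set
#'
#' The MDscan-style maximum a posteriori objective, multiplied by ln(w) to
#' account for motif length (see the package vignette for the exact form).
#' Position frequencies are raw (no pseudocount), so that for x_m identical
#' sites on a uniform background the score equals
#' ln(w) * ln(x_m) * ln(4) exactly.
#'
#' @param instances Instance tibble with columns `site` and `left_context`
#'   (as produced by [scan_instances()] plus context annotation, or built
#'   directly).
#' @param bgm A `markov_background` object.
#' @return The modified MAP score (numeric scalar).
#' @export
map_score <- function(instances, bgm) {
  x <- nrow(instances)
  if (x == 0) stop("MAP score undefined for zero instances")
  w <- nchar(instances$site[1])
  if (!all(nchar(instances$site) == w)) stop("sites have unequal widths")
  lnp0 <- instances[["lnp0"]] %||%
    log_p0_batch(bgm, instances$site,
                 instances[["left_context"]] %||% rep("", x))
  M <- site_code_matrix(instances$site, seq_len(w))
  if (any(M == 0)) stop("sites contain N")
  cnt <- position_counts(M, w)
  map_from_parts(sum(xlogx(cnt)), sum(lnp0), x, w)
}

xlogx <- function(v) ifelse(v > 0, v * log(v), 0)

position_counts <- function(M, w) {
  t(vapply(seq_len(w), function(r) tabulate(M[, r], nbins = 4L), numeric(4)))
}

map_from_parts <- function(sum_clogc, S0, x, w) {
  if (x == 0) return(-Inf)
  ent <- sum_clogc / x - w * log(x)
  log(w) * (log(x) / w) * (ent - S0 / x)
}

#' Leave-one-out pruning of motif instances
#'
#' Computes the modified MAP score over all instances and, for each
#' instance, the score with that instance removed (each test against the
#' full set, a single pass). An instance is preserved iff the full-set score
#' strictly exceeds the leave-one-out score. The score of an empty set is
#' -Inf, so a lone instance is always preserved.
#'
#' @inheritParams map_score
#' @return List with `preserved` (filtered instance tibble), `keep`
#'   (logical vector), `map_all` (scalar) and `map_minus` (per-instance
#'   leave-one-out scores).
#' @export
prune_instances <- function(instances, bgm) {
  x <- nrow(instances)
  if (x == 0) stop("no instances to prune")
  w <- nchar(instances$site[1])
  lnp0 <- instances[["lnp0"]] %||%
    log_p0_batch(bgm, instances$site,
                 instances[["left_context"]] %||% rep("", x))
  M <- site_code_matrix(instances$site, seq_len(w))
  if (any(M == 0)) stop("sites contain N")
  cnt <- position_counts(M, w)
  sum_clogc <- sum(xlogx(cnt))
  S0 <- sum(lnp0)
  map_all <- map_from_parts(sum_clogc, S0, x, w)
  if (x == 1) {
    map_minus <- -Inf
  } else {
    # removing instance i changes one count per position:
    # c -> c - 1 at (position r, base M[i, r])
    G <- matrix(0, w, 4)
    pos_counts_pos <- cnt > 0
    G[pos_counts_pos] <- xlogx(cnt[pos_counts_pos]) -
      xlogx(cnt[pos_counts_pos] - 1)
    vals <- G[cbind(rep(seq_len(w), times = x), as.vector(t(M)))]
    delta <- rowSums(matrix(vals, nrow = x, byrow = TRUE))
    x1 <- x - 1
    ent_minus <- (sum_clogc - delta) / x1 - w * log(x1)
    map_minus <- log(w) * (log(x1) / w) * (ent_minus - (S0 - lnp0) / x1)
  }
  keep <- map_all > map_minus
  list(preserved = instances[keep, , drop = FALSE], keep = keep,
       map_all = map_all, map_minus = map_minus)
}

#' Refine an extended consensus into a PWM motif
#'
#' Trims flanking N columns from the consensus, scans the foreground for
#' instances with up to `scan_mismatch` mismatches, drops instances whose
#' site or 3-base left context contains N, prunes uninformative instances by
#' leave-one-out MAP comparison and merges the preserved instances into a
#' position weight matrix (pseudocount 0.25 per cell). The stored MAP score
#' is recomputed on the preserved set.
#'
#' @param fg Foreground sequence set.
#' @param core Extended consensus (may carry flanking N).
#' @param bgm `markov_background` fitted from the background sequences.
#' @param scan_mismatch Mismatches allowed when scanning (default 1).
#' @return A `refined_motif` object, or `NULL` (with a warning) when the
#'   consensus has no instances in the foreground.
#' @export
refine_motif <- function(fg, core, bgm, scan_mismatch = 1) {
  pattern <- gsub("^N+|N+$", "", toupper(core))
  if (nchar(pattern) == 0) stop("consensus is all N")
  inst <- scan_instances(fg, pattern, scan_mismatch)
  inst <- add_left_context(inst, fg, nchar(pattern), bgm$order)
  ok <- !grepl("N", inst$site, fixed = TRUE) &
    !grepl("N", inst$left_context, fixed = TRUE)
  inst <- inst[ok, , drop = FALSE]
  if (nrow(inst) == 0) {
    warning("no instances of '", pattern, "' in the foreground; motif dropped")
    return(NULL)
  }
  inst$lnp0 <- log_p0_batch(bgm, inst$site, inst$left_context)
  pr <- prune_instances(inst, bgm)
  kept <- pr$preserved
  if (nrow(kept) == 0) {
    warning("leave-one-out pruning removed all instances of '", pattern,
            "'; keeping the full scanned set")
    kept <- inst
  }
  refined_motif(kept, pattern, bgm)
}

# context of up to `order` bases preceding each instance on its own strand
add_left_context <- function(inst, seqs, span, order = 3) {
  seq_chr <- seqs$seq[match(inst$sequence_id, seqs$id)]
  plus <- inst$strand == "+"
  ctx <- character(nrow(inst))
  if (any(plus)) {
    start <- pmax(1L, inst$offset[plus] - order + 1L)
    ctx[plus] <- substr(seq_chr[plus], start, inst$offset[plus])
  }
  if (any(!plus)) {
    after <- substr(seq_chr[!plus], inst$offset[!plus] + span + 1L,
                    inst$offset[!plus] + span + order)
    ctx[!plus] <- reverse_complement(after)
  }
  inst$left_context <- ctx
  inst
}

# construct a refined_motif from a preserved instance set
refined_motif <- function(instances, source_consensus, bgm,
                          pseudocount = 0.25) {
  x <- nrow(instances)
  w <- nchar(instances$site[1])
  M <- site_code_matrix(instances$site, seq_len(w))
  cnt <- position_counts(M, w)
  pwm <- (cnt + pseudocount) / (x + 4 * pseudocount)
  colnames(pwm) <- BASES
  structure(list(
    consensus = consensus_from_pwm(pwm),
    source_consensus = source_consensus,
    width = as.integer(w),
    pwm = pwm,
    instances = instances,
    x_m = as.integer(x),
    map_score = map_score(instances, bgm),
    fold = NA_real_,
    zscore = NA_real_
  ), class = "refined_motif")
}

#' Derive an IUPAC consensus string from a PWM
#'
#' Per position, bases are added in decreasing probability until their
#' cumulative probability reaches `min_mass`; the resulting base set is
#' written as its IUPAC code (a near-uniform column becomes N).
#'
#' @param pwm Row-stochastic matrix with columns A, C, G, T.
#' @param min_mass Cumulative probability to cover (default 0.8).
#' @return Consensus string.
#' @export
consensus_from_pwm <- function(pwm, min_mass = 0.8) {
  code_of <- vapply(names(IUPAC_CODES), function(cd) {
    paste(sort(IUPAC_CODES[[cd]]), collapse = "")
  }, character(1))
  paste(apply(pwm, 1, function(p) {
    o <- order(-p, seq_along(p))
    k <- which(cumsum(p[o]) >= min_mass)[1]
    if (is.na(k)) k <- 4L
    names(code_of)[match(paste(sort(BASES[o[seq_len(k)]]), collapse = ""),
                         code_of)]
  }), collapse = "")
}

#' @export
print.refined_motif <- function(x, ...) {
  cat("Refined motif:", x$consensus, "\n")
  cat("  width:", x$width, "| instances:", x$x_m,
      "| MAP:", format(x$map_score, digits = 4), "\n")
  cat("  source consensus:", x$source_consensus, "\n")
  invisible(x)
}
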