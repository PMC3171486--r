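# Stage 2: degeneration of primary cores into IUPAC consensuses.
# Stage 3: extension with informative flanking (and gap-interior) positions.
#
# Both stages score every candidate exactly. Degeneration candidates differ
# from the core only at the six informative positions, so their counts
# follow from the same trimer-pair tables used for stage 1, contracted with
# per-position code-indicator matrices (Kronecker products). Extension
# candidates specialize N positions of a base pattern, so their instances
# are a subset of the base pattern's and their counts follow from joint
# residue tallies of the base instance list. Equivalence of both shortcuts
# with direct scanning is property-tested.

#' Enumerate degenerations of a primary core motif
#'
#' All consensuses obtained from a two-triplet core UVW-N^g-XYZ by replacing
#' the characters at up to `max_changed` of the six informative positions
#' with a different consistent IUPAC code (a code whose nucleotide set
#' contains the original base; each base has 7 such non-identity codes,
#' N included). The unmodified core is part of the enumeration (0 changes);
#' the gap region is never touched.
#'
#' @param core Core consensus string of shape UVW-N^g-XYZ.
#' @param max_changed Maximum number of informative positions changed
#'   (default 4).
#' @return Character vector of candidate consensus patterns.
#' @examples
#' length(enumerate_degenerations("ACGTAG", max_changed = 0))  # 1
#' @export
enumerate_degenerations <- function(core, max_changed = 4) {
  pc <- parse_core(core)
  cc <- lapply(pc$bases, consistent_codes)
  grid <- as.matrix(expand.grid(j1 = 1:8, j2 = 1:8, j3 = 1:8,
                                j4 = 1:8, j5 = 1:8, j6 = 1:8))
  changes <- rowSums(grid > 1L)
  grid <- grid[changes <= max_changed, , drop = FALSE]
  gapN <- strrep("N", pc$gap)
  paste0(cc[[1]][grid[, 1]], cc[[2]][grid[, 2]], cc[[3]][grid[, 3]], gapN,
         cc[[4]][grid[, 4]], cc[[5]][grid[, 5]], cc[[6]][grid[, 6]])
}

parse_core <- function(core) {
  core <- toupper(core)
  n <- nchar(core)
  if (n < 6) stop("core must have at least 6 positions")
  chars <- strsplit(core, "")[[1]]
  gap <- n - 6L
  inf_idx <- c(1:3, (4L + gap):(6L + gap))
  if (gap > 0 && any(chars[4:(3L + gap)] != "N")) {
    stop("core gap region must be all N")
  }
  bases <- chars[inf_idx]
  if (!all(bases %in% BASES)) {
    stop("core must have exactly 6 informative A/C/G/T positions")
  }
  list(bases = bases, gap = gap, span = n)
}

#' Select the best degenerate form of a primary core
#'
#' Scores every consensus enumerated by [enumerate_degenerations()] on the
#' foreground/background pair and keeps those whose fold enrichment and
#' z-score both strictly exceed the core's own. Among the qualifiers, the
#' one with the largest z-score is returned (ties broken lexicographically);
#' if none qualify, the original core is returned unchanged.
#'
#' @param fg,bg Foreground and background sequence sets.
#' @param core Primary core consensus (UVW-N^g-XYZ).
#' @param max_changed Maximum informative positions changed (default 4).
#' @return List with elements `pattern` (selected consensus), `stats`
#'   (one-row enrichment tibble) and `changed` (logical).
#' @export
select_degenerate <- function(fg, bg, core, max_changed = 4) {
  pc <- parse_core(core)
  Tfg <- pair_tables(fg, gaps = pc$gap)[[1]]
  Tbg <- pair_tables(bg, gaps = pc$gap)[[1]]
  select_degenerate_impl(Tfg, Tbg, total_length(fg), total_length(bg),
                         core, max_changed)
}

select_degenerate_impl <- function(Tfg, Tbg, L_fg, L_bg, core,
                                   max_changed = 4) {
  pc <- parse_core(core)
  cc <- lapply(pc$bases, consistent_codes)
  P <- lapply(cc, code_indicator)
  A1 <- kronecker(P[[1]], kronecker(P[[2]], P[[3]]))
  A2 <- kronecker(P[[4]], kronecker(P[[5]], P[[6]]))
  rcidx <- rc3_perm() + 1L

  fwd_rc_counts <- function(Tm) {
    Trc <- t(Tm)[rcidx, rcidx]
    list(fwd = crossprod(A1, Tm %*% A2), rc = crossprod(A1, Trc %*% A2))
  }
  Mfg <- fwd_rc_counts(Tfg)
  Mbg <- fwd_rc_counts(Tbg)

  # column h of a half: h = 64*(j1-1) + 8*(j2-1) + j3 (j3 fastest)
  j3 <- rep(1:8, times = 64)
  j2 <- rep(rep(1:8, each = 8), times = 8)
  j1 <- rep(1:8, each = 64)
  ch_half1 <- (j1 > 1) + (j2 > 1) + (j3 > 1)
  half_chars <- function(ccs) cbind(ccs[[1]][j1], ccs[[2]][j2], ccs[[3]][j3])
  H1 <- half_chars(cc[1:3])
  H2 <- half_chars(cc[4:6])
  ch2 <- (H2[, 1] != pc$bases[4]) + (H2[, 2] != pc$bases[5]) +
    (H2[, 3] != pc$bases[6])

  pal <- outer(H1[, 1], unname(IUPAC_COMPLEMENT[H2[, 3]]), "==") &
    outer(H1[, 2], unname(IUPAC_COMPLEMENT[H2[, 2]]), "==") &
    outer(H1[, 3], unname(IUPAC_COMPLEMENT[H2[, 1]]), "==")

  Cfg <- Mfg$fwd + Mfg$rc
  Cbg <- Mbg$fwd + Mbg$rc
  Cfg[pal] <- Mfg$fwd[pal]
  Cbg[pal] <- Mbg$fwd[pal]

  stats0 <- enrichment_stats(Cfg[1, 1], Cbg[1, 1], L_fg, L_bg)

  keep <- outer(ch_half1, ch2, "+") <= max_changed
  idx <- which(keep)
  st <- enrichment_stats(Cfg[idx], Cbg[idx], L_fg, L_bg)
  qual <- st$fold > stats0$fold & st$zscore > stats0$zscore
  if (!any(qual)) {
    return(list(pattern = core, stats = stats0, changed = FALSE))
  }
  zq <- st$zscore[qual]
  best_z <- max(zq)
  cand_idx <- idx[qual][zq == best_z]
  gapN <- strrep("N", pc$gap)
  patterns <- vapply(cand_idx, function(i) {
    h1 <- (i - 1L) %% 512L + 1L
    h2 <- (i - 1L) %/% 512L + 1L
    paste0(paste(H1[h1, ], collapse = ""), gapN,
           paste(H2[h2, ], collapse = ""))
  }, character(1))
  o <- order(patterns)[1]
  sel <- which(idx == cand_idx[o])
  list(pattern = patterns[o],
       stats = st[sel, , drop = FALSE],
       changed = TRUE)
}

#' Extend a core motif with informative flanking positions
#'
#' Pads the consensus with equal numbers of N on each side up to a span of
#' 20 (cores with an even original gap) or 19 (odd gap), then exhaustively
#' scores every variant in which up to `max_changed` non-informative N
#' positions (flanks or gap interior) are replaced by any of the 14 non-N
#' IUPAC codes. The variant with the largest z-score is adopted if it beats
#' the unextended padded core; otherwise the padded core is kept. For large
#' datasets (foreground above `large_threshold` nucleotides) the step is run
#' a second time starting from the first round's winner.
#'
#' @param fg,bg Foreground and background sequence sets.
#' @param core Consensus to extend (typically from [select_degenerate()]).
#' @param max_changed Maximum N positions specialized per round (default 3).
#' @param large_threshold Foreground length (nt) above which a second
#'   round is run (default 100000).
#' @return List with elements `pattern` (extended consensus), `stats`
#'   (one-row enrichment tibble for the returned pattern) and `rounds`.
#' @export
extend_core <- function(fg, bg, core, max_changed = 3,
                        large_threshold = 100000) {
  core <- toupper(core)
  span <- nchar(core)
  gap <- span - 6L
  if (gap < 0) stop("core span below 6")
  target <- if (gap %% 2L == 0L) 20L else 19L
  if (span > target) stop("core span ", span, " exceeds extension target ", target)
  pad <- (target - span) %/% 2L
  pattern <- paste0(strrep("N", pad), core, strrep("N", pad))

  L_fg <- total_length(fg)
  L_bg <- total_length(bg)
  n_rounds <- if (L_fg > large_threshold) 2L else 1L
  res <- NULL
  for (r in seq_len(n_rounds)) {
    res <- extend_round(fg, bg, pattern, max_changed, L_fg, L_bg)
    pattern <- res$pattern
  }
  list(pattern = pattern, stats = res$stats, rounds = n_rounds)
}

extend_round <- function(fg, bg, pattern, max_changed, L_fg, L_bg) {
  chars <- strsplit(pattern, "")[[1]]
  npos <- which(chars == "N")
  m <- length(npos)

  inst_fg <- scan_instances(fg, pattern, 0)
  inst_bg <- scan_instances(bg, pattern, 0)
  stats0 <- enrichment_stats(nrow(inst_fg), nrow(inst_bg), L_fg, L_bg)
  if (m == 0 || (nrow(inst_fg) == 0 && nrow(inst_bg) == 0)) {
    return(list(pattern = pattern, stats = stats0))
  }

  pal_base <- is_palindromic(pattern)
  sites_fg <- inst_fg$site
  sites_bg <- inst_bg$site
  if (pal_base) {
    sites_fg <- c(sites_fg, reverse_complement(sites_fg))
    sites_bg <- c(sites_bg, reverse_complement(sites_bg))
  }

  mat_fg <- site_code_matrix(sites_fg, npos)
  mat_bg <- site_code_matrix(sites_bg, npos)

  S <- code_indicator(NON_N_CODES)             # 4 x 14
  nc <- length(NON_N_CODES)                    # 14 non-N IUPAC codes
  comp_codes <- unname(IUPAC_COMPLEMENT[NON_N_CODES])
  selfc <- NON_N_CODES == comp_codes
  L <- length(chars)
  center <- if (L %% 2L == 1L) (L + 1L) %/% 2L else NA_integer_
  mirror <- L + 1L - npos

  # ---- candidate counts per change-count k ------------------------------
  cand <- list()

  tab1 <- function(mat) {
    if (nrow(mat) == 0) return(matrix(0, 4, m))
    vapply(seq_len(m), function(p) tabulate(mat[, p], nbins = 4L), numeric(4))
  }
  C1_fg <- crossprod(S, tab1(mat_fg))          # 15 x m
  C1_bg <- crossprod(S, tab1(mat_bg))
  pal1 <- if (pal_base && !is.na(center)) outer(selfc, npos == center, "&")
  else matrix(FALSE, nc, m)
  cand$k1 <- list(C = as.vector(C1_fg), N = as.vector(C1_bg),
                  pal = as.vector(pal1), k = 1L,
                  pos = matrix(rep(npos, each = nc), ncol = 1),
                  code = matrix(rep(seq_len(nc), times = m), ncol = 1))

  if (max_changed >= 2L && m >= 2L) {
    pairs <- t(utils::combn(m, 2L))
    K2 <- kronecker(S, S)                      # 16 x nc^2, combo (j1 slow, j2 fast)
    J2_fg <- tally_pairs_cpp(mat_fg, pairs)
    J2_bg <- tally_pairs_cpp(mat_bg, pairs)
    C2_fg <- crossprod(K2, J2_fg)              # nc^2 x npairs
    C2_bg <- crossprod(K2, J2_bg)
    cj2 <- rep(seq_len(nc), times = nc)        # j2 (second position code)
    cj1 <- rep(seq_len(nc), each = nc)
    combo_pal2 <- cj2 == match(comp_codes[cj1], NON_N_CODES)
    pair_mirror <- npos[pairs[, 2]] == mirror[pairs[, 1]]
    pal2 <- if (pal_base) outer(combo_pal2, pair_mirror, "&") else
      matrix(FALSE, nc^2, nrow(pairs))
    cand$k2 <- list(C = as.vector(C2_fg), N = as.vector(C2_bg),
                    pal = as.vector(pal2), k = 2L,
                    pos = cbind(rep(npos[pairs[, 1]], each = nc^2),
                                rep(npos[pairs[, 2]], each = nc^2)),
                    code = cbind(rep(cj1, times = nrow(pairs)),
                                 rep(cj2, times = nrow(pairs))))
  }

  if (max_changed >= 3L && m >= 3L) {
    triples <- t(utils::combn(m, 3L))
    K3 <- kronecker(S, kronecker(S, S))        # 64 x nc^3
    J3_fg <- tally_triples_cpp(mat_fg, triples)
    J3_bg <- tally_triples_cpp(mat_bg, triples)
    C3_fg <- crossprod(K3, J3_fg)              # nc^3 x ntriples
    C3_bg <- crossprod(K3, J3_bg)
    r <- seq_len(nc^3) - 1L
    cj1 <- r %/% nc^2 + 1L
    cj2 <- (r %/% nc) %% nc + 1L
    cj3 <- r %% nc + 1L
    combo_pal3 <- selfc[cj2] & (cj3 == match(comp_codes[cj1], NON_N_CODES))
    trip_mirror <- !is.na(center) & npos[triples[, 2]] == center &
      npos[triples[, 3]] == mirror[triples[, 1]]
    pal3 <- if (pal_base) outer(combo_pal3, trip_mirror, "&") else
      matrix(FALSE, nc^3, nrow(triples))
    cand$k3 <- list(C = as.vector(C3_fg), N = as.vector(C3_bg),
                    pal = as.vector(pal3), k = 3L,
                    pos = cbind(rep(npos[triples[, 1]], each = nc^3),
                                rep(npos[triples[, 2]], each = nc^3),
                                rep(npos[triples[, 3]], each = nc^3)),
                    code = cbind(rep(cj1, times = nrow(triples)),
                                 rep(cj2, times = nrow(triples)),
                                 rep(cj3, times = nrow(triples))))
  }

  C <- unlist(lapply(cand, `[[`, "C"), use.names = FALSE)
  N <- unlist(lapply(cand, `[[`, "N"), use.names = FALSE)
  pal <- unlist(lapply(cand, `[[`, "pal"), use.names = FALSE)
  C[pal] <- C[pal] / 2
  N[pal] <- N[pal] / 2

  st <- enrichment_stats(C, N, L_fg, L_bg)
  best_z <- max(st$zscore)
  if (!(best_z > stats0$zscore)) {
    return(list(pattern = pattern, stats = stats0))
  }
  best_idx <- which(st$zscore == best_z)
  # materialize the tied candidates' patterns, pick the lexicographic min
  all_pos <- do.call(rbind, lapply(cand, function(x) {
    p <- x$pos
    cbind(p, matrix(NA_integer_, nrow(p), 3L - ncol(p)))
  }))
  all_code <- do.call(rbind, lapply(cand, function(x) {
    cd <- x$code
    cbind(cd, matrix(NA_integer_, nrow(cd), 3L - ncol(cd)))
  }))
  patt_of <- function(i) {
    ch <- chars
    for (j in 1:3) {
      if (!is.na(all_pos[i, j])) ch[all_pos[i, j]] <- NON_N_CODES[all_code[i, j]]
    }
    paste(ch, collapse = "")
  }
  patterns <- vapply(best_idx, patt_of, character(1))
  o <- order(patterns)[1]
  list(pattern = patterns[o], stats = st[best_idx[o], , drop = FALSE])
}

# integer codes 1..4 (0 for N) of site residues at the given positions
site_code_matrix <- function(sites, positions) {
  n <- length(sites)
  m <- length(positions)
  if (n == 0) return(matrix(integer(0), nrow = 0, ncol = m))
  out <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    b <- substr(sites, positions[j], positions[j])
    code <- match(b, BASES)
    code[is.na(code)] <- 0L
    out[, j] <- code
  }
  out
}
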