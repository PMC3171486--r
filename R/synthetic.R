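# Seeded synthetic foreground/background generator with planted motif
# instances, used by the test-suite and for end-to-end validation.

#' Specification for a synthetic planted-motif dataset
#'
#' Describes a dataset in which background sequences are drawn from a
#' background model (uniform by default, or an order-3 Markov model fitted
#' from real sequences) and one motif instance is planted into a chosen
#' fraction of the foreground sequences (ZOOPS-style: zero or one occurrence
#' per sequence), at a uniform random position and strand.
#'
#' @param motif IUPAC consensus string or PWM (row-stochastic matrix,
#'   columns A,C,G,T) to plant.
#' @param planted_fraction Fraction of foreground sequences receiving an
#'   instance, in \[0, 1\] (default 0.4).
#' @param per_site_mismatch_rate Per-position probability of substituting a
#'   planted informative base with a different one (default 0).
#' @param seed Integer seed; identical specs and seeds give identical
#'   datasets.
#' @param n_seqs,seq_length Number and length (nt) of foreground sequences
#'   (defaults 200 and 500).
#' @param n_bg_seqs,bg_seq_length Background dimensions. The default
#'   background holds four times as many sequences as the foreground,
#'   mirroring the usual situation where the background (all promoters,
#'   matched random regions) is much larger than the target set and making
#'   the enrichment z-score well defined.
#' @param background `"uniform"` or a `markov_background` object.
#' @return A `plant_spec` object.
#' @export
plant_spec <- function(motif, planted_fraction = 0.4,
                       per_site_mismatch_rate = 0, seed = 1L,
                       n_seqs = 200L, seq_length = 500L,
                       n_bg_seqs = 4L * n_seqs, bg_seq_length = seq_length,
                       background = "uniform") {
  stopifnot(planted_fraction >= 0, planted_fraction <= 1,
            per_site_mismatch_rate >= 0, per_site_mismatch_rate <= 1,
            n_seqs >= 1, seq_length >= 1)
  span <- if (is.matrix(motif)) nrow(motif) else nchar(motif)
  if (span > seq_length) stop("motif span exceeds the sequence length")
  structure(list(motif = motif, planted_fraction = planted_fraction,
                 per_site_mismatch_rate = per_site_mismatch_rate,
                 seed = as.integer(seed), n_seqs = as.integer(n_seqs),
                 seq_length = as.integer(seq_length),
                 n_bg_seqs = as.integer(n_bg_seqs),
                 bg_seq_length = as.integer(bg_seq_length),
                 background = background),
            class = "plant_spec")
}

#' Generate a synthetic dataset with planted motif instances
#'
#' @param spec A [plant_spec()] object.
#' @return List with `fg` and `bg` sequence sets and `truth`, a tibble of
#'   planted instances (`sequence_id`, `offset`, `strand`, `site` in motif
#'   orientation, `mismatches`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  withr::with_seed(spec$seed, {
    bg <- seq_set(paste0("bg_", seq_len(spec$n_bg_seqs)),
                  sample_background(spec$n_bg_seqs, spec$bg_seq_length,
                                    spec$background))
    fg_seqs <- sample_background(spec$n_seqs, spec$seq_length,
                                 spec$background)
    span <- if (is.matrix(spec$motif)) nrow(spec$motif) else nchar(spec$motif)
    k <- round(spec$planted_fraction * spec$n_seqs)
    planted <- if (k > 0) sort(sample.int(spec$n_seqs, k)) else integer(0)
    truth <- vector("list", length(planted))
    for (j in seq_along(planted)) {
      i <- planted[j]
      st <- sample_site(spec$motif, spec$per_site_mismatch_rate)
      offset <- sample.int(spec$seq_length - span + 1L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      inserted <- if (strand == "+") st$site else reverse_complement(st$site)
      substr(fg_seqs[i], offset + 1L, offset + span) <- inserted
      truth[[j]] <- tibble::tibble(
        sequence_id = paste0("fg_", i), offset = offset, strand = strand,
        site = st$site, mismatches = st$mismatches)
    }
    fg <- seq_set(paste0("fg_", seq_len(spec$n_seqs)), fg_seqs)
    truth <- if (length(truth)) dplyr::bind_rows(truth) else
      tibble::tibble(sequence_id = character(), offset = integer(),
                     strand = character(), site = character(),
                     mismatches = integer())
    list(fg = fg, bg = bg, truth = truth)
  })
}

sample_background <- function(n, len, background) {
  if (identical(background, "uniform")) {
    return(vapply(seq_len(n), function(i) {
      paste(sample(BASES, len, replace = TRUE), collapse = "")
    }, character(1)))
  }
  if (!inherits(background, "markov_background")) {
    stop("background must be \"uniform\" or a markov_background object")
  }
  probs <- lapply(background$logp, exp)
  o <- background$order
  vapply(seq_len(n), function(i) {
    e <- integer(len)
    ctx <- 0L
    for (p in seq_len(len)) {
      avail <- min(o, p - 1L)
      e[p] <- sample.int(4L, 1L, prob = probs[[avail + 1L]][ctx + 1L, ]) - 1L
      if (avail < o) ctx <- ctx * 4L + e[p]
      else ctx <- (ctx %% 4L^(o - 1L)) * 4L + e[p]
    }
    decode_bases(e)
  }, character(1))
}

sample_site <- function(motif, mismatch_rate) {
  if (is.matrix(motif)) {
    bases <- apply(motif, 1, function(p) sample(BASES, 1L, prob = p))
    informative <- rep(TRUE, nrow(motif))
  } else {
    chars <- strsplit(toupper(motif), "")[[1]]
    bases <- vapply(chars, function(cd) {
      set <- IUPAC_CODES[[cd]]
      if (is.null(set)) stop("invalid IUPAC character in motif: ", cd)
      set[sample.int(length(set), 1L)]
    }, character(1), USE.NAMES = FALSE)
    informative <- chars != "N"
  }
  mm <- 0L
  if (mismatch_rate > 0) {
    hit <- which(informative & stats::runif(length(bases)) < mismatch_rate)
    for (i in hit) {
      bases[i] <- sample(setdiff(BASES, bases[i]), 1L)
    }
    mm <- length(hit)
  }
  list(site = paste(bases, collapse = ""), mismatches = mm)
}

#' Write a synthetic dataset to disk
#'
#' Writes `fg.fasta`, `bg.fasta` and `truth.bed` (BED6; 0-based half-open,
#' planted strand in column 6) into a directory.
#'
#' @param dataset List as returned by [generate_dataset()].
#' @param dir Output directory, created if needed.
#' @return Named vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fg_path <- file.path(dir, "fg.fasta")
  bg_path <- file.path(dir, "bg.fasta")
  bed_path <- file.path(dir, "truth.bed")
  write_fasta(dataset$fg, fg_path)
  write_fasta(dataset$bg, bg_path)
  tr <- dataset$truth
  span <- if (nrow(tr)) nchar(tr$site[1]) else 0L
  bed <- data.frame(tr$sequence_id, tr$offset, tr$offset + span,
                    "planted", 0L, tr$strand)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(fg = fg_path, bg = bg_path, truth = bed_path))
}
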