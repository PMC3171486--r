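# FASTA input, sequence-set containers (plain tibbles) and report writers.

#' Build a sequence set from identifiers and residues
#'
#' A sequence set is an ordinary tibble with columns `id` and `seq`, the
#' container used for foreground and background sequences throughout the
#' package. Residues are folded to uppercase and every letter other than
#' A, C, G or T (including the other IUPAC ambiguity codes) is replaced by N;
#' an N never matches a specified consensus position during scanning, so
#' ambiguous input cannot inflate enrichment counts.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param seq Character vector of residues, same length as `id`.
#' @return A tibble with columns `id`, `seq`.
#' @examples
#' seq_set(c("s1", "s2"), c("acgt", "ACRGT"))
#' @export
seq_set <- function(id, seq) {
  stopifnot(length(id) == length(seq))
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  seq <- gsub("[^ACGT]", "N", seq)
  if (anyDuplicated(id)) {
    warning("duplicated sequence identifiers; making them unique")
    id <- make.unique(id, sep = "_")
  }
  tibble::tibble(id = id, seq = seq)
}

#' Total residue length of a sequence set
#'
#' The sum of sequence lengths in nucleotides (N residues included), the
#' quantity used to scale background counts into foreground expectations.
#'
#' @param seqs A sequence set tibble (see [seq_set()]).
#' @return Integer total length.
#' @export
total_length <- function(seqs) {
  sum(nchar(seqs$seq))
}

#' Read a FASTA file into a sequence set
#'
#' Records are kept in file order and residues normalized as in [seq_set()]:
#' uppercase, non-ACGT letters folded to N. Empty headers or zero-length
#' records are retained with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A sequence set tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  dss <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("failed to parse FASTA file '", path, "': ",
                             conditionMessage(e))
  )
  ids <- names(dss)
  if (is.null(ids)) ids <- rep("", length(dss))
  # keep only the first whitespace-delimited token of each header
  ids <- sub("\\s.*$", "", ids)
  if (any(ids == "")) {
    warning("FASTA records with empty headers; assigning positional ids")
    ids[ids == ""] <- paste0("seq_", which(ids == ""))
  }
  if (any(Biostrings::width(dss) == 0)) {
    warning("FASTA records with zero-length sequences retained")
  }
  seq_set(ids, as.character(dss))
}

#' Write a sequence set to a FASTA file
#'
#' @param seqs A sequence set tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  dss <- Biostrings::DNAStringSet(seqs$seq)
  names(dss) <- seqs$id
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Write discovered motifs as MEME, TSV and BED files
#'
#' Writes three plain-text artifacts for a list of refined motifs:
#' `<prefix>.meme` (MEME minimal motif format, version 4),
#' `<prefix>_summary.tsv` (rank, consensus, width, instance count, MAP score,
#' fold enrichment, z-score) and `<prefix>_sites.bed` (BED6, 0-based
#' half-open coordinates of the preserved instances, strand in column 6).
#'
#' @param motifs List of [refined_motif] objects (may be empty).
#' @param out_dir Output directory, created if needed.
#' @param prefix File-name prefix, default `"motifs"`.
#' @param background Length-4 numeric of background letter frequencies for
#'   the MEME header, default uniform.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_motif_report <- function(motifs, out_dir, prefix = "motifs",
                               background = rep(0.25, 4)) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  meme_path <- file.path(out_dir, paste0(prefix, ".meme"))
  tsv_path <- file.path(out_dir, paste0(prefix, "_summary.tsv"))
  bed_path <- file.path(out_dir, paste0(prefix, "_sites.bed"))

  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
             "Background letter frequencies",
             paste(sprintf("%s %.5f", BASES, background), collapse = " "), "")
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    lines <- c(lines,
               sprintf("MOTIF motif_%d %s", i, m$consensus),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       m$width, m$x_m),
               apply(m$pwm, 1, function(p) paste(sprintf("%.6f", p), collapse = " ")),
               "")
  }
  writeLines(lines, meme_path)

  summ <- motif_summary(motifs)
  utils::write.table(summ, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  bed <- dplyr::bind_rows(lapply(seq_along(motifs), function(i) {
    m <- motifs[[i]]
    if (is.null(m$instances) || nrow(m$instances) == 0) return(NULL)
    tibble::tibble(
      chrom = m$instances$sequence_id,
      start = m$instances$offset,
      end = m$instances$offset + m$width,
      name = paste0("motif_", i),
      score = 0L,
      strand = m$instances$strand
    )
  }))
  if (is.null(bed) || nrow(bed) == 0) {
    bed <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = integer(), strand = character())
  }
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(meme = meme_path, tsv = tsv_path, bed = bed_path))
}

motif_summary <- function(motifs) {
  if (length(motifs) == 0) {
    return(tibble::tibble(rank = integer(), consensus = character(),
                          width = integer(), x_m = integer(),
                          map_score = numeric(), fold = numeric(),
                          zscore = numeric()))
  }
  dplyr::bind_rows(lapply(seq_along(motifs), function(i) {
    m <- motifs[[i]]
    tibble::tibble(rank = i, consensus = m$consensus, width = m$width,
                   x_m = m$x_m, map_score = m$map_score,
                   fold = m$fold %||% NA_real_,
                   zscore = m$zscore %||% NA_real_)
  }))
}

#' Read motifs from a MEME minimal motif file
#'
#' Parses the letter-probability matrices of a MEME minimal format (v4) file,
#' such as those written by [write_motif_report()]. Only the fields used by
#' the accuracy measures are retained.
#'
#' @param path Path to a MEME minimal motif file.
#' @return Named list of PWMs (row-stochastic matrices, columns A,C,G,T).
#' @export
read_meme <- function(path) {
  if (!file.exists(path)) stop("MEME file not found: ", path)
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  pwms <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- s + 1
    while (h <= length(lines) && !grepl("^letter-probability matrix", lines[h])) h <- h + 1
    if (h > length(lines)) stop("malformed MEME file: missing matrix for ", name)
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1):(h + w)]
    pwm <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }))
    colnames(pwm) <- BASES
    pwms[[name]] <- pwm
  }
  pwms
}

`%||%` <- function(a, b) if (is.null(a)) b else a
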