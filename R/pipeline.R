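# End-to-end orchestration of the five discovery stages: core filtering ->
# degeneration -> extension -> refinement -> redundancy removal.

#' Pipeline configuration
#'
#' All tunable parameters of the discovery workflow with their default
#' values: minimal fold enrichment 1.2, top 50 primary cores, gaps 0-14,
#' at most 4 of 6 informative positions degenerated, at most 3
#' non-informative positions specialized per extension round, a second
#' extension round above 100 kb of foreground, refinement scanning with 1
#' mismatch, redundancy cutoff 0.6 and an order-3 Markov background.
#'
#' @param min_fold Minimal fold enrichment for primary cores.
#' @param top_k_cores Number of primary cores retained.
#' @param max_gap Maximum core gap length.
#' @param degeneration_max_changed Informative positions degenerated.
#' @param extension_max_changed N positions specialized per round.
#' @param large_fg_threshold Foreground length (nt) triggering a second
#'   extension round.
#' @param scan_mismatch Mismatches allowed when scanning for refinement.
#' @param redundancy_cutoff CompareACE similarity above which motifs are
#'   redundant.
#' @param markov_order Background Markov model order.
#' @param seed Integer seed recorded with the run (the discovery stages are
#'   deterministic; the seed governs auxiliary simulation commands).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(min_fold = 1.2, top_k_cores = 50, max_gap = 14,
                            degeneration_max_changed = 4,
                            extension_max_changed = 3,
                            large_fg_threshold = 100000,
                            scan_mismatch = 1, redundancy_cutoff = 0.6,
                            markov_order = 3, seed = 1L) {
  cfg <- list(min_fold = min_fold, top_k_cores = as.integer(top_k_cores),
              max_gap = as.integer(max_gap),
              degeneration_max_changed = as.integer(degeneration_max_changed),
              extension_max_changed = as.integer(extension_max_changed),
              large_fg_threshold = large_fg_threshold,
              scan_mismatch = as.integer(scan_mismatch),
              redundancy_cutoff = redundancy_cutoff,
              markov_order = as.integer(markov_order),
              seed = as.integer(seed))
  ok <- cfg$min_fold > 0 && cfg$top_k_cores > 0 && cfg$max_gap >= 0 &&
    cfg$degeneration_max_changed >= 0 && cfg$extension_max_changed >= 0 &&
    cfg$large_fg_threshold > 0 && cfg$scan_mismatch >= 0 &&
    cfg$redundancy_cutoff > 0 && cfg$markov_order >= 0
  if (!ok) stop("invalid pipeline configuration")
  structure(cfg, class = "pipeline_config")
}

#' Run the full motif discovery workflow
#'
#' Executes core filtering, degeneration, extension, refinement and
#' redundancy removal on a foreground/background pair and returns the final
#' motifs sorted by decreasing MAP score. Identical consensuses emerging
#' from different cores are computed once (results are unchanged: duplicate
#' intermediates converge to identical motifs, which the redundancy stage
#' would collapse anyway).
#'
#' @param fg,bg Sequence sets (tibbles from [read_fasta()]/[seq_set()]) or
#'   paths to FASTA files.
#' @param config A [pipeline_config()] object.
#' @param out_dir Optional output directory; when given, MEME/TSV/BED
#'   reports and a run log are written there.
#' @param verbose Emit per-stage progress messages (default `FALSE`).
#' @return A `motifstep_result` list with elements `motifs` (list of
#'   `refined_motif`), `summary` (tibble), `trace` (per-core stage
#'   provenance), `stages` (per-stage counts) and `config`.
#' @export
run_pipeline <- function(fg, bg, config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(fg)) fg <- read_fasta(fg)
  if (is.character(bg)) bg <- read_fasta(bg)
  if (nrow(fg) == 0 || nrow(bg) == 0) {
    stop("foreground and background must be non-empty")
  }
  say <- function(...) if (verbose) message(...)
  L_fg <- total_length(fg)
  L_bg <- total_length(bg)

  say("stage 1/5: scoring ", 4096 * (config$max_gap + 1), " core consensuses")
  tab_fg <- pair_tables(fg, gaps = 0:config$max_gap)
  tab_bg <- pair_tables(bg, gaps = 0:config$max_gap)
  cores <- core_enrichment_impl(tab_fg, tab_bg, L_fg, L_bg, config$max_gap)
  cores <- dplyr::filter(cores, .data$fold >= config$min_fold)
  cores <- dplyr::arrange(cores, dplyr::desc(.data$zscore), .data$pattern)
  cores <- utils::head(cores, config$top_k_cores)
  say("  ", nrow(cores), " primary cores retained")
  if (nrow(cores) == 0) {
    res <- empty_result(config)
    if (!is.null(out_dir)) write_result(res, out_dir)
    return(res)
  }

  say("stage 2/5: degenerating ", nrow(cores), " cores")
  deg <- lapply(seq_len(nrow(cores)), function(i) {
    select_degenerate_impl(tab_fg[[cores$gap[i] + 1L]],
                           tab_bg[[cores$gap[i] + 1L]],
                           L_fg, L_bg, cores$pattern[i],
                           config$degeneration_max_changed)
  })

  say("stage 3/5: extending")
  deg_patterns <- vapply(deg, `[[`, character(1), "pattern")
  uniq_deg <- unique(deg_patterns)
  ext_by_deg <- lapply(uniq_deg, function(p) {
    extend_core(fg, bg, p, config$extension_max_changed,
                config$large_fg_threshold)
  })
  names(ext_by_deg) <- uniq_deg
  ext <- ext_by_deg[deg_patterns]

  say("stage 4/5: refining against an order-", config$markov_order,
      " Markov background")
  bgm <- fit_markov_background(bg, config$markov_order)
  ext_patterns <- vapply(ext, `[[`, character(1), "pattern")
  uniq_ext <- unique(ext_patterns)
  ref_by_ext <- lapply(uniq_ext, function(p) {
    refine_motif(fg, p, bgm, config$scan_mismatch)
  })
  names(ref_by_ext) <- uniq_ext

  trace <- tibble::tibble(
    core = cores$pattern, core_zscore = cores$zscore,
    core_fold = cores$fold,
    degenerate = deg_patterns,
    degenerate_zscore = vapply(deg, function(d) d$stats$zscore, numeric(1)),
    extended = ext_patterns,
    extended_zscore = vapply(ext, function(e) e$stats$zscore, numeric(1)),
    extended_fold = vapply(ext, function(e) e$stats$fold, numeric(1))
  )

  refined <- list()
  for (p in uniq_ext) {
    mot <- ref_by_ext[[p]]
    if (is.null(mot)) next
    i <- match(p, ext_patterns)
    mot$fold <- ext[[i]]$stats$fold
    mot$zscore <- ext[[i]]$stats$zscore
    refined[[length(refined) + 1L]] <- mot
  }
  say("  ", length(refined), " refined motifs")

  say("stage 5/5: redundancy removal at cutoff ", config$redundancy_cutoff)
  final <- remove_redundant(refined, config$redundancy_cutoff)
  say("  ", length(final), " motifs reported")

  res <- structure(list(
    motifs = final,
    summary = motif_summary(final),
    trace = trace,
    stages = tibble::tibble(
      stage = c("primary_cores", "degenerate", "extended", "refined", "final"),
      n = c(nrow(cores), length(deg), length(ext), length(refined),
            length(final))),
    config = config
  ), class = "motifstep_result")
  if (!is.null(out_dir)) write_result(res, out_dir)
  res
}

empty_result <- function(config) {
  structure(list(
    motifs = list(), summary = motif_summary(list()),
    trace = tibble::tibble(), stages = tibble::tibble(
      stage = c("primary_cores", "degenerate", "extended", "refined", "final"),
      n = rep(0L, 5)),
    config = config
  ), class = "motifstep_result")
}

write_result <- function(res, out_dir) {
  paths <- write_motif_report(res$motifs, out_dir)
  log_path <- file.path(out_dir, "run_log.txt")
  cfg <- res$config
  lines <- c(
    "motifstep run log",
    paste0("config: ", paste(names(cfg), unlist(cfg), sep = "=",
                             collapse = " ")),
    paste0("stage counts: ",
           paste(res$stages$stage, res$stages$n, sep = "=", collapse = " ")),
    "final motifs:",
    if (nrow(res$summary)) {
      sprintf("  %d %s w=%d x_m=%d MAP=%.4f fold=%.3f Z=%.3f",
              res$summary$rank, res$summary$consensus, res$summary$width,
              res$summary$x_m, res$summary$map_score, res$summary$fold,
              res$summary$zscore)
    } else "  (none passed the filters)"
  )
  writeLines(lines, log_path)
  invisible(c(paths, log = log_path))
}

#' @export
print.motifstep_result <- function(x, ...) {
  cat("motifstep result:", length(x$motifs), "motifs\n")
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}
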