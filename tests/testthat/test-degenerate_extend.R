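test_that("consistent codes and the degeneration space have the stated size", {
  cc <- motifstep:::consistent_codes("A")
  expect_setequal(cc, c("A", "M", "R", "W", "V", "H", "D", "N"))
  expect_length(cc, 8L)
  for (b in c("A", "C", "G", "T")) {
    expect_length(motifstep:::consistent_codes(b), 8L)
    expect_true(all(c(b, "N") %in% motifstep:::consistent_codes(b)))
  }

  # sum_{k<=4} C(6,k) 7^k candidates per core
  expect_length(enumerate_degenerations("ACGTAG"), 43653L)
  expect_equal(enumerate_degenerations("ACGTAG", max_changed = 0), "ACGTAG")
  # gapped core: gap region untouched
  degs <- enumerate_degenerations("ACGNNTAG", max_changed = 1)
  expect_true(all(substr(degs, 4, 5) == "NN"))
  expect_error(enumerate_degenerations("ACGRAG"), "informative")
})

test_that("degenerate selection never lowers fold or z and is scanner-exact", {
  set.seed(61)
  bg <- random_seq_set(80, 200, prefix = "b")
  fg_seqs <- random_seqs(20, 200)
  for (i in 1:16) {
    substr(fg_seqs[i], 90, 95) <- if (i %% 2) "ACGTAG" else "ACGTAC"
  }
  fg <- seq_set(paste0("f", 1:20), fg_seqs)

  sel <- select_degenerate(fg, bg, "ACGTAG")
  st0 <- enrichment_stats(count_instances(fg, "ACGTAG"),
                          count_instances(bg, "ACGTAG"),
                          total_length(fg), total_length(bg))
  expect_gte(sel$stats$zscore, st0$zscore)
  if (sel$changed) expect_gt(sel$stats$fold, st0$fold)

  # the reported stats match a direct re-scan of the chosen consensus
  expect_equal(sel$stats$C, count_instances(fg, sel$pattern))
  expect_equal(sel$stats$N_bg, count_instances(bg, sel$pattern))
})

test_that("split planted bases drive degeneration toward the covering code", {
  set.seed(62)
  bg <- random_seq_set(200, 150, prefix = "b")
  fg_seqs <- random_seqs(40, 150)
  for (i in 1:36) {
    substr(fg_seqs[i], 70, 75) <- if (i %% 2) "ACGTAG" else "ACGTAC"
  }
  fg <- seq_set(paste0("f", 1:40), fg_seqs)
  sel <- select_degenerate(fg, bg, "ACGTAG")
  expect_true(sel$changed)
  expect_equal(substr(sel$pattern, 6, 6), "S")
})

test_that("a core with only exact instances is kept unchanged", {
  # foreground carries many exact copies; degenerating only adds
  # background-matching windows, so no candidate raises both fold and z
  set.seed(63)
  bg <- random_seq_set(100, 120, prefix = "b")
  fg <- seq_set("f1", paste(rep("ACGTAGTT", 40), collapse = ""))
  sel <- select_degenerate(fg, bg, "ACGTAG")
  expect_false(sel$changed)
  expect_equal(sel$pattern, "ACGTAG")
})

test_that("extension pads to span 19 or 20 by original gap parity", {
  set.seed(64)
  fg <- random_seq_set(6, 120, prefix = "f")
  bg <- random_seq_set(24, 120, prefix = "b")
  e0 <- extend_core(fg, bg, "ACGTAG")            # gap 0, even
  expect_equal(nchar(e0$pattern), 20L)
  e1 <- extend_core(fg, bg, "ACGNTAG")           # gap 1, odd
  expect_equal(nchar(e1$pattern), 19L)
  e14 <- extend_core(fg, bg, paste0("ACG", strrep("N", 14), "TAG"))
  expect_equal(nchar(e14$pattern), 20L)
  expect_error(extend_core(fg, bg, paste0("ACG", strrep("N", 15), "TAG")),
               "exceeds")
})

test_that("extension preserves informative positions and only specializes N", {
  set.seed(65)
  bg <- random_seq_set(60, 200, prefix = "b")
  fg_seqs <- random_seqs(15, 200)
  for (i in 1:12) substr(fg_seqs[i], 90, 99) <- "TTGACGTCAA"
  fg <- seq_set(paste0("f", 1:15), fg_seqs)
  core <- "ACGTCA"
  e <- extend_core(fg, bg, core)
  expect_equal(nchar(e$pattern), 20L)
  # the original informative positions sit unchanged at offset 7..12
  expect_equal(substr(e$pattern, 8, 13), core)
})

test_that("extension candidate stats match a direct re-scan of the winner", {
  set.seed(66)
  bg <- random_seq_set(60, 150, prefix = "b")
  fg_seqs <- random_seqs(15, 150)
  for (i in 1:12) substr(fg_seqs[i], 60, 69) <- "TTGACGTCAA"
  fg <- seq_set(paste0("f", 1:15), fg_seqs)
  e <- extend_core(fg, bg, "ACGTCA")
  expect_equal(e$stats$C, count_instances(fg, e$pattern))
  expect_equal(e$stats$N_bg, count_instances(bg, e$pattern))
})

test_that("extension adopts a variant only when it strictly beats the padded core", {
  set.seed(67)
  bg <- random_seq_set(120, 200, prefix = "b")
  fg <- random_seq_set(30, 200, prefix = "f")
  padded <- paste0(strrep("N", 7), "GGGCCC", strrep("N", 7))
  e <- extend_core(fg, bg, "GGGCCC", max_changed = 1)
  z_of <- function(p) {
    enrichment_stats(count_instances(fg, p), count_instances(bg, p),
                     total_length(fg), total_length(bg))$zscore
  }
  if (e$pattern == padded) {
    succeed("padded core retained")
  } else {
    expect_gt(z_of(e$pattern), z_of(padded))
  }
})

test_that("pipeline z-scores are monotone across degeneration and extension", {
  set.seed(68)
  bg <- random_seq_set(120, 200, prefix = "b")
  fg_seqs <- random_seqs(30, 200)
  for (i in 1:24) substr(fg_seqs[i], 100, 109) <- "TTGACGTCAA"
  fg <- seq_set(paste0("f", 1:30), fg_seqs)
  core <- "ACGTCA"
  st0 <- enrichment_stats(count_instances(fg, core),
                          count_instances(bg, core),
                          total_length(fg), total_length(bg))
  d <- select_degenerate(fg, bg, core)
  e <- extend_core(fg, bg, d$pattern)
  expect_gte(d$stats$zscore, st0$zscore)
  expect_gte(e$stats$zscore, d$stats$zscore)
})

test_that("palindromic extension candidates are not double counted", {
  # base core TGACGTCA... use the palindromic plant TTGACGTCAA whose core
  # GACGTC is itself palindromic: derived counts must equal direct scans
  set.seed(69)
  bg <- random_seq_set(60, 150, prefix = "b")
  fg_seqs <- random_seqs(15, 150)
  for (i in 1:12) substr(fg_seqs[i], 60, 69) <- "TTGACGTCAA"
  fg <- seq_set(paste0("f", 1:15), fg_seqs)
  core <- "GACGTC"
  expect_equal(core, reverse_complement(core))
  e <- extend_core(fg, bg, core, max_changed = 2)
  expect_equal(e$stats$C, count_instances(fg, e$pattern))
  expect_equal(e$stats$N_bg, count_instances(bg, e$pattern))
})
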