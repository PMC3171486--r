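test_that("core space enumeration has the expected size, order and bounds", {
  cs0 <- enumerate_core_space(0)
  expect_equal(nrow(cs0), 4096L)
  expect_true(all(cs0$span == 6L))

  cs <- enumerate_core_space(14)
  expect_equal(nrow(cs), 61440L)
  expect_equal(anyDuplicated(cs$pattern), 0L)
  expect_equal(max(cs$span), 20L)
  expect_equal(max(cs$gap), 14L)
  # ordered by gap then lexicographically
  expect_true(!is.unsorted(cs$gap))
  g3 <- cs$pattern[cs$gap == 3]
  expect_equal(g3, sort(g3))
})

test_that("count_instances matches hand-derived counts", {
  expect_equal(count_instances(seq_set("s1", "ACGTAGACGTAG"), "ACGTAG"), 2L)
  expect_equal(count_instances(seq_set(character(), character()), "ACGTAG"), 0L)
  gal4 <- paste0("CGG", strrep("N", 11), "CCG")
  expect_equal(count_instances(
    seq_set("g", paste0("CGG", strrep("A", 11), "CCG")), gal4), 1L)
  expect_error(count_instances(seq_set("s", "ACGT"), ""), "zero span")
})

test_that("scan_instances reports offsets, strands and oriented sites", {
  hits <- scan_instances(seq_set("s1", "ACGTAGTTACCTAG"), "ACGTAG", 1)
  expect_equal(hits$offset[hits$mismatches == 0], 0L)
  one_mm <- hits[hits$mismatches == 1 & hits$strand == "+", ]
  expect_true(8L %in% one_mm$offset)
  expect_equal(one_mm$site[one_mm$offset == 8L], "ACCTAG")
  # minus-strand site is reported in motif orientation
  hits2 <- scan_instances(seq_set("s1", "TTCTACGTTT"), "ACGTAG", 0)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$offset, 2L)
  expect_equal(hits2$site, "ACGTAG")
})

test_that("count_instances equals the brute-force oracle on random cases", {
  set.seed(101)
  n_cases <- 250
  for (i in seq_len(n_cases)) {
    seqs <- random_seq_set(sample(1:3, 1), sample(20:60, 1))
    gap <- sample(0:6, 1)
    tri <- function() paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")
    pattern <- paste0(tri(), strrep("N", gap), tri())
    mm <- sample(0:1, 1)
    expect_equal(count_instances(seqs, pattern, mm),
                 oracle_count(seqs, pattern, mm),
                 info = paste("pattern", pattern, "mm", mm, "case", i))
  }
})

test_that("palindromic consensuses are not double counted", {
  set.seed(202)
  pal_patterns <- c("ACGCGT", paste0("CGG", strrep("N", 11), "CCG"),
                    "TTGACGTCAA", "GGATCC")
  for (pattern in pal_patterns) {
    expect_equal(pattern, reverse_complement(pattern))
    for (i in 1:20) {
      seqs <- random_seq_set(2, 50)
      expect_equal(count_instances(seqs, pattern, 0),
                   oracle_count(seqs, pattern, 0),
                   info = pattern)
    }
  }
})

test_that("sequence N never satisfies a specified pattern position", {
  expect_equal(count_instances(seq_set("s", "ACNTAG"), "ACGTAG"), 0L)
  # but pattern N positions accept sequence N for free
  expect_equal(count_instances(seq_set("s", "ACGNAG"), "ACGNAG"), 1L)
  expect_equal(count_instances(seq_set("s", "ACGNAG"),
                               paste0("ACG", "N", "AG")), 1L)
})

test_that("enrichment statistics follow their definitions", {
  st <- enrichment_stats(10, 20, 1000, 4000)
  expect_equal(st$E, 5)
  expect_equal(st$fold, 2)
  expect_equal(st$zscore, 5 / sqrt(5 * 0.75), tolerance = 1e-9)
  expect_equal(round(st$zscore, 4), 2.582)

  # C = E gives fold 1, Z 0
  st0 <- enrichment_stats(5, 20, 1000, 4000)
  expect_equal(st0$fold, 1)
  expect_equal(st0$zscore, 0)

  # E = 0 sentinels
  stE <- enrichment_stats(c(3, 0), c(0, 0), 1000, 4000)
  expect_equal(stE$fold, c(Inf, 1))
  expect_equal(stE$zscore, c(0, 0))

  expect_error(enrichment_stats(-1, 2, 10, 10), "non-negative")
})

test_that("fold enrichment is invariant under duplicating both sets", {
  st1 <- enrichment_stats(7, 13, 900, 3100)
  st3 <- enrichment_stats(21, 39, 2700, 9300)
  expect_equal(st1$fold, st3$fold)
})

test_that("z-score standardizes a binomial count", {
  # with N_bg = n and p = L_fg/L_bg, E = n p and the z of a Binomial(n, p)
  # draw should be ~N(0, 1)
  set.seed(7)
  n0 <- 400L
  L_fg <- 1000
  L_bg <- 4000
  sims <- rbinom(4000, n0, L_fg / L_bg)
  zs <- vapply(sims, function(C) {
    enrichment_stats(C, n0, L_fg, L_bg)$zscore
  }, numeric(1))
  expect_equal(mean(zs), 0, tolerance = 0.05)
  expect_equal(stats::sd(zs), 1, tolerance = 0.05)
})

test_that("whole-space core counts agree with the scanner on small data", {
  set.seed(33)
  fg <- random_seq_set(3, 60, prefix = "f")
  bg <- random_seq_set(5, 60, prefix = "b")
  stats <- motifstep:::core_enrichment(fg, bg, max_gap = 2)
  pick <- stats[sample.int(nrow(stats), 60), ]
  for (i in seq_len(nrow(pick))) {
    expect_equal(pick$C[i], oracle_count(fg, pick$pattern[i], 0),
                 info = pick$pattern[i])
    expect_equal(pick$N_bg[i], oracle_count(bg, pick$pattern[i], 0),
                 info = pick$pattern[i])
  }
})

test_that("primary core selection filters, ranks and truncates", {
  set.seed(44)
  fg <- random_seq_set(20, 200, prefix = "f")
  for (i in 1:16) substr(fg$seq[i], 50, 59) <- "TTGACGTCAA"
  bg <- random_seq_set(80, 200, prefix = "b")
  sel <- select_primary_cores(fg, bg, top_k = 25)
  expect_lte(nrow(sel), 25L)
  expect_true(all(sel$fold >= 1.2))
  expect_true(!is.unsorted(rev(sel$zscore)))
  # the top core is one of the two-triplet cores inside the planted 10-mer
  planted <- "TTGACGTCAA"
  in_plant <- unlist(lapply(0:4, function(g) {
    vapply(1:(5 - g), function(i) {
      paste0(substr(planted, i, i + 2), strrep("N", g),
             substr(planted, i + 3 + g, i + 5 + g))
    }, character(1))
  }))
  expect_true(sel$pattern[1] %in% in_plant)
})

test_that("identical foreground and background select nothing", {
  set.seed(55)
  s <- random_seq_set(4, 150)
  # equal total lengths make the z variance degenerate: warned once per call
  expect_warning(enrichment_stats(5, 5, 100, 100), "z-scores undefined")
  sel <- suppressWarnings(select_primary_cores(s, s))
  expect_equal(nrow(sel), 0L)
  expect_error(select_primary_cores(s[0, ], s), "non-empty")
})
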