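test_that("Markov background probabilities are normalized and sensible", {
  set.seed(71)
  bg <- seq_set("b", paste(random_seqs(1, 100000), collapse = ""))
  bgm <- fit_markov_background(bg)
  for (k in 1:4) {
    p <- exp(bgm$logp[[k]])
    expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)
    # uniform source at 100 kb: low orders are tight, order 3 has only
    # ~3000 observations per context (max over 1024 cells needs headroom)
    tol <- if (k <= 2) 0.01 else 0.03
    expect_true(all(abs(p - 0.25) < tol))
  }

  polyA <- seq_set("a", strrep("A", 1000))
  bgmA <- fit_markov_background(polyA)
  expect_gt(exp(bgmA$logp[[4]][1, 1]), 0.95)  # p(A|AAA) ~ 1

  expect_error(fit_markov_background(seq_set("n", "NNNNNN")), "content")
})

test_that("log_p0 follows the conditional decomposition with backoff", {
  u <- uniform_background()
  expect_equal(log_p0(u, "ACGTA"), 5 * log(0.25), tolerance = 1e-12)

  set.seed(72)
  bg <- random_seq_set(10, 2000)
  bgm <- fit_markov_background(bg)
  # full-context site decomposes into order-3 conditionals
  site <- "TCATG"
  ctx <- "AGG"
  idx <- function(s) {
    codes <- c(A = 0, C = 1, G = 2, T = 3)
    sum(codes[strsplit(s, "")[[1]]] * 4^((nchar(s) - 1):0))
  }
  manual <- sum(vapply(seq_len(5), function(i) {
    full <- paste0(ctx, site)
    context3 <- substr(full, i, i + 2)
    b <- substr(full, i + 3, i + 3)
    bgm$logp[[4]][idx(context3) + 1, idx(b) + 1]
  }, numeric(1)))
  expect_equal(log_p0(bgm, site, ctx), manual, tolerance = 1e-12)

  # empty context backs off through orders 0, 1, 2, then 3
  manual_bo <- bgm$logp[[1]][1, idx("T") + 1] +
    bgm$logp[[2]][idx("T") + 1, idx("C") + 1] +
    bgm$logp[[3]][idx("TC") + 1, idx("A") + 1] +
    bgm$logp[[4]][idx("TCA") + 1, idx("T") + 1] +
    bgm$logp[[4]][idx("CAT") + 1, idx("G") + 1]
  expect_equal(log_p0(bgm, site, ""), manual_bo, tolerance = 1e-12)

  expect_error(log_p0(bgm, "ACNGT"), "N")
})

test_that("fitted background reproduces a sequence's own order-3 likelihood", {
  # for one long sequence, the fitted conditional probabilities approach the
  # empirical transition frequencies, so log_p0 of a segment approaches its
  # empirical log-likelihood; check self-consistency via exp(mean) bounds
  set.seed(73)
  s <- paste(random_seqs(1, 50000), collapse = "")
  bgm <- fit_markov_background(seq_set("s", s))
  seg <- substr(s, 1001, 1050)
  ctx <- substr(s, 998, 1000)
  lp <- log_p0(bgm, seg, ctx)
  expect_gt(lp / nchar(seg), log(0.25) - 0.05)
  expect_lt(lp / nchar(seg), log(0.25) + 0.05)
})

test_that("MAP score matches the closed form for identical sites", {
  u <- uniform_background()
  for (w in c(4, 9, 20)) {
    site <- strrep("A", w)
    for (x in c(2, 7, 50)) {
      expect_equal(map_score(instance_tbl(rep(site, x), "AAA"), u),
                   log(w) * log(x) * log(4), tolerance = 1e-9)
    }
  }
  # w = 4, x = 4: all three factors are ln 4
  expect_equal(map_score(instance_tbl(rep("ACGT", 4), "AAA"), u),
               log(4)^3, tolerance = 1e-9)
  # a single instance scores 0 regardless of site
  expect_equal(map_score(instance_tbl("ACGTA", "AAA"), u), 0)
  # strictly increasing in x for identical sites
  scores <- vapply(2:10, function(x) {
    map_score(instance_tbl(rep("ACGTAA", x), "AAA"), u)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_error(map_score(instance_tbl(character(0)), u), "zero instances")
})

test_that("leave-one-out pruning matches brute-force recomputation", {
  set.seed(74)
  u <- uniform_background()
  bgm_list <- list(u, fit_markov_background(random_seq_set(5, 3000)))
  for (bgm in bgm_list) {
    sites <- c(rep("ACGTAGAC", 12),
               vapply(1:6, function(i) {
                 paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
               }, character(1)))
    ctx <- vapply(seq_along(sites), function(i) {
      paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")
    }, character(1))
    inst <- tibble::tibble(site = sites, left_context = ctx)
    pr <- prune_instances(inst, bgm)
    # oracle: recompute each leave-one-out score from scratch
    brute <- vapply(seq_len(nrow(inst)), function(i) {
      map_score(inst[-i, ], bgm)
    }, numeric(1))
    expect_equal(pr$map_minus, brute, tolerance = 1e-9)
    expect_equal(pr$keep, pr$map_all > brute)
  }
})

test_that("pruning is invariant to instance order", {
  set.seed(75)
  sites <- c(rep("TTGACG", 15), "AGAGAG", "CCCCCC")
  inst <- tibble::tibble(site = sites, left_context = "AAA")
  u <- uniform_background()
  keep1 <- prune_instances(inst, u)
  perm <- sample(nrow(inst))
  keep2 <- prune_instances(inst[perm, ], u)
  expect_equal(keep2$keep, keep1$keep[perm])
})

test_that("a planted outlier among identical sites is pruned", {
  u <- uniform_background()
  inst <- tibble::tibble(site = c(rep("ACGTACGT", 20), "TGCATGCA"),
                         left_context = "AAA")
  pr <- prune_instances(inst, u)
  expect_equal(pr$keep, c(rep(TRUE, 20), FALSE))
  expect_equal(nrow(pr$preserved), 20L)
})

test_that("refine_motif trims N flanks, prunes and builds a stochastic PWM", {
  set.seed(76)
  bg <- random_seq_set(80, 200, prefix = "b")
  fg_seqs <- random_seqs(20, 200)
  for (i in 1:16) substr(fg_seqs[i], 90, 99) <- "TTGACGTCAA"
  fg <- seq_set(paste0("f", 1:20), fg_seqs)
  bgm <- fit_markov_background(bg)
  m <- refine_motif(fg, paste0("NNN", "TTGACGTCAA", "NNN"), bgm)
  expect_s3_class(m, "refined_motif")
  expect_equal(m$width, 10L)
  expect_equal(rowSums(m$pwm), rep(1, 10), tolerance = 1e-9)
  expect_gte(m$x_m, 16L)
  expect_gt(m$map_score, 0)
  # every preserved instance matches the consensus within the scan budget
  expect_true(all(vapply(m$instances$site, function(s) {
    oracle_mismatches(s, strsplit("TTGACGTCAA", "")[[1]]) <= 1
  }, logical(1))))

  expect_warning(
    expect_null(refine_motif(fg, "GGGGGGGGGGGGGGGGGGGG", bgm)),
    "dropped")
})
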