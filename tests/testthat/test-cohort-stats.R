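fake_pqs <- function(n, score = 1.25) {
  data.frame(seq_id = rep("chr", n), start = seq_len(n) * 100L,
             end = seq_len(n) * 100L + 30L, strand = rep("+", n),
             score = rep_len(score, n), sequence = rep("", n),
             stringsAsFactors = FALSE)
}

test_that("per-genome frequency follows the per-kbp formula", {
  # 40 PQS on a 3,192,399 bp genome -> 0.0125 PQS/kbp at 3 s.f.
  g <- genome_record("lacinutrix_like", c(chr = strrep("A", 3192399)))
  s <- summarize_genome(g, fake_pqs(40))
  expect_identical(s$pqs_total, 40L)
  expect_equal(round(s$freq_per_kbp, 4), 0.0125)
  expect_equal(s$freq_per_kbp, 1000 * 40 / 3192399, tolerance = 1e-12)

  g2 <- genome_record("tiny", c(chr = strrep("AT", 25000)))
  expect_equal(summarize_genome(g2, fake_pqs(100))$freq_per_kbp, 2.0)
  expect_equal(summarize_genome(g2, fake_pqs(0))$freq_per_kbp, 0)
})

test_that("bin counts in a summary sum to the PQS total", {
  p <- scan_params()
  pqs <- fake_pqs(10, score = c(1.21, 1.25, -1.3, 1.45, 1.59, 1.7, -1.82,
                                1.95, 2.2, 3.0))
  g <- genome_record("g", c(chr = strrep("A", 10000)))
  s <- summarize_genome(g, pqs, p)
  counts <- unlist(s[grep("^n_", names(s))])
  expect_identical(unname(counts),
                   c(3L, 2L, 1L, 2L, 2L))
  expect_identical(sum(counts), s$pqs_total)
  expect_equal(unname(unlist(s[grep("^f_", names(s))])),
               1000 * counts / 10000, ignore_attr = TRUE)
})

test_that("group aggregation matches an independent recomputation", {
  set.seed(31)
  n <- 9
  summaries <- data.frame(
    genome_id = paste0("g", 1:n),
    group = rep(c("A", "B", "C"), each = 3),
    subgroup = rep(c("a1", "b1", "c1"), each = 3),
    total_length = c(1e6, 2e6, 3e6, 5e5, 1.5e6, 2.5e6, 1e6, 1e6, 4e6),
    gc_percent = runif(n, 30, 70),
    pqs_total = rpois(n, 500),
    stringsAsFactors = FALSE)
  summaries$freq_per_kbp <- 1000 * summaries$pqs_total / summaries$total_length
  gs <- summarize_group(summaries, level = "group")
  expect_identical(gs$group, c("A", "B", "C"))
  for (g in c("A", "B", "C")) {
    s <- summaries[summaries$group == g, ]
    row <- gs[gs$group == g, ]
    expect_identical(row$n_genomes, nrow(s))
    expect_equal(row$median_length, median(s$total_length))
    expect_equal(row$shortest, min(s$total_length))
    expect_equal(row$longest, max(s$total_length))
    expect_equal(row$mean_gc, mean(s$gc_percent))
    expect_equal(row$pqs_total, sum(s$pqs_total))
    expect_equal(row$mean_f, mean(s$freq_per_kbp))
    expect_equal(row$min_f, min(s$freq_per_kbp))
    expect_equal(row$max_f, max(s$freq_per_kbp))
    expect_true(row$min_f <= row$mean_f && row$mean_f <= row$max_f)
  }
  # median of {1,2,3} Mbp is 2 Mbp
  expect_equal(gs$median_length[1], 2e6)
  # single genome: median = short = long, mean = min = max
  one <- summarize_group(summaries[1, ], level = "group")
  expect_equal(one$median_length, one$shortest)
  expect_equal(one$median_length, one$longest)
  expect_equal(one$mean_f, one$min_f)
  # pooled alternative divides pooled counts by pooled length
  pooled <- summarize_group(summaries, level = "group",
                            mean_f_method = "pooled")
  expect_equal(pooled$mean_f[1],
               1000 * sum(summaries$pqs_total[1:3]) /
                 sum(summaries$total_length[1:3]))
})

test_that("Kruskal-Wallis H matches the hand-ranked two-group example", {
  kw <- kruskal_wallis(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3),
                       min_group_size = 3)
  # ranks 1..6: H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7 = 27/7
  expect_equal(kw$H, 27 / 7, tolerance = 1e-9)
  expect_identical(kw$df, 1L)
  expect_equal(kw$p_value, stats::pchisq(27 / 7, 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("Kruskal-Wallis agrees with independent rank-sum recomputation", {
  set.seed(17)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    g <- rep(letters[1:k], times = sample(5:12, k, TRUE))
    v <- round(rnorm(length(g)), sample(0:2, 1))  # rounding induces ties
    kw <- kruskal_wallis(v, g, min_group_size = 2)
    expect_equal(kw$H, manual_kw_H(v, g), tolerance = 1e-9)
    kt <- stats::kruskal.test(v, factor(g))
    expect_equal(kw$p_value, kt$p.value, tolerance = 1e-12)
  }
})

test_that("all-tied input is the defined degenerate case H = 0, p = 1", {
  kw <- kruskal_wallis(rep(5, 6), rep(c("a", "b"), each = 3),
                       min_group_size = 3)
  expect_identical(kw$H, 0)
  expect_identical(kw$p_value, 1)
  expect_false(kw$significant)
})

test_that("undersized groups are excluded before ranking", {
  v <- c(rnorm(12), rnorm(11), rnorm(4) + 100)
  g <- rep(c("big1", "big2", "small"), c(12, 11, 4))
  kw <- kruskal_wallis(v, g, min_group_size = 10)
  expect_identical(kw$k, 2L)
  expect_identical(kw$excluded, "small")
  # the extreme 'small' values never entered the ranking
  expect_equal(kw$H, manual_kw_H(v[g != "small"], g[g != "small"]),
               tolerance = 1e-9)
  expect_error(kruskal_wallis(v, g, min_group_size = 12),
               "fewer than 2 groups")
})

test_that("a planted five-fold density shift is detected", {
  set.seed(23)
  rejected <- vapply(1:50, function(i) {
    a <- rpois(10, 20)
    b <- rpois(10, 100)
    kruskal_wallis(c(a, b), rep(c("a", "b"), each = 10))$significant
  }, logical(1))
  expect_gt(mean(rejected), 0.95)
})

test_that("max-normalization flags strictly above half of the maximum", {
  nf <- normalize_and_flag(c(2, 4, 1))
  expect_equal(nf$normalized, c(0.5, 1.0, 0.25))
  expect_identical(nf$outlier, c(FALSE, TRUE, FALSE))  # 0.5 is not flagged
  one <- normalize_and_flag(3.7)
  expect_equal(one$normalized, 1.0)
  expect_true(one$outlier)
  zero <- normalize_and_flag(c(0, 0, 0))
  expect_equal(zero$normalized, c(0, 0, 0))
  expect_false(any(zero$outlier))
  # scale invariance
  nf2 <- normalize_and_flag(c(2, 4, 1) * 17.3)
  expect_equal(nf2$normalized, nf$normalized)
})

test_that("the score-bin census totals counts over the whole cohort", {
  p <- scan_params()
  g1 <- genome_record("g1", c(chr = strrep("A", 40000)))
  g2 <- genome_record("g2", c(chr = strrep("A", 60000)))
  s <- rbind(summarize_genome(g1, fake_pqs(6, c(1.25, 1.25, 1.5, 1.7, 1.9, 2.4)), p),
             summarize_genome(g2, fake_pqs(4, c(1.3, 1.45, 1.45, 2.1)), p))
  census <- score_bin_census(s, p)
  expect_identical(census$bin, p$bin_labels)
  expect_equal(census$pqs_count, c(3, 3, 1, 1, 2))
  expect_equal(census$freq_per_kbp, 1000 * census$pqs_count / 100000)
  expect_equal(sum(census$pqs_count), sum(s$pqs_total))
})
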