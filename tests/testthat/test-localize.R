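feat <- function(start, end, strand = "+", class = "gene", seq_id = "chr") {
  data.frame(seq_id = seq_id, feature_class = class, start = start,
             end = end, strand = strand, stringsAsFactors = FALSE)
}
pqs_at <- function(start, end, seq_id = "chr") {
  n <- length(start)
  data.frame(seq_id = rep_len(seq_id, n), start = start, end = end,
             strand = rep("+", n), score = rep(1.5, n),
             sequence = rep("", n), stringsAsFactors = FALSE)
}

test_that("zones are flank-wide, strand-oriented and boundary-truncated", {
  L <- c(chr = 10000)
  z <- zone_intervals(feat(1000, 2000, "+"), flank = 100, seq_lengths = L)
  expect_identical(z$zone, c("before", "inside", "after"))
  expect_equal(z$start, c(900, 1000, 2000))
  expect_equal(z$end, c(1000, 2000, 2100))

  zm <- zone_intervals(feat(1000, 2000, "-"), flank = 100, seq_lengths = L)
  expect_equal(zm[zm$zone == "before", c("start", "end")],
               data.frame(start = 2000, end = 2100), ignore_attr = TRUE)
  expect_equal(zm[zm$zone == "after", c("start", "end")],
               data.frame(start = 900, end = 1000), ignore_attr = TRUE)

  zt <- zone_intervals(feat(30, 200, "+"), flank = 100, seq_lengths = L)
  expect_equal(zt[zt$zone == "before", "start"], 0)
  expect_equal(zt[zt$zone == "before", "length"], 30)
  ze <- zone_intervals(feat(9950, 9990, "+"), flank = 100, seq_lengths = L)
  expect_equal(ze[ze$zone == "after", "end"], 10000)

  # unknown strand oriented as plus; genomic orientation ignores strand
  zu <- zone_intervals(feat(1000, 2000, "?"), flank = 100, seq_lengths = L)
  expect_equal(zu[zu$zone == "before", "start"], 900)
  zg <- zone_intervals(feat(1000, 2000, "-"), flank = 100, seq_lengths = L,
                       orientation = "genomic")
  expect_equal(zg[zg$zone == "before", "start"], 900)
})

test_that("a PQS joins every zone it overlaps by at least one base", {
  z <- zone_intervals(feat(1000, 2000, "+"), flank = 100,
                      seq_lengths = c(chr = 10000))
  expect_identical(assign_pqs(pqs_at(950, 975), z), "before")
  expect_setequal(assign_pqs(pqs_at(980, 1010), z), c("before", "inside"))
  expect_identical(assign_pqs(pqs_at(5000, 5030), z), character(0))
  expect_identical(assign_pqs(pqs_at(950, 975, seq_id = "other"), z),
                   character(0))
  # 1 bp overlap counts; abutting does not
  expect_identical(assign_pqs(pqs_at(899, 901), z), "before")
  expect_identical(assign_pqs(pqs_at(880, 900), z), character(0))
})

test_that("single fully-inside PQS produces the definitional frequency", {
  tab <- zone_frequency_table(pqs_at(1200, 1230), feat(1000, 2000),
                              seq_lengths = c(chr = 10000), flank = 100)
  inside <- tab[tab$zone == "inside", ]
  expect_identical(inside$pqs_count, 1L)
  expect_equal(inside$freq_per_kbp, 1000 / 1000)
  expect_identical(tab[tab$zone != "inside", "pqs_count"], c(0L, 0L))
  expect_equal(sum(tab$total_length_bp), 1000 + 2 * 100)
})

test_that("PQS planted upstream of tRNAs dominate the (tRNA, before) cell", {
  # construction oracle: 10 tRNAs, one 30 bp PQS 50 bp upstream of each
  starts <- seq(1000, by = 800, length.out = 10)
  feats <- rbind(feat(starts, starts + 80, class = "tRNA"),
                 feat(starts + 400, starts + 600, class = "gene"))
  pqs <- pqs_at(starts - 80, starts - 50)
  tab <- zone_frequency_table(pqs, feats, seq_lengths = c(chr = 20000),
                              flank = 100)
  cell <- tab[tab$feature_class == "tRNA" & tab$zone == "before", ]
  expect_identical(cell$pqs_count, 10L)
  expect_identical(cell$n_features, 10L)
  expect_equal(cell$total_length_bp, 10 * 100)
  others <- tab[!(tab$feature_class == "tRNA" & tab$zone == "before"), ]
  expect_true(all(others$pqs_count == 0))
  expect_gt(cell$freq_per_kbp, max(others$freq_per_kbp))
})

test_that("widening the flank captures more distant upstream PQS", {
  starts <- seq(1000, by = 800, length.out = 5)
  feats <- feat(starts, starts + 80, class = "tRNA")
  pqs <- pqs_at(starts - 180, starts - 150)  # 150 bp upstream
  t100 <- zone_frequency_table(pqs, feats, c(chr = 10000), flank = 100)
  t200 <- zone_frequency_table(pqs, feats, c(chr = 10000), flank = 200)
  expect_identical(t100[t100$zone == "before", "pqs_count"], 0L)
  expect_identical(t200[t200$zone == "before", "pqs_count"], 5L)
})

test_that("flank 0 removes before/after without touching inside counts", {
  starts <- seq(1000, by = 500, length.out = 8)
  feats <- feat(starts, starts + 100)
  pqs <- pqs_at(c(starts + 10, starts - 40), c(starts + 40, starts - 10))
  t0 <- zone_frequency_table(pqs, feats, c(chr = 10000), flank = 0)
  t100 <- zone_frequency_table(pqs, feats, c(chr = 10000), flank = 100)
  expect_identical(unique(t0$zone), "inside")
  expect_identical(t0[t0$zone == "inside", "pqs_count"],
                   t100[t100$zone == "inside", "pqs_count"])
})

test_that("a boundary-spanning PQS counts once in each zone it touches", {
  f <- feat(1000, 2000)
  tab <- zone_frequency_table(pqs_at(980, 1010), f, c(chr = 10000),
                              flank = 100)
  expect_identical(tab[tab$zone == "before", "pqs_count"], 1L)
  expect_identical(tab[tab$zone == "inside", "pqs_count"], 1L)
  expect_identical(tab[tab$zone == "after", "pqs_count"], 0L)
})

test_that("overlapping same-class features are each counted independently", {
  feats <- rbind(feat(1000, 2000), feat(1500, 2500))
  tab <- zone_frequency_table(pqs_at(1600, 1650), feats, c(chr = 10000),
                              flank = 100)
  expect_identical(tab[tab$zone == "inside", "pqs_count"], 2L)
  expect_identical(tab[tab$zone == "inside", "n_features"], 2L)
})

test_that("zone lengths match an independent truncated-interval sum", {
  set.seed(33)
  L <- c(chr = 5000)
  starts <- sort(sample(0:4900, 20))
  feats <- feat(starts, pmin(starts + sample(50:300, 20, TRUE), 5000),
                strand = sample(c("+", "-"), 20, TRUE))
  tab <- zone_frequency_table(empty <- pqs_at(integer(0), integer(0)),
                              feats, L, flank = 100)
  indep <- sum(pmin(feats$end + 100, 5000) - feats$end) +
    sum(feats$start - pmax(feats$start - 100, 0)) +
    sum(feats$end - feats$start)
  expect_equal(sum(tab$total_length_bp), indep)
})

test_that("results are invariant to feature and PQS row order", {
  set.seed(14)
  starts <- sample(seq(500, 9000, by = 400))
  feats <- feat(starts, starts + 120,
                class = sample(c("gene", "tRNA"), length(starts), TRUE))
  pqs <- pqs_at(starts - 60, starts - 20)
  t1 <- zone_frequency_table(pqs, feats, c(chr = 10000))
  shuffle <- sample(nrow(feats))
  t2 <- zone_frequency_table(pqs[sample(nrow(pqs)), ], feats[shuffle, ],
                             c(chr = 10000))
  expect_equal(t1, t2)
})

test_that("no features yields an empty table with a warning", {
  expect_warning(
    tab <- zone_frequency_table(pqs_at(10, 40), feat(1, 2)[0, ],
                                c(chr = 1000)),
    "no features")
  expect_identical(nrow(tab), 0L)
})
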