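# Independent oracles: deliberately naive re-derivations of the scoring,
# merging and rank-test rules, sharing no code path with the package.

# Per-base scores by scanning left/right from each position for its run.
naive_base_scores <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  vapply(seq_len(n), function(i) {
    b <- ch[i]
    if (b != "G" && b != "C") return(0)
    j <- i
    while (j > 1 && ch[j - 1] == b) j <- j - 1
    k <- i
    while (k < n && ch[k + 1] == b) k <- k + 1
    sign <- if (b == "G") 1 else -1
    sign * min(k - j + 1, 4)
  }, numeric(1))
}

# Merged PQS by exhaustive window enumeration + coverage-vector union,
# one sign at a time; regions re-scored over their full extent.
brute_pqs <- function(seq, W = 25, threshold = 1.2) {
  sc <- naive_base_scores(seq)
  L <- length(sc)
  if (L < W) return(data.frame(start = integer(0), end = integer(0),
                               strand = character(0), score = numeric(0)))
  means <- vapply(1:(L - W + 1), function(k) mean(sc[k:(k + W - 1)]),
                  numeric(1))
  one_sign <- function(qualify, strand) {
    cov <- logical(L)
    for (k in which(qualify)) cov[k:(k + W - 1)] <- TRUE
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (!length(keep)) return(NULL)
    data.frame(start = as.integer(starts[keep] - 1L),
               end = as.integer(ends[keep]),
               strand = strand,
               score = vapply(keep, function(i) {
                 mean(sc[starts[i]:ends[i]])
               }, numeric(1)))
  }
  out <- rbind(one_sign(means >= threshold, "+"),
               one_sign(means <= -threshold, "-"))
  if (is.null(out)) return(data.frame(start = integer(0), end = integer(0),
                                      strand = character(0),
                                      score = numeric(0)))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Tie-corrected Kruskal-Wallis H recomputed from first principles.
manual_kw_H <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  groups <- as.character(groups)
  Rj <- tapply(r, groups, sum)
  nj <- tapply(r, groups, length)
  H <- 12 / (n * (n + 1)) * sum(Rj^2 / nj) - 3 * (n + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# The perfect-repeat quadruplex motif used as the standard plant.
repeat_motif <- function(n = 8) strrep("GGGGTGT", n)
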