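#' PQS frequency per 1000 bp
#'
#' The survey's density unit: `1000 * count / length_bp` (PQS/kbp).
#'
#' @param count Number of PQS.
#' @param length_bp Sequence length in bp (> 0).
#' @return Frequency in PQS per 1000 bp.
#' @examples
#' pqs_frequency(40, 3192399)  # ~0.0125
#' @export
pqs_frequency <- function(count, length_bp) {
  if (any(length_bp <= 0)) stop("'length_bp' must be positive")
  1000 * count / length_bp
}

bin_count_cols <- function(params) {
  paste0("n_", gsub("[.]", "", gsub("-", "_", params$bin_labels)))
}

#' Per-genome PQS summary
#'
#' One summary row per genome: assembly length, GC content, total PQS,
#' counts per score bin, and frequencies per 1000 bp (overall and per
#' bin, computed over the total assembly length).
#'
#' @param genome A [genome_record()].
#' @param pqs PQS data frame called from this genome.
#' @param params The [scan_params()] used.
#' @param group,subgroup Optional taxonomic labels carried through to
#'   cohort aggregation.
#' @return One-row data frame (class `"genome_summary"` rows bind into a
#'   plain data frame).
#' @export
summarize_genome <- function(genome, pqs, params = scan_params(),
                             group = NA_character_,
                             subgroup = NA_character_) {
  if (!inherits(genome, "genome_record")) stop("'genome' must be a genome_record")
  L <- genome$total_length
  bins <- if (nrow(pqs)) bin_score_clamped(pqs$score, params) else character(0)
  counts <- vapply(params$bin_labels, function(b) sum(bins == b), integer(1))
  cols <- bin_count_cols(params)
  out <- data.frame(genome_id = genome$genome_id, group = group,
                    subgroup = subgroup, total_length = L,
                    gc_percent = gc_content(genome),
                    pqs_total = nrow(pqs),
                    freq_per_kbp = pqs_frequency(nrow(pqs), L),
                    stringsAsFactors = FALSE)
  out[cols] <- as.list(counts)
  out[sub("^n_", "f_", cols)] <- as.list(pqs_frequency(counts, L))
  out
}

#' Aggregate genome summaries by taxonomic group
#'
#' Per group: number of genomes, median/shortest/longest genome length,
#' mean GC content (unweighted), total PQS, and mean/min/max per-genome
#' frequency. The mean frequency is the unweighted mean of per-genome
#' frequencies by default; `mean_f_method = "pooled"` instead divides
#' pooled PQS counts by pooled length.
#'
#' @param summaries Data frame of rows from [summarize_genome()].
#' @param level `"group"` or `"subgroup"`: which label to aggregate on.
#' @param mean_f_method `"unweighted"` (default) or `"pooled"`.
#' @return Data frame with one row per group, in first-appearance order.
#' @export
summarize_group <- function(summaries, level = c("group", "subgroup"),
                            mean_f_method = c("unweighted", "pooled")) {
  level <- match.arg(level)
  mean_f_method <- match.arg(mean_f_method)
  lab <- summaries[[level]]
  keep <- !is.na(lab) & nzchar(lab)
  if (!all(keep)) {
    warning(sum(!keep), " genome(s) without a ", level, " label skipped")
    summaries <- summaries[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  if (nrow(summaries) == 0L) stop("no labeled genomes to aggregate")
  groups <- unique(lab)
  rows <- lapply(groups, function(g) {
    s <- summaries[lab == g, , drop = FALSE]
    data.frame(
      group = g,
      n_genomes = nrow(s),
      median_length = stats::median(s$total_length),
      shortest = min(s$total_length),
      longest = max(s$total_length),
      mean_gc = mean(s$gc_percent),
      pqs_total = sum(s$pqs_total),
      mean_f = if (mean_f_method == "unweighted") mean(s$freq_per_kbp)
               else pqs_frequency(sum(s$pqs_total), sum(s$total_length)),
      min_f = min(s$freq_per_kbp),
      max_f = max(s$freq_per_kbp),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis comparison of PQS frequencies across groups
#'
#' Rank-based k-sample test of per-genome PQS frequencies between
#' taxonomic groups. Groups with fewer than `min_group_size` genomes are
#' excluded before ranking (the survey convention: only groups with 10
#' or more sequenced genomes). The H statistic is tie-corrected and the
#' p-value uses the chi-square approximation with k-1 degrees of
#' freedom. When every retained value is identical the statistic is
#' defined as H = 0 with p = 1.
#'
#' @param values Numeric vector of per-genome frequencies.
#' @param groups Group label per value.
#' @param min_group_size Minimum genomes per group (default 10).
#' @param alpha Significance cut-off (default 0.05).
#' @return An object of class `"kw_test"`: list with `k`, `n`,
#'   `group_sizes`, `H`, `df`, `p_value`, `significant`, `alpha`,
#'   `excluded` (names of groups dropped by the size filter).
#' @examples
#' kruskal_wallis(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3),
#'                min_group_size = 3)
#' @export
kruskal_wallis <- function(values, groups, min_group_size = 10L,
                           alpha = 0.05) {
  if (length(values) != length(groups))
    stop("'values' and 'groups' must have equal length")
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  sizes <- table(groups)
  eligible <- names(sizes)[sizes >= min_group_size]
  excluded <- setdiff(names(sizes), eligible)
  if (length(eligible) < 2L)
    stop("fewer than 2 groups with >= ", min_group_size,
         " genomes: cannot test")
  keep <- groups %in% eligible
  v <- values[keep]; g <- factor(groups[keep], levels = eligible)
  if (length(unique(v)) == 1L) {
    H <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(v, g)
    H <- unname(kt$statistic)
    p <- kt$p.value
  }
  structure(list(k = length(eligible), n = length(v),
                 group_sizes = as.integer(sizes[eligible]),
                 H = H, df = length(eligible) - 1L, p_value = p,
                 significant = p < alpha, alpha = alpha,
                 excluded = excluded),
            class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat("Kruskal-Wallis rank sum test\n")
  cat(sprintf("  k = %d groups (n = %d), H = %.4f, df = %d, p = %.4g\n",
              x$k, x$n, x$H, x$df, x$p_value))
  cat(sprintf("  %s at alpha = %g\n",
              if (x$significant) "significant" else "not significant",
              x$alpha))
  if (length(x$excluded))
    cat("  excluded (too few genomes):", paste(x$excluded, collapse = ", "),
        "\n")
  invisible(x)
}

#' Max-normalize frequencies and flag outliers
#'
#' Within one score bin, divides each per-genome frequency by the
#' highest observed frequency and flags genomes whose normalized value
#' exceeds 0.5 (strictly greater than 50% of the maximum). An all-zero
#' bin normalizes to all zeros with no flags.
#'
#' @param frequencies Numeric vector of per-genome frequencies (>= 0).
#' @param cutoff Flagging cut-off on the normalized scale (default 0.5,
#'   strict inequality).
#' @return Data frame with columns `frequency`, `normalized`, `outlier`.
#' @examples
#' normalize_and_flag(c(2, 4, 1))
#' @export
normalize_and_flag <- function(frequencies, cutoff = 0.5) {
  if (!length(frequencies)) stop("empty bin: nothing to normalize")
  if (any(frequencies < 0)) stop("frequencies must be non-negative")
  m <- max(frequencies)
  normalized <- if (m == 0) rep(0, length(frequencies)) else frequencies / m
  data.frame(frequency = frequencies, normalized = normalized,
             outlier = normalized > cutoff)
}

#' Score-bin census across a cohort
#'
#' Totals PQS per score interval over all genomes and converts to
#' frequencies per 1000 bp of total analyzed sequence, the cohort-level
#' census layout.
#'
#' @param summaries Data frame of rows from [summarize_genome()].
#' @param params The [scan_params()] used.
#' @return Data frame with columns `bin`, `pqs_count`, `freq_per_kbp`.
#' @export
score_bin_census <- function(summaries, params = scan_params()) {
  cols <- bin_count_cols(params)
  total_len <- sum(summaries$total_length)
  counts <- vapply(cols, function(cl) sum(summaries[[cl]]), numeric(1))
  data.frame(bin = params$bin_labels,
             pqs_count = as.numeric(counts),
             freq_per_kbp = pqs_frequency(counts, total_len),
             row.names = NULL, stringsAsFactors = FALSE)
}
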