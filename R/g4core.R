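#' Scan parameters for PQS calling
#'
#' Bundles the G4Hunter scan settings: sliding-window size, detection
#' threshold, and the score intervals used to census called regions by
#' predicted stability. Defaults are the standard survey settings: window
#' 25 bp, threshold 1.2, bins 1.2-1.4, 1.4-1.6, 1.6-1.8, 1.8-2.0 and
#' 2.0-more (half-open, last bin unbounded above).
#'
#' @param window_size Sliding-window width in bp (integer, >= 2).
#' @param threshold Minimum window |score| for a window to qualify (> 0).
#' @param bin_bounds Increasing numeric vector of score-bin lower bounds;
#'   the first bound must equal `threshold`. Bins are left-closed,
#'   right-open; the last bin is unbounded above.
#' @return An object of class `"scan_params"`.
#' @examples
#' scan_params()
#' scan_params(window_size = 20, threshold = 1.5, bin_bounds = c(1.5, 2))
#' @export
scan_params <- function(window_size = 25L, threshold = 1.2,
                        bin_bounds = c(1.2, 1.4, 1.6, 1.8, 2.0)) {
  window_size <- as.integer(window_size)
  if (length(window_size) != 1L || is.na(window_size) || window_size < 2L)
    stop("'window_size' must be a single integer >= 2")
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0)
    stop("'threshold' must be a single positive number")
  if (!is.numeric(bin_bounds) || length(bin_bounds) < 1L ||
      anyNA(bin_bounds) || is.unsorted(bin_bounds, strictly = TRUE))
    stop("'bin_bounds' must be a strictly increasing numeric vector")
  if (abs(bin_bounds[1L] - threshold) > 1e-12)
    stop("score bins must start at the detection threshold")
  nb <- length(bin_bounds)
  b <- format(bin_bounds, trim = TRUE)  # common decimals: 2 prints as "2.0"
  labels <- c(if (nb > 1L) paste0(b[-nb], "-", b[-1L]),
              paste0(b[nb], "-more"))
  structure(
    list(window_size = window_size, threshold = threshold,
         bin_bounds = as.numeric(bin_bounds), bin_labels = labels),
    class = "scan_params"
  )
}

#' @export
print.scan_params <- function(x, ...) {
  cat("G4Hunter scan parameters\n")
  cat("  window size :", x$window_size, "bp\n")
  cat("  threshold   :", x$threshold, "\n")
  cat("  score bins  :", paste(x$bin_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Per-base G4Hunter scores
#'
#' Scores each position of a nucleotide sequence by its G/C run context:
#' every base inside a run of n consecutive G scores `+min(n, 4)`, every
#' base inside a run of n consecutive C scores `-min(n, 4)`, all other
#' positions score 0. Case-insensitive; `U` is treated like `T` (neither
#' is G or C) and any non-ACGT symbol scores 0 and breaks a run.
#'
#' @param sequence A single non-empty nucleotide string.
#' @return Integer vector of per-base scores in `[-4, 4]`, one per position.
#' @examples
#' base_scores("GGGGG")  # 4 4 4 4 4
#' base_scores("CCG")    # -2 -2 1
#' @export
base_scores <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence))
    stop("'sequence' must be a single non-empty string")
  v <- utf8ToInt(toupper(sequence))
  code <- integer(length(v))
  code[v == 71L] <- 1L   # G
  code[v == 67L] <- -1L  # C
  r <- rle(code)
  contrib <- r$values * pmin(r$lengths, 4L)
  rep.int(contrib, r$lengths)
}

#' Sliding-window mean scores
#'
#' Mean of the per-base scores over every window of `window_size`
#' consecutive positions. A sequence shorter than the window yields an
#' empty result with a warning (the genome is still counted, with 0 PQS),
#' so plasmid-bearing assemblies aggregate cleanly.
#'
#' @param scores Integer/numeric vector of per-base scores
#'   (see [base_scores()]).
#' @param params A [scan_params()] object.
#' @return Numeric vector of `length(scores) - window_size + 1` window
#'   means (empty if the sequence is shorter than the window).
#' @examples
#' window_scores(base_scores(strrep("GGGGTGT", 4)), scan_params())[1]  # 2.68
#' @export
window_scores <- function(scores, params = scan_params()) {
  W <- params$window_size
  L <- length(scores)
  if (L < W) {
    warning(sprintf("sequence length %d < window size %d: no windows scored",
                    L, W))
    return(numeric(0))
  }
  cs <- c(0, cumsum(as.numeric(scores)))
  (cs[(W + 1L):(L + 1L)] - cs[1L:(L - W + 1L)]) / W
}

# Merge sorted 0-based window starts into maximal regions: windows k and k'
# merge when their [k, k+W) intervals overlap or touch, i.e. k' <= k + W.
merge_window_starts <- function(k0, W) {
  if (!length(k0)) return(NULL)
  new_run <- c(TRUE, k0[-1L] > k0[-length(k0)] + W)
  grp <- cumsum(new_run)
  data.frame(start = k0[new_run],
             end = as.integer(tapply(k0, grp, max)) + W)
}

empty_pqs <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), score = numeric(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

#' Call putative quadruplex-forming sequences (PQS)
#'
#' Scans a sequence with the G4Hunter sliding window and reports merged
#' regions whose window mean score reaches the threshold. Windows with
#' mean `>= threshold` qualify on the plus strand, windows with mean
#' `<= -threshold` on the minus strand (C-rich regions: the quadruplex
#' would form on the complementary strand). Overlapping or adjacent
#' qualifying windows of the same sign are merged into one maximal
#' region, which is re-scored as the mean per-base score over its full
#' extent. Regions of opposite sign never merge.
#'
#' @param sequence A single nucleotide string.
#' @param params A [scan_params()] object.
#' @param seq_id Identifier recorded for the scanned sequence.
#' @return A data frame with one row per PQS and columns `seq_id`,
#'   `start`, `end` (0-based half-open), `strand` (`"+"`/`"-"`), `score`
#'   (signed mean base score over the merged extent) and `sequence`,
#'   sorted by start. Zero rows when nothing qualifies.
#' @examples
#' call_pqs(paste0(strrep("AT", 50), strrep("GGGGTGT", 4), strrep("AT", 50)))
#' @export
call_pqs <- function(sequence, params = scan_params(), seq_id = "seq") {
  sc <- base_scores(sequence)
  w <- window_scores(sc, params)
  if (!length(w)) return(empty_pqs())
  W <- params$window_size
  t <- params$threshold
  out <- list()
  for (sgn in c(1, -1)) {
    k0 <- which(if (sgn > 0) w >= t else w <= -t) - 1L
    reg <- merge_window_starts(k0, W)
    if (is.null(reg)) next
    score <- vapply(seq_len(nrow(reg)), function(i) {
      mean(sc[(reg$start[i] + 1L):reg$end[i]])
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      seq_id = seq_id, start = reg$start, end = reg$end,
      strand = if (sgn > 0) "+" else "-", score = score,
      sequence = substring(sequence, reg$start + 1L, reg$end),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty_pqs())
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assign a score to its census bin
#'
#' Places a signed PQS score into the score intervals of
#' [scan_params()] by its absolute value. Intervals are left-closed,
#' right-open; the last is unbounded above.
#'
#' @param score Numeric vector of signed scores with `|score| >=
#'   threshold`.
#' @param params A [scan_params()] object.
#' @return Character vector of bin labels (e.g. `"1.2-1.4"`).
#' @examples
#' bin_score(c(1.25, -1.40, 2.43))
#' @export
bin_score <- function(score, params = scan_params()) {
  a <- abs(score)
  if (anyNA(a) || any(a < params$threshold))
    stop("|score| below the detection threshold has no census bin")
  params$bin_labels[findInterval(a, params$bin_bounds)]
}

# Census-path binning: merged-region re-scoring can leave |score| a shade
# under the threshold; such regions stay in the lowest bin.
bin_score_clamped <- function(score, params = scan_params()) {
  params$bin_labels[pmax(findInterval(abs(score), params$bin_bounds), 1L)]
}

#' Reverse complement of a nucleotide string
#'
#' @param sequence Character vector of nucleotide strings (ACGT plus
#'   ambiguity codes; case preserved per base).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("GGT")  # "ACC"
#' @export
reverse_complement <- function(sequence) {
  vapply(sequence, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}
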