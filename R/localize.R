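#' Before/inside/after zones around a feature
#'
#' Builds the three neighborhood zones used to localize PQS relative to
#' an annotated feature: `inside` is the feature interval itself,
#' `before` and `after` are flanks of at most `flank` bp, truncated at
#' the sequence boundaries. With `orientation = "strand"` (default),
#' "before" is the feature's 5' side: upstream on the annotated strand
#' (features with unknown strand are oriented as plus). With
#' `orientation = "genomic"`, "before" is always the genomic-left flank.
#'
#' @param features Feature data frame (`seq_id`, `feature_class`,
#'   `start`, `end`, `strand`; 0-based half-open).
#' @param flank Flank width in bp (>= 0); default 100.
#' @param seq_lengths Named numeric vector of sequence lengths by
#'   `seq_id`, used for boundary truncation.
#' @param orientation `"strand"` (upstream/downstream) or `"genomic"`
#'   (left/right).
#' @return Data frame with one row per (feature, zone): `feature_id`
#'   (row index into `features`), `feature_class`, `seq_id`, `zone`
#'   (`before`/`inside`/`after`), `start`, `end`, `length`.
#' @examples
#' f <- data.frame(seq_id = "chr", feature_class = "gene",
#'                 start = 1000, end = 2000, strand = "+")
#' zone_intervals(f, flank = 100, seq_lengths = c(chr = 10000))
#' @export
zone_intervals <- function(features, flank = 100L,
                           seq_lengths,
                           orientation = c("strand", "genomic")) {
  orientation <- match.arg(orientation)
  if (flank < 0) stop("'flank' must be >= 0")
  n <- nrow(features)
  if (is.null(n) || n == 0L) {
    return(data.frame(feature_id = integer(0), feature_class = character(0),
                      seq_id = character(0), zone = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  L <- unname(seq_lengths[features$seq_id])
  if (anyNA(L)) stop("missing sequence length for seq_id(s): ",
                     paste(unique(features$seq_id[is.na(L)]), collapse = ", "))
  left_start <- pmax(features$start - flank, 0)
  left_end <- features$start
  right_start <- features$end
  right_end <- pmin(features$end + flank, L)
  minus <- orientation == "strand" & features$strand == "-"
  before_start <- ifelse(minus, right_start, left_start)
  before_end <- ifelse(minus, right_end, left_end)
  after_start <- ifelse(minus, left_start, right_start)
  after_end <- ifelse(minus, left_end, right_end)
  zones <- data.frame(
    feature_id = rep(seq_len(n), 3L),
    feature_class = rep(features$feature_class, 3L),
    seq_id = rep(features$seq_id, 3L),
    zone = rep(c("before", "inside", "after"), each = n),
    start = c(before_start, features$start, after_start),
    end = c(before_end, features$end, after_end),
    stringsAsFactors = FALSE
  )
  zones$length <- zones$end - zones$start
  zones[order(zones$feature_id, match(zones$zone,
                                      c("before", "inside", "after"))), ,
        drop = FALSE]
}

#' Zones overlapped by one PQS
#'
#' A PQS belongs to every zone it overlaps by at least 1 bp; a PQS
#' touching no zone yields an empty set.
#'
#' @param pqs A one-row PQS data frame (or list with `seq_id`, `start`,
#'   `end`).
#' @param zones Zone data frame from [zone_intervals()].
#' @return Character vector of the distinct zone labels overlapped.
#' @export
assign_pqs <- function(pqs, zones) {
  hit <- zones$seq_id == pqs$seq_id &
    pmax(zones$start, pqs$start) < pmin(zones$end, pqs$end)
  unique(zones$zone[hit])
}

# PQS-per-zone-interval overlap counts via IRanges; coordinates are
# 0-based half-open internally, shifted to 1-based closed for IRanges.
count_zone_overlaps <- function(zones, pqs) {
  counts <- integer(nrow(zones))
  nonzero <- which(zones$length > 0L)
  if (!length(nonzero) || nrow(pqs) == 0L) return(counts)
  for (sid in unique(zones$seq_id[nonzero])) {
    zi <- nonzero[zones$seq_id[nonzero] == sid]
    pi <- which(pqs$seq_id == sid & pqs$end > pqs$start)
    if (!length(pi)) next
    zr <- IRanges::IRanges(start = zones$start[zi] + 1L, end = zones$end[zi])
    pr <- IRanges::IRanges(start = pqs$start[pi] + 1L, end = pqs$end[pi])
    counts[zi] <- IRanges::countOverlaps(zr, pr, minoverlap = 1L)
  }
  counts
}

#' PQS frequency by feature class and zone
#'
#' Aggregates PQS counts per (feature class, zone) over all features:
#' each feature contributes its three zones independently; a PQS counts
#' once per zone interval it overlaps (by >= 1 bp), so it may appear in
#' several cells and in both zones it spans, but never twice in one zone
#' of one feature. Frequencies are per 1000 bp of summed (truncated)
#' zone length. Cells with zero total zone length are dropped.
#'
#' @param pqs PQS data frame (possibly spanning several genomes; seq_ids
#'   must match those of `features`).
#' @param features Feature data frame.
#' @param seq_lengths Named numeric vector of sequence lengths.
#' @param flank Flank width in bp (default 100).
#' @param orientation Passed to [zone_intervals()].
#' @return Data frame with columns `feature_class`, `zone`,
#'   `n_features`, `pqs_count`, `total_length_bp`, `freq_per_kbp`.
#' @export
zone_frequency_table <- function(pqs, features, seq_lengths, flank = 100L,
                                 orientation = c("strand", "genomic")) {
  orientation <- match.arg(orientation)
  empty <- data.frame(feature_class = character(0), zone = character(0),
                      n_features = integer(0), pqs_count = integer(0),
                      total_length_bp = numeric(0), freq_per_kbp = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(features) == 0L) {
    warning("no features: zone table is empty")
    return(empty)
  }
  zones <- zone_intervals(features, flank = flank, seq_lengths = seq_lengths,
                          orientation = orientation)
  zones$pqs_count <- count_zone_overlaps(zones, pqs)
  key <- interaction(zones$feature_class, zones$zone, drop = TRUE, sep = "\r")
  agg <- data.frame(
    key = levels(key),
    n_features = as.integer(tapply(zones$feature_id, key,
                                   function(i) length(unique(i)))),
    pqs_count = as.integer(tapply(zones$pqs_count, key, sum)),
    total_length_bp = as.numeric(tapply(zones$length, key, sum)),
    stringsAsFactors = FALSE
  )
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  agg$feature_class <- vapply(parts, `[`, "", 1L)
  agg$zone <- vapply(parts, `[`, "", 2L)
  agg <- agg[agg$total_length_bp > 0, , drop = FALSE]
  agg$freq_per_kbp <- 1000 * agg$pqs_count / agg$total_length_bp
  agg <- agg[order(agg$feature_class,
                   match(agg$zone, c("before", "inside", "after"))), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg[c("feature_class", "zone", "n_features", "pqs_count",
        "total_length_bp", "freq_per_kbp")]
}

#' Write a zone-frequency table
#'
#' @param tab Table from [zone_frequency_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zone_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
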