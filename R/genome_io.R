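#' Construct a genome record
#'
#' A genome record groups the sequences of one assembly (chromosome(s)
#' plus any plasmids) under a single genome identifier.
#'
#' @param genome_id Genome/assembly identifier.
#' @param sequences Named character vector of nucleotide sequences; names
#'   are the per-sequence identifiers and must be unique.
#' @return An object of class `"genome_record"` with elements
#'   `genome_id`, `sequences` and `total_length`.
#' @export
genome_record <- function(genome_id, sequences) {
  if (!is.character(genome_id) || length(genome_id) != 1L || !nzchar(genome_id))
    stop("'genome_id' must be a single non-empty string")
  if (!is.character(sequences) || length(sequences) == 0L || anyNA(sequences))
    stop("'sequences' must be a non-empty character vector")
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("sequences must carry unique non-empty names (seq_ids)")
  total <- sum(nchar(sequences))
  if (total == 0L) stop("genome has zero total length")
  structure(list(genome_id = genome_id, sequences = sequences,
                 total_length = total),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("Genome '%s': %d sequence(s), %s bp, GC %.1f%%\n",
              x$genome_id, length(x$sequences),
              format(x$total_length, big.mark = ","), gc_content(x)))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' @param path Path to a FASTA file (one or more records).
#' @param genome_id Genome identifier; defaults to the file name without
#'   extension.
#' @return A [genome_record()]. Residues are upper-cased; record order is
#'   preserved; seq_ids are the first whitespace-delimited word of each
#'   header.
#' @export
read_genome_fasta <- function(path,
                              genome_id = sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                                              basename(path))) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("malformed FASTA '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  if (length(x) == 0L)
    stop("FASTA file '", path, "' contains no records")
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  genome_record(genome_id, seqs)
}

#' Write sequences to a FASTA file
#'
#' @param x A [genome_record()] or named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- if (inherits(x, "genome_record")) x$sequences else x
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' Read an NCBI feature table
#'
#' Parses the tab-delimited `*_feature_table.txt` dialect distributed
#' with NCBI assemblies (header line starting `# feature`). Feature
#' classes are kept verbatim from the `feature` column; 1-based inclusive
#' coordinates are converted to the internal 0-based half-open
#' convention; rows whose coordinates do not parse are skipped with a
#' message; start/end swapped in the file are normalized. Gene/CDS
#' duplicate rows are kept as distinct features under their own classes.
#'
#' @param path Path to the feature table.
#' @return A data frame of features with columns `seq_id`,
#'   `feature_class`, `start`, `end` (0-based half-open) and `strand`
#'   (`"+"`, `"-"` or `"?"` for unknown).
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  header <- readLines(path, n = 1L)
  if (!length(header) || !grepl("^#\\s*feature", header))
    stop("not an NCBI feature table (header must start '# feature'): ", path)
  cols <- strsplit(sub("^#\\s*", "", header), "\t")[[1]]
  required <- c("feature", "genomic_accession", "start", "end", "strand")
  if (!all(required %in% cols))
    stop("feature table missing mandatory column(s): ",
         paste(setdiff(required, cols), collapse = ", "))
  tab <- utils::read.delim(path, header = FALSE, skip = 1L,
                           col.names = make.names(cols), sep = "\t",
                           quote = "", comment.char = "",
                           colClasses = "character")
  if (nrow(tab) == 0L) {
    return(data.frame(seq_id = character(0), feature_class = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  start <- suppressWarnings(as.integer(tab$start))
  end <- suppressWarnings(as.integer(tab$end))
  bad <- is.na(start) | is.na(end) | !nzchar(tab$feature)
  if (any(bad))
    message(sum(bad), " feature row(s) with unparsable coordinates skipped")
  tab <- tab[!bad, , drop = FALSE]
  start <- start[!bad]; end <- end[!bad]
  swapped <- start > end
  tmp <- start[swapped]; start[swapped] <- end[swapped]; end[swapped] <- tmp
  strand <- ifelse(tab$strand %in% c("+", "-"), tab$strand, "?")
  data.frame(seq_id = tab$genomic_accession, feature_class = tab$feature,
             start = start - 1L, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Write features as an NCBI-dialect feature table
#'
#' Emits the minimal tab-delimited dialect [read_feature_table()] parses
#' (1-based inclusive coordinates), so tables round-trip exactly.
#'
#' @param features Feature data frame (internal 0-based half-open
#'   coordinates, as returned by [read_feature_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  cols <- c("feature", "class", "assembly", "genomic_accession",
            "start", "end", "strand")
  out <- data.frame(feature = features$feature_class,
                    class = features$feature_class,
                    assembly = "synthetic",
                    genomic_accession = features$seq_id,
                    start = features$start + 1L,
                    end = features$end,
                    strand = ifelse(features$strand %in% c("+", "-"),
                                    features$strand, "?"),
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(cols, collapse = "\t")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' GC content of a genome or sequence
#'
#' Percentage of G+C over all residues of all sequences; non-ACGT symbols
#' count in the denominator only.
#'
#' @param x A [genome_record()] or character vector of sequences.
#' @return GC content in percent (0-100).
#' @examples
#' gc_content("GATC")  # 50
#' @export
gc_content <- function(x) {
  seqs <- if (inherits(x, "genome_record")) x$sequences else x
  if (!is.character(seqs) || length(seqs) == 0L)
    stop("'x' must be a genome_record or character vector")
  total <- sum(nchar(seqs))
  if (total == 0L) stop("zero-length genome has no GC content")
  gc <- sum(vapply(seqs, function(s) {
    v <- utf8ToInt(toupper(s))
    sum(v == 71L | v == 67L)
  }, numeric(1)))
  100 * gc / total
}

#' Write a PQS table
#'
#' Tab-delimited output with 1-based inclusive coordinates: `seq_id`,
#' `start`, `end`, `length`, `strand`, `score` (4 decimals), `bin`,
#' `sequence`; one row per PQS in deterministic (seq_id, start) order.
#'
#' @param pqs PQS data frame from [call_pqs()].
#' @param path Output path.
#' @param params The [scan_params()] used for the scan (for bin labels).
#' @return `path`, invisibly.
#' @export
write_pqs_table <- function(pqs, path, params = scan_params()) {
  pqs <- pqs[order(pqs$seq_id, pqs$start), , drop = FALSE]
  out <- data.frame(seq_id = pqs$seq_id,
                    start = pqs$start + 1L,
                    end = pqs$end,
                    length = pqs$end - pqs$start,
                    strand = pqs$strand,
                    score = sprintf("%.4f", pqs$score),
                    bin = if (nrow(pqs)) bin_score_clamped(pqs$score, params)
                          else character(0),
                    sequence = pqs$sequence,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PQS table written by [write_pqs_table()]
#'
#' @param path Path to a PQS table.
#' @return PQS data frame in internal (0-based half-open) coordinates.
#' @export
read_pqs_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", quote = "",
                           colClasses = c(seq_id = "character",
                                          strand = "character",
                                          sequence = "character"))
  data.frame(seq_id = tab$seq_id, start = tab$start - 1L, end = tab$end,
             strand = tab$strand, score = as.numeric(tab$score),
             sequence = tab$sequence, stringsAsFactors = FALSE)
}

#' Read a cohort manifest
#'
#' The manifest is a tab-delimited file with header columns `genome_id`,
#' `fasta_path`, `feature_table_path`, `group`, `subgroup`; paths are
#' resolved relative to the manifest's directory.
#'
#' @param path Manifest path.
#' @return Data frame with the five manifest columns (paths resolved).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.delim(path, sep = "\t", quote = "",
                         colClasses = "character")
  required <- c("genome_id", "fasta_path", "feature_table_path",
                "group", "subgroup")
  if (!all(required %in% names(m)))
    stop("manifest missing column(s): ",
         paste(setdiff(required, names(m)), collapse = ", "))
  if (nrow(m) == 0L) stop("manifest is empty: ", path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(nzchar(p) & !grepl("^/", p),
                                file.path(base, p), p)
  m$fasta_path <- resolve(m$fasta_path)
  m$feature_table_path <- resolve(m$feature_table_path)
  m[required]
}
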