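# Run `expr` under a temporary RNG state when `seed` is given, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Rejection-sample 0-based motif start positions keeping >= min_spacing bp
# between planted intervals.
place_motifs <- function(L, lens, min_spacing, max_tries = 5000L) {
  placed_start <- integer(0)
  placed_end <- integer(0)
  starts <- integer(length(lens))
  for (i in seq_along(lens)) {
    if (lens[i] > L) stop("motif ", i, " (", lens[i], " bp) exceeds genome length")
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(L - lens[i] + 1L, 1L) - 1L
      e <- s + lens[i]
      if (all(s >= placed_end + min_spacing | e + min_spacing <= placed_start)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf(paste0("could not place motif %d (%d bp) with min_spacing ",
                          "%d bp in a %d bp genome"), i, lens[i], min_spacing, L))
    placed_start <- c(placed_start, s)
    placed_end <- c(placed_end, e)
    starts[i] <- s
  }
  starts
}

#' Generate a synthetic genome with planted motifs
#'
#' Draws an i.i.d. background with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1-gc)/2` and overwrites planted motifs at explicit or
#' random positions (uniform subject to a minimum spacing between
#' plants), keeping the stated genome length exact. The returned ground
#' truth lists every plant, so scanner recovery can be checked exactly.
#'
#' @param length Genome length in bp.
#' @param gc Target GC fraction in `[0, 1]`.
#' @param seed Optional integer seed; fixed seeds give byte-identical
#'   output and the caller's RNG stream is left untouched.
#' @param motifs Optional data frame describing plants, with columns
#'   `motif` (sequence to plant), `copies` (count) and optionally
#'   `strand` (`"+"` plants the motif, `"-"` its reverse complement;
#'   default `"+"`).
#' @param positions Optional list of integer vectors (0-based starts),
#'   one per `motifs` row, overriding random placement for that row.
#' @param min_spacing Minimum bp between planted intervals (default 100).
#' @param genome_id,seq_id Identifiers for the emitted record.
#' @return A list of class `"synth_genome"`: `record` (a
#'   [genome_record()]) and `plants`, a data frame with `seq_id`,
#'   `motif`, `start`, `end` (0-based half-open) and `strand`.
#' @examples
#' g <- synth_genome(10000, gc = 0.3, seed = 1,
#'                   motifs = data.frame(motif = strrep("GGGGTGT", 8),
#'                                       copies = 2))
#' g$plants
#' @export
synth_genome <- function(length, gc = 0.5, seed = NULL, motifs = NULL,
                         positions = NULL, min_spacing = 100L,
                         genome_id = "synthetic", seq_id = "chr") {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("'length' must be a positive integer")
  if (!is.numeric(gc) || gc < 0 || gc > 1) stop("'gc' must be in [0, 1]")
  with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    seqc <- paste(bases, collapse = "")
    plants <- data.frame(seq_id = character(0), motif = character(0),
                         start = integer(0), end = integer(0),
                         strand = character(0), stringsAsFactors = FALSE)
    if (!is.null(motifs) && nrow(motifs) > 0L) {
      if (is.null(motifs$strand)) motifs$strand <- "+"
      rows <- motifs[rep(seq_len(nrow(motifs)), motifs$copies), , drop = FALSE]
      lens <- nchar(rows$motif)
      if (!is.null(positions)) {
        starts <- unlist(positions, use.names = FALSE)
        if (length(starts) != nrow(rows))
          stop("'positions' must supply one start per planted copy")
        ends <- starts + lens
        if (any(starts < 0L) || any(ends > length))
          stop("explicit plant positions fall outside the genome")
        so <- order(starts)
        if (any(starts[so][-1L] < ends[so][-length(so)] + min_spacing))
          stop("explicit plant positions violate min_spacing")
        starts <- as.integer(starts)
      } else {
        starts <- place_motifs(length, lens, min_spacing)
      }
      planted <- ifelse(rows$strand == "-", reverse_complement(rows$motif),
                        rows$motif)
      for (i in seq_along(starts))
        substr(seqc, starts[i] + 1L, starts[i] + lens[i]) <- planted[i]
      plants <- data.frame(seq_id = seq_id, motif = rows$motif,
                           start = starts, end = starts + lens,
                           strand = rows$strand, stringsAsFactors = FALSE)
      plants <- plants[order(plants$start), , drop = FALSE]
      rownames(plants) <- NULL
    }
    seqs <- stats::setNames(seqc, seq_id)
    structure(list(record = genome_record(genome_id, seqs), plants = plants),
              class = "synth_genome")
  })
}

#' @export
print.synth_genome <- function(x, ...) {
  print(x$record)
  cat(sprintf("  %d planted motif(s)\n", nrow(x$plants)))
  invisible(x)
}

#' Generate a synthetic feature table
#'
#' Places non-overlapping features of the requested classes on the first
#' sequence of a genome and (optionally) writes them in the NCBI
#' feature-table dialect.
#'
#' @param genome A [genome_record()] (or `synth_genome` result).
#' @param plan Data frame with columns `feature_class`, `count`,
#'   `length` and optionally `strand` (default `"+"`).
#' @param min_spacing Minimum bp between features (default 50).
#' @param seed Optional integer seed.
#' @param path Optional output path; when given the table is written.
#' @return Feature data frame (internal coordinates), invisibly carrying
#'   the written path as attribute `"path"` when `path` is given.
#' @export
synth_feature_table <- function(genome, plan, min_spacing = 50L, seed = NULL,
                                path = NULL) {
  if (inherits(genome, "synth_genome")) genome <- genome$record
  if (!inherits(genome, "genome_record")) stop("'genome' must be a genome_record")
  if (is.null(plan$strand)) plan$strand <- "+"
  sid <- names(genome$sequences)[1L]
  L <- nchar(genome$sequences[[1L]])
  rows <- plan[rep(seq_len(nrow(plan)), plan$count), , drop = FALSE]
  feats <- with_seed(seed, {
    starts <- place_motifs(L, rows$length, min_spacing)
    data.frame(seq_id = sid, feature_class = rows$feature_class,
               start = as.integer(starts),
               end = as.integer(starts + rows$length),
               strand = rows$strand, stringsAsFactors = FALSE)
  })
  feats <- feats[order(feats$start), , drop = FALSE]
  rownames(feats) <- NULL
  if (!is.null(path)) {
    write_feature_table(feats, path)
    attr(feats, "path") <- path
  }
  feats
}

#' Generate a synthetic cohort with known planted PQS densities
#'
#' Builds a multi-group cohort of synthetic genomes: per genome, the
#' number of planted G-rich tracts is Poisson-distributed at the group's
#' requested per-kbp density, plants are placed uniformly at random
#' subject to spacing, and FASTA files, optional feature tables and the
#' cohort manifest are written to `dir`. Each genome uses its own RNG
#' stream derived from `(seed, genome index)`, so cohorts are
#' reproducible file-by-file.
#'
#' @param groups Data frame with one row per group: `group`,
#'   `n_genomes`, `length` (bp per genome), `gc` (fraction),
#'   `density_per_kbp` (planted tracts per 1000 bp) and optionally
#'   `subgroup` (defaults to the group name).
#' @param dir Output directory (created if needed).
#' @param seed Integer cohort seed (default 1).
#' @param motif Planted tract (default `(GGGGTGT)_8`, 56 bp, a
#'   perfect-repeat PQS of the kind seen in cyanobacterial genomes).
#' @param min_spacing Minimum bp between plants (default 100).
#' @param features_plan Optional plan passed to [synth_feature_table()]
#'   for every genome; when `NULL` no feature tables are written.
#' @return A list of class `"synth_cohort"`: `manifest` (data frame),
#'   `manifest_path`, and `plants` (named list of per-genome plant
#'   ledgers).
#' @export
synth_cohort <- function(groups, dir, seed = 1L,
                         motif = strrep("GGGGTGT", 8), min_spacing = 100L,
                         features_plan = NULL) {
  if (is.null(groups$subgroup)) groups$subgroup <- groups$group
  if (any(groups$n_genomes < 1L)) stop("each group needs >= 1 genome")
  if (any(groups$density_per_kbp < 0)) stop("densities must be >= 0")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  plants <- list()
  idx <- 0L
  for (gi in seq_len(nrow(groups))) {
    for (j in seq_len(groups$n_genomes[gi])) {
      idx <- idx + 1L
      gid <- sprintf("%s_g%02d", gsub("[^A-Za-z0-9]+", "_", groups$group[gi]), j)
      gseed <- as.integer((as.numeric(seed) * 1000003 + idx * 7919) %%
                            2147483647)
      gl <- as.integer(groups$length[gi])
      res <- with_seed(gseed, {
        n_plants <- stats::rpois(1L, groups$density_per_kbp[gi] * gl / 1000)
        sg <- synth_genome(gl, gc = groups$gc[gi], seed = NULL,
                           motifs = if (n_plants > 0)
                             data.frame(motif = motif, copies = n_plants,
                                        strand = "+", stringsAsFactors = FALSE),
                           min_spacing = min_spacing, genome_id = gid,
                           seq_id = paste0(gid, "_chr"))
        ft <- if (!is.null(features_plan))
          synth_feature_table(sg$record, features_plan, seed = NULL,
                              path = file.path(dir, paste0(gid, "_feature_table.txt")))
        list(sg = sg, has_ft = !is.null(ft))
      })
      fa <- paste0(gid, ".fna")
      write_fasta(res$sg$record, file.path(dir, fa))
      manifest[[idx]] <- data.frame(
        genome_id = gid, fasta_path = fa,
        feature_table_path = if (res$has_ft) paste0(gid, "_feature_table.txt")
                             else "",
        group = groups$group[gi], subgroup = groups$subgroup[gi],
        stringsAsFactors = FALSE)
      plants[[gid]] <- res$sg$plants
    }
  }
  manifest <- do.call(rbind, manifest)
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  structure(list(manifest = manifest, manifest_path = manifest_path,
                 plants = plants),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d genome(s), %d group(s), manifest %s\n",
              nrow(x$manifest), length(unique(x$manifest$group)),
              x$manifest_path))
  invisible(x)
}
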