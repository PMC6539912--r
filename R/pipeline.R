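#' Build a pipeline run configuration
#'
#' Collects every tunable of the survey in one object. Defaults are the
#' standard settings: window 25 bp, threshold 1.2, census bins from
#' 1.2 in steps of 0.2 with the top bin unbounded, flank 100 bp,
#' Kruskal-Wallis at alpha 0.05 over groups with at least 10 genomes.
#'
#' @param manifest Path to the cohort manifest (see [read_manifest()]).
#' @param out_dir Output directory (created if needed).
#' @param window,threshold,bin_bounds Passed to [scan_params()].
#' @param flank Feature-neighborhood width in bp.
#' @param level `"group"` or `"subgroup"`: primary aggregation level.
#' @param min_group_size Minimum genomes per group for the
#'   Kruskal-Wallis test.
#' @param alpha Significance cut-off.
#' @param orientation Zone orientation, `"strand"` or `"genomic"`
#'   (see [zone_intervals()]).
#' @param plots Emit convenience plots (PNG) alongside the tables.
#' @return An object of class `"g4_config"`.
#' @export
g4_config <- function(manifest, out_dir, window = 25L, threshold = 1.2,
                      bin_bounds = c(1.2, 1.4, 1.6, 1.8, 2.0), flank = 100L,
                      level = c("group", "subgroup"), min_group_size = 10L,
                      alpha = 0.05, orientation = c("strand", "genomic"),
                      plots = FALSE) {
  structure(list(
    manifest = manifest, out_dir = out_dir,
    params = scan_params(window, threshold, bin_bounds),
    flank = as.integer(flank), level = match.arg(level),
    min_group_size = as.integer(min_group_size), alpha = alpha,
    orientation = match.arg(orientation), plots = isTRUE(plots)
  ), class = "g4_config")
}

log_msg <- function(...) message(format(Sys.time(), "[%H:%M:%S] "), ...)

#' Scan every genome of a cohort for PQS
#'
#' Reads each genome of the manifest, calls PQS on every sequence,
#' writes one PQS table per genome plus a cohort summary table. Genomes
#' are processed independently; an unreadable genome is recorded as a
#' failure and the run continues.
#'
#' @param config A [g4_config()].
#' @return A list with `summaries` (per-genome summary data frame),
#'   `pqs` (named list of per-genome PQS data frames), `seq_lengths`
#'   (named list of per-genome sequence-length vectors) and `failures`
#'   (data frame of genome_id/error).
#' @export
run_scan <- function(config) {
  manifest <- read_manifest(config$manifest)
  dir.create(file.path(config$out_dir, "pqs"), showWarnings = FALSE,
             recursive = TRUE)
  summaries <- list()
  pqs_all <- list()
  seq_lengths <- list()
  failures <- list()
  for (i in seq_len(nrow(manifest))) {
    gid <- manifest$genome_id[i]
    res <- tryCatch({
      genome <- read_genome_fasta(manifest$fasta_path[i], genome_id = gid)
      pqs <- do.call(rbind, lapply(names(genome$sequences), function(sid) {
        withCallingHandlers(
          call_pqs(genome$sequences[[sid]], config$params, seq_id = sid),
          warning = function(w) {
            log_msg(gid, "/", sid, ": ", conditionMessage(w))
            invokeRestart("muffleWarning")
          })
      }))
      if (is.null(pqs)) pqs <- empty_pqs()
      write_pqs_table(pqs, file.path(config$out_dir, "pqs",
                                     paste0(gid, "_pqs.tsv")), config$params)
      list(summary = summarize_genome(genome, pqs, config$params,
                                      group = manifest$group[i],
                                      subgroup = manifest$subgroup[i]),
           pqs = pqs, lens = nchar(genome$sequences))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log_msg("FAILED ", gid, ": ", conditionMessage(res))
      failures[[length(failures) + 1L]] <-
        data.frame(genome_id = gid, error = conditionMessage(res),
                   stringsAsFactors = FALSE)
      next
    }
    summaries[[gid]] <- res$summary
    pqs_all[[gid]] <- res$pqs
    seq_lengths[[gid]] <- res$lens
  }
  if (!length(summaries)) stop("no genome could be scanned")
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  utils::write.table(summaries,
                     file.path(config$out_dir, "genome_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  failures <- if (length(failures)) do.call(rbind, failures)
              else data.frame(genome_id = character(0), error = character(0))
  list(summaries = summaries, pqs = pqs_all, seq_lengths = seq_lengths,
       failures = failures)
}

#' Localize PQS around annotated features across a cohort
#'
#' For every genome with a feature table, classifies its PQS into
#' before/inside/after zones and writes a per-genome zone table; also
#' writes a cohort-level table aggregating counts and zone lengths over
#' all localized genomes. Genomes without a feature table are skipped
#' with a log message.
#'
#' @param config A [g4_config()].
#' @param scan Result of [run_scan()].
#' @return A list with `cohort` (cohort-level zone table) and
#'   `per_genome` (named list of per-genome zone tables).
#' @export
run_localize <- function(config, scan) {
  manifest <- read_manifest(config$manifest)
  dir.create(file.path(config$out_dir, "zones"), showWarnings = FALSE,
             recursive = TRUE)
  per_genome <- list()
  feats_all <- list()
  pqs_all <- list()
  lens_all <- numeric(0)
  for (i in seq_len(nrow(manifest))) {
    gid <- manifest$genome_id[i]
    ft <- manifest$feature_table_path[i]
    if (!gid %in% names(scan$pqs)) next
    if (!nzchar(ft) || !file.exists(ft)) {
      log_msg("no feature table for ", gid, ": skipped from localization")
      next
    }
    feats <- read_feature_table(ft)
    lens <- scan$seq_lengths[[gid]]
    unknown <- sum(feats$strand == "?")
    if (unknown > 0)
      log_msg(gid, ": ", unknown,
              " feature(s) with unknown strand oriented as plus")
    tab <- withCallingHandlers(
      zone_frequency_table(scan$pqs[[gid]], feats, lens,
                           flank = config$flank,
                           orientation = config$orientation),
      warning = function(w) {
        log_msg(gid, ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    write_zone_table(tab, file.path(config$out_dir, "zones",
                                    paste0(gid, "_zones.tsv")))
    per_genome[[gid]] <- tab
    # genome-scoped seq_ids so identically named sequences never collide
    f2 <- feats; f2$seq_id <- paste(gid, f2$seq_id, sep = ":")
    p2 <- scan$pqs[[gid]]
    p2$seq_id <- paste(gid, p2$seq_id, sep = ":")
    names(lens) <- paste(gid, names(lens), sep = ":")
    feats_all[[gid]] <- f2
    pqs_all[[gid]] <- p2
    lens_all <- c(lens_all, lens)
  }
  cohort <- if (length(feats_all)) {
    zone_frequency_table(do.call(rbind, pqs_all), do.call(rbind, feats_all),
                         lens_all, flank = config$flank,
                         orientation = config$orientation)
  } else {
    log_msg("no genome had a feature table: cohort zone table is empty")
    suppressWarnings(zone_frequency_table(
      empty_pqs(),
      data.frame(seq_id = character(0), feature_class = character(0),
                 start = integer(0), end = integer(0),
                 strand = character(0)), numeric(0), flank = config$flank))
  }
  write_zone_table(cohort, file.path(config$out_dir, "zones",
                                     "cohort_zones.tsv"))
  list(cohort = cohort, per_genome = per_genome)
}

#' Cohort-level census and group statistics
#'
#' Produces the score-bin census (totals and frequencies per 1000 bp
#' over all analyzed sequence), group and subgroup summaries, and
#' Kruskal-Wallis comparisons of per-genome frequencies at both levels
#' where at least two groups meet the size filter.
#'
#' @param config A [g4_config()].
#' @param summaries Per-genome summary data frame from [run_scan()].
#' @return A list with `census`, `group_summary`, `subgroup_summary`
#'   and `kw` (named list of `"kw_test"` objects or error messages).
#' @export
run_cohort <- function(config, summaries) {
  if (nrow(summaries) < 1L) stop("need at least one genome summary")
  census <- score_bin_census(summaries, config$params)
  utils::write.table(census, file.path(config$out_dir, "score_bin_census.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(census = census)
  kw <- list()
  for (level in c("group", "subgroup")) {
    gs <- summarize_group(summaries, level = level)
    utils::write.table(gs, file.path(config$out_dir,
                                     paste0(level, "_summary.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out[[paste0(level, "_summary")]] <- gs
    kw[[level]] <- tryCatch(
      kruskal_wallis(summaries$freq_per_kbp, summaries[[level]],
                     min_group_size = config$min_group_size,
                     alpha = config$alpha),
      error = function(e) {
        log_msg("Kruskal-Wallis at ", level, " level not run: ",
                conditionMessage(e))
        conditionMessage(e)
      })
  }
  kw_rows <- lapply(names(kw), function(lv) {
    x <- kw[[lv]]
    if (inherits(x, "kw_test"))
      data.frame(level = lv, k = x$k, n = x$n, H = x$H, df = x$df,
                 p_value = x$p_value, significant = x$significant,
                 stringsAsFactors = FALSE)
    else
      data.frame(level = lv, k = NA, n = NA, H = NA, df = NA, p_value = NA,
                 significant = NA, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, kw_rows),
                     file.path(config$out_dir, "kw_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out$kw <- kw
  if (config$plots) plot_cohort(summaries, config)
  out
}

# Convenience plots (not part of the analysis surface): per-subgroup
# frequency boxplot and GC-vs-frequency scatter.
plot_cohort <- function(summaries, config) {
  dir.create(file.path(config$out_dir, "plots"), showWarnings = FALSE,
             recursive = TRUE)
  grDevices::png(file.path(config$out_dir, "plots", "freq_by_subgroup.png"),
                 width = 800, height = 500)
  graphics::boxplot(freq_per_kbp ~ subgroup, data = summaries,
                    las = 2, ylab = "PQS per 1000 bp", xlab = "")
  grDevices::dev.off()
  grDevices::png(file.path(config$out_dir, "plots", "gc_vs_freq.png"),
                 width = 600, height = 500)
  graphics::plot(summaries$gc_percent, summaries$freq_per_kbp,
                 xlab = "GC %", ylab = "PQS per 1000 bp", pch = 19)
  grDevices::dev.off()
  invisible(NULL)
}

#' Run the full survey pipeline
#'
#' scan -> localize -> cohort on the manifest of a [g4_config()].
#'
#' @param config A [g4_config()].
#' @return An object of class `"g4_run"` with elements `scan`,
#'   `localize`, `cohort` and `config`.
#' @export
run_pipeline <- function(config) {
  scan <- run_scan(config)
  loc <- run_localize(config, scan)
  coh <- run_cohort(config, scan$summaries)
  structure(list(scan = scan, localize = loc, cohort = coh, config = config),
            class = "g4_run")
}

#' @export
print.g4_run <- function(x, ...) {
  s <- x$scan$summaries
  cat("G4 census run\n")
  cat(sprintf("  genomes scanned : %d (%d failed)\n", nrow(s),
              nrow(x$scan$failures)))
  cat(sprintf("  total sequence  : %s bp\n",
              format(sum(s$total_length), big.mark = ",")))
  cat(sprintf("  total PQS       : %s (%.3f per kbp)\n",
              format(sum(s$pqs_total), big.mark = ","),
              pqs_frequency(sum(s$pqs_total), sum(s$total_length))))
  cat("  outputs in      :", x$config$out_dir, "\n")
  invisible(x)
}

#' @export
summary.g4_run <- function(object, ...) {
  list(census = object$cohort$census,
       group_summary = object$cohort$group_summary,
       kw = object$cohort$kw)
}
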