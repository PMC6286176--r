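#' Pipeline run configuration
#'
#' Gathers every stage parameter and I/O path in one place. Defaults follow
#' a typical MBD-Seq analysis: depth threshold 10, promoter 5000 bp upstream /
#' 2000 bp downstream of the TSS, 100 bp merge distance, |log2FC| cutoff 1.0,
#' adjusted-p cutoff 0.05.
#'
#' @param contigs_path Contig-sizes file.
#' @param annotation_path Transcript annotation (GTF or BED6).
#' @param annotation_format \code{"gtf"} or \code{"bed6"}.
#' @param alignments Named character vector: sample id -> BED path.
#' @param condition Named character vector: sample id -> condition label.
#' @param region Scan regions: \code{"promoter"}, \code{"intragenic"} or
#'   \code{"both"}.
#' @param up,down Promoter window geometry (bases).
#' @param depth_threshold Peak depth threshold.
#' @param min_width Minimum peak width.
#' @param merge_dist Site merge distance (bases).
#' @param lfc_cutoff,padj_cutoff,pseudocount,n_permutations Screen settings.
#' @param numerator Condition used as fold-change numerator (default
#'   \code{"M1"} when present, else the first label).
#' @param seed Seed for the permutation screen.
#' @param outdir Output directory.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(contigs_path, annotation_path,
                       annotation_format = c("gtf", "bed6"), alignments,
                       condition, region = "promoter", up = 5000L,
                       down = 2000L, depth_threshold = 10L, min_width = 1L,
                       merge_dist = 100L, lfc_cutoff = 1.0,
                       padj_cutoff = 0.05, pseudocount = 1.0,
                       n_permutations = 10000L, numerator = NULL,
                       seed = 1L, outdir = ".") {
  structure(list(contigs_path = contigs_path,
                 annotation_path = annotation_path,
                 annotation_format = match.arg(annotation_format),
                 alignments = alignments, condition = condition,
                 region = region, up = as.integer(up),
                 down = as.integer(down),
                 depth_threshold = as.integer(depth_threshold),
                 min_width = as.integer(min_width),
                 merge_dist = as.integer(merge_dist),
                 lfc_cutoff = lfc_cutoff, padj_cutoff = padj_cutoff,
                 pseudocount = pseudocount,
                 n_permutations = as.integer(n_permutations),
                 numerator = numerator, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' The YAML mirrors the arguments of \code{\link{run_config}};
#' \code{alignments} and \code{condition} are maps of sample id to path /
#' label.
#'
#' @param path YAML file.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  for (field in c("alignments", "condition")) {
    if (!is.null(y[[field]])) args[[field]] <- unlist(y[[field]])
  }
  do.call(run_config, args)
}

#' Run the full peak-calling and screening pipeline
#'
#' Executes, in order: read contigs/annotation/alignments, build scan
#' windows, call per-sample peaks, compile and merge the master site list,
#' count fragments per site per sample, and run the differential screen.
#' Writes per-sample peak BEDs, \code{master_sites.bed}, \code{counts.tsv}
#' and \code{screen.tsv} under \code{cfg$outdir}. Rerunning with identical
#' inputs and seed reproduces all outputs byte-identically.
#'
#' @param cfg A \code{\link{run_config}}.
#' @param with_screen Run the permutation screen stage (default TRUE;
#'   requires exactly 2 conditions with >= 2 samples each).
#' @return Invisibly, a list with \code{windows}, \code{sample_peaks},
#'   \code{master}, \code{merged}, \code{counts} (the
#'   \code{RangedSummarizedExperiment}), \code{screen} (data.frame or NULL)
#'   and \code{files}.
#' @export
run_pipeline <- function(cfg, with_screen = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  contigs <- stage("contigs", read_contig_sizes(cfg$contigs_path))
  tx <- stage("annotation",
              read_transcripts(cfg$annotation_path, contigs,
                               format = cfg$annotation_format))
  windows <- stage("windows",
                   scan_windows(tx, contigs, region = cfg$region,
                                up = cfg$up, down = cfg$down))
  message("methseek: ", length(windows), " scan window(s) from ",
          length(tx), " transcript(s)")

  samples <- names(cfg$alignments)
  aln <- lapply(samples, function(sm) {
    stage(paste0("alignments:", sm),
          read_alignments_bed(cfg$alignments[[sm]], contigs, sample_id = sm))
  })
  names(aln) <- samples

  sample_peaks <- lapply(samples, function(sm) {
    p <- stage(paste0("callpeaks:", sm),
               call_sample_peaks(aln[[sm]], windows,
                                 depth_threshold = cfg$depth_threshold,
                                 min_width = cfg$min_width))
    message("methseek: ", sm, ": ", length(p), " peak(s)")
    p
  })
  names(sample_peaks) <- samples

  master <- stage("master", compile_master_list(sample_peaks, contigs))
  merged <- stage("merge", merge_sites(master, merge_dist = cfg$merge_dist))
  message("methseek: master list ", length(master), " site(s), ",
          length(merged), " after merging at ", cfg$merge_dist, " bp")

  counts <- stage("count",
                  count_reads_per_site(aln, merged, cfg$condition))

  files <- list()
  for (sm in samples) {
    files[[paste0("peaks_", sm)]] <-
      write_sites_bed(sample_peaks[[sm]],
                      file.path(cfg$outdir, paste0(sm, ".peaks.bed")))
  }
  files$master <- write_sites_bed(merged,
                                  file.path(cfg$outdir, "master_sites.bed"))
  files$counts <- write_count_matrix(counts,
                                     file.path(cfg$outdir, "counts.tsv"))

  screen <- NULL
  if (with_screen && length(merged)) {
    numerator <- cfg$numerator
    if (is.null(numerator)) {
      numerator <- if ("M1" %in% cfg$condition) "M1" else cfg$condition[[1L]]
    }
    screen <- stage("screen",
                    screen_sites(counts, numerator = numerator,
                                 lfc_cutoff = cfg$lfc_cutoff,
                                 padj_cutoff = cfg$padj_cutoff,
                                 pseudocount = cfg$pseudocount,
                                 n_permutations = cfg$n_permutations,
                                 seed = cfg$seed))
    files$screen <- write_screen_tsv(screen,
                                     file.path(cfg$outdir, "screen.tsv"))
    message("methseek: screen flagged ", sum(screen$flagged), " of ",
            nrow(screen), " site(s)")
  }

  invisible(list(windows = windows, sample_peaks = sample_peaks,
                 master = master, merged = merged, counts = counts,
                 screen = screen, files = files))
}
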