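#' Simulation configuration
#'
#' Defaults describe a small two-condition MBD-Seq experiment: 4 biological
#' replicates per condition, sonication fragments with hard bounds 200-500 bp
#' and modal length 350 bp (triangular distribution), planted methylated
#' regions centered in promoter windows at a mean fragment depth of 20
#' against a sparse uniform background of 2 fragments per kb (expected
#' background depth about 0.7x), and no differential effect — the null in
#' which the two conditions share one methylation landscape.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bases.
#' @param n_transcripts Transcripts placed uniformly without overlap.
#' @param tx_length Transcript length in bases.
#' @param strand_fraction Probability a transcript is on the + strand.
#' @param planted_fraction Fraction of promoters given a planted methylated
#'   region.
#' @param planted_region_width Width of each planted region in bases.
#' @param enriched_depth Target mean fragment depth over planted regions.
#' @param background_rate Expected background fragments per kb of genome per
#'   sample.
#' @param frag_len_min,frag_len_mode,frag_len_max Triangular fragment-length
#'   parameters in bases (defaults 200/350/500).
#' @param n_samples_per_condition Biological replicates per condition
#'   (default 4).
#' @param differential_effect Depth multiplier applied in condition M1 (the
#'   "A" condition) at the differential subset of planted regions; 1 means
#'   no effect.
#' @param diff_fraction Fraction of planted regions that are differential.
#' @param up,down Promoter window geometry used to center planted regions.
#' @param seed Integer seed; every random draw derives from it.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_contigs = 2L, contig_length = 1000000L,
                       n_transcripts = 60L, tx_length = 2000L,
                       strand_fraction = 0.5, planted_fraction = 0.5,
                       planted_region_width = 1000L, enriched_depth = 20,
                       background_rate = 2, frag_len_min = 200L,
                       frag_len_mode = 350L, frag_len_max = 500L,
                       n_samples_per_condition = 4L,
                       differential_effect = 1, diff_fraction = 0,
                       up = 5000L, down = 2000L, seed = 1L) {
  cfg <- list(n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length),
              n_transcripts = as.integer(n_transcripts),
              tx_length = as.integer(tx_length),
              strand_fraction = strand_fraction,
              planted_fraction = planted_fraction,
              planted_region_width = as.integer(planted_region_width),
              enriched_depth = enriched_depth,
              background_rate = background_rate,
              frag_len_min = as.integer(frag_len_min),
              frag_len_mode = as.integer(frag_len_mode),
              frag_len_max = as.integer(frag_len_max),
              n_samples_per_condition = as.integer(n_samples_per_condition),
              differential_effect = differential_effect,
              diff_fraction = diff_fraction,
              up = as.integer(up), down = as.integer(down),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(frag_len_min <= frag_len_mode, frag_len_mode <= frag_len_max,
              background_rate >= 0, enriched_depth >= 0,
              planted_fraction >= 0, planted_fraction <= 1,
              diff_fraction >= 0, diff_fraction <= 1,
              strand_fraction >= 0, strand_fraction <= 1,
              planted_region_width >= 1L, n_samples_per_condition >= 1L,
              differential_effect > 0)
  })
  structure(cfg, class = "sim_config")
}

# Triangular(min, mode, max) sampling by inverse CDF.
rtriangular <- function(n, lo, mode, hi) {
  u <- stats::runif(n)
  fc <- (mode - lo) / (hi - lo)
  left <- u < fc
  x <- numeric(n)
  x[left] <- lo + sqrt(u[left] * (hi - lo) * (mode - lo))
  x[!left] <- hi - sqrt((1 - u[!left]) * (hi - lo) * (hi - mode))
  x
}

# Place n non-overlapping transcripts of the given length uniformly on one
# contig, keeping a margin so promoter windows are never clipped. Rejection
# sampling with a bounded retry budget.
place_transcripts <- function(n, contig_length, tx_length, margin,
                              max_tries = 10000L) {
  lo <- margin + 1L
  hi <- contig_length - margin - tx_length
  if (n == 0L) return(integer(0))
  if (hi < lo) {
    stop("contig too small to place transcripts; increase contig_length",
         call. = FALSE)
  }
  starts <- integer(0)
  tries <- 0L
  while (length(starts) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", n, " non-overlapping transcripts after ",
           max_tries, " tries; increase contig_length", call. = FALSE)
    }
    cand <- lo + floor(stats::runif(1) * (hi - lo + 1L))
    if (!any(cand < starts + tx_length & starts < cand + tx_length)) {
      starts <- c(starts, as.integer(cand))
    }
  }
  sort(starts)
}

# Fragments over one region: count ~ Poisson(depth * width / mean_frag_len),
# midpoints uniform over the region, triangular lengths, clipped to contig.
region_fragments <- function(region_start, region_end, depth, cfg,
                             contig_length) {
  mean_len <- (cfg$frag_len_min + cfg$frag_len_mode + cfg$frag_len_max) / 3
  width <- region_end - region_start + 1L
  n <- stats::rpois(1L, depth * width / mean_len)
  if (n == 0L) return(IRanges::IRanges())
  mids <- region_start + floor(stats::runif(n) * width)
  lens <- round(rtriangular(n, cfg$frag_len_min, cfg$frag_len_mode,
                            cfg$frag_len_max))
  s <- pmax(1, round(mids - lens / 2))
  e <- pmin(contig_length, s + lens - 1)
  IRanges::IRanges(start = as.integer(s), end = as.integer(e))
}

#' Simulate an MBD-Seq dataset with known truth
#'
#' Generates a toy genome, non-overlapping transcripts, planted methylated
#' regions centered in promoter windows, and per-sample fragment alignments
#' for two conditions (M1 and M2), writing everything as plain-text files
#' that the package's readers accept: \code{contigs.txt},
#' \code{transcripts.gtf}, \code{truth.bed}, \code{truth.json} and one
#' \code{<sample>.bed} per sample. Fragment counts over a planted region are
#' Poisson with mean \code{enriched_depth * width / mean_fragment_length}
#' (times \code{differential_effect} in M1 at differential regions);
#' background fragments are Poisson over the whole genome. All randomness
#' derives from \code{cfg$seed}, so reruns are byte-identical.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list: \code{contigs}, \code{transcripts},
#'   \code{truth} (a \code{GRanges} of planted regions with
#'   \code{transcript_id}, \code{multiplier}), \code{condition} (named
#'   vector sample -> condition), \code{files} (named paths), and
#'   \code{fragment_counts} (per-sample totals).
#' @export
simulate_dataset <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  contig_names <- sprintf("sim%d", seq_len(cfg$n_contigs))
  contigs <- contig_table(contig_names,
                          rep(cfg$contig_length, cfg$n_contigs))

  # spread transcripts across contigs as evenly as possible
  per_contig <- diff(floor(seq(0, cfg$n_transcripts,
                               length.out = cfg$n_contigs + 1L)))
  margin <- cfg$up + cfg$down
  tx_list <- lapply(seq_len(cfg$n_contigs), function(ci) {
    starts <- place_transcripts(per_contig[ci], cfg$contig_length,
                                cfg$tx_length, margin)
    if (!length(starts)) return(NULL)
    GenomicRanges::GRanges(
      seqnames = contig_names[ci],
      ranges = IRanges::IRanges(start = starts,
                                width = cfg$tx_length),
      strand = ifelse(stats::runif(length(starts)) < cfg$strand_fraction,
                      "+", "-"))
  })
  tx <- suppressWarnings(do.call(c, tx_list[!vapply(tx_list, is.null,
                                                    logical(1))]))
  GenomeInfoDb::seqlevels(tx) <- contig_names
  GenomeInfoDb::seqinfo(tx) <- contig_seqinfo(contigs)
  tx$transcript_id <- sprintf("tx%04d", seq_along(tx))

  # planted methylated regions, centered in each chosen promoter window
  prom <- suppressWarnings(promoter_windows(tx, contigs,
                                            up = cfg$up, down = cfg$down))
  n_planted <- round(cfg$planted_fraction * length(prom))
  planted_idx <- if (n_planted > 0L) {
    sort(sample.int(length(prom), n_planted))
  } else integer(0)
  if (length(planted_idx)) {
    pw <- prom[planted_idx]
    centers <- floor((GenomicRanges::start(pw) +
                        GenomicRanges::end(pw)) / 2)
    half <- floor(cfg$planted_region_width / 2)
    truth <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(pw),
      ranges = IRanges::IRanges(
        start = pmax(1L, centers - half),
        width = cfg$planted_region_width),
      seqinfo = contig_seqinfo(contigs))
    truth$transcript_id <- pw$transcript_id
    n_diff <- round(cfg$diff_fraction * length(truth))
    mult <- rep(1, length(truth))
    if (n_diff > 0L) {
      mult[sort(sample.int(length(truth), n_diff))] <- cfg$differential_effect
    }
    truth$multiplier <- mult
  } else {
    truth <- GenomicRanges::GRanges(seqinfo = contig_seqinfo(contigs))
    truth$transcript_id <- character(0)
    truth$multiplier <- numeric(0)
  }

  samples <- c(sprintf("M1_rep%d", seq_len(cfg$n_samples_per_condition)),
               sprintf("M2_rep%d", seq_len(cfg$n_samples_per_condition)))
  condition <- stats::setNames(rep(c("M1", "M2"),
                                   each = cfg$n_samples_per_condition),
                               samples)

  genome_kb <- cfg$n_contigs * cfg$contig_length / 1000
  truth_contig <- as.character(GenomicRanges::seqnames(truth))
  frag_counts <- integer(length(samples))
  files <- list()
  for (si in seq_along(samples)) {
    sm <- samples[si]
    frag_sn <- character(0)
    frag_ranges <- IRanges::IRanges()
    for (ri in seq_along(truth)) {
      depth <- cfg$enriched_depth
      if (condition[sm] == "M1") depth <- depth * truth$multiplier[ri]
      fr <- region_fragments(GenomicRanges::start(truth)[ri],
                             GenomicRanges::end(truth)[ri], depth, cfg,
                             cfg$contig_length)
      frag_ranges <- c(frag_ranges, fr)
      frag_sn <- c(frag_sn, rep(truth_contig[ri], length(fr)))
    }
    n_bg <- stats::rpois(1L, cfg$background_rate * genome_kb)
    if (n_bg > 0L) {
      bg_contig <- contig_names[1L + floor(stats::runif(n_bg) *
                                             cfg$n_contigs)]
      bg_start <- 1L + floor(stats::runif(n_bg) * cfg$contig_length)
      bg_len <- round(rtriangular(n_bg, cfg$frag_len_min, cfg$frag_len_mode,
                                  cfg$frag_len_max))
      bg_end <- pmin(cfg$contig_length, bg_start + bg_len - 1)
      frag_ranges <- c(frag_ranges,
                       IRanges::IRanges(start = as.integer(bg_start),
                                        end = as.integer(bg_end)))
      frag_sn <- c(frag_sn, bg_contig)
    }
    frag_counts[si] <- length(frag_ranges)
    path <- file.path(outdir, paste0(sm, ".bed"))
    if (length(frag_ranges)) {
      gr <- GenomicRanges::GRanges(seqnames = frag_sn, ranges = frag_ranges,
                                   seqinfo = contig_seqinfo(contigs))
      gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
      writeLines(sprintf("%s\t%d\t%d",
                         as.character(GenomicRanges::seqnames(gr)),
                         GenomicRanges::start(gr) - 1L,
                         GenomicRanges::end(gr)), path)
    } else {
      file.create(path)
    }
    files[[sm]] <- path
  }
  names(frag_counts) <- samples

  # reference files
  contig_path <- file.path(outdir, "contigs.txt")
  writeLines(sprintf("%s\t%d", names(contigs), as.integer(contigs)),
             contig_path)
  gtf_path <- file.path(outdir, "transcripts.gtf")
  writeLines(sprintf(
    "%s\tmethseek_sim\ttranscript\t%d\t%d\t.\t%s\t.\ttranscript_id \"%s\";",
    as.character(GenomicRanges::seqnames(tx)), GenomicRanges::start(tx),
    GenomicRanges::end(tx), as.character(GenomicRanges::strand(tx)),
    tx$transcript_id), gtf_path)
  truth_bed <- file.path(outdir, "truth.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g", truth_contig,
                     GenomicRanges::start(truth) - 1L,
                     GenomicRanges::end(truth), truth$transcript_id,
                     truth$multiplier), truth_bed)
  truth_json <- file.path(outdir, "truth.json")
  jsonlite::write_json(
    list(seed = cfg$seed,
         samples = as.list(condition),
         planted = data.frame(
           contig = truth_contig,
           start = GenomicRanges::start(truth) - 1L,
           end = GenomicRanges::end(truth),
           transcript_id = truth$transcript_id,
           multiplier = truth$multiplier),
         fragment_counts = as.list(frag_counts)),
    truth_json, auto_unbox = TRUE, digits = NA)

  invisible(list(contigs = contigs, transcripts = tx, truth = truth,
                 condition = condition,
                 files = c(list(contigs = contig_path, gtf = gtf_path,
                                truth_bed = truth_bed,
                                truth_json = truth_json), files),
                 fragment_counts = frag_counts))
}

#' Evaluate recovery of planted regions
#'
#' Compares called sites with the simulator's truth: a planted region is
#' recovered when at least one called site overlaps it; its boundary error is
#' the larger of the start and end distances to the best-overlapping site.
#'
#' @param called A \code{GRanges} of called sites.
#' @param truth A \code{GRanges} of planted regions.
#' @param boundary_tol Tolerance in bases used for the
#'   \code{frac_within_tol} summary (default 500).
#' @return A list: \code{recall}, \code{precision} (fraction of called sites
#'   overlapping any planted region), \code{mean_boundary_error},
#'   \code{max_boundary_error}, \code{frac_within_tol}, and the per-region
#'   \code{boundary_error} vector (NA when unrecovered).
#' @export
evaluate_recovery <- function(called, truth, boundary_tol = 500L) {
  if (!length(truth)) {
    return(list(recall = NA_real_,
                precision = if (length(called)) 0 else NA_real_,
                mean_boundary_error = NA_real_,
                max_boundary_error = NA_real_,
                frac_within_tol = NA_real_,
                boundary_error = numeric(0)))
  }
  hits <- GenomicRanges::findOverlaps(truth, called, ignore.strand = TRUE)
  berr <- rep(NA_real_, length(truth))
  if (length(hits)) {
    for (ti in unique(S4Vectors::queryHits(hits))) {
      cand <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == ti]
      errs <- pmax(abs(GenomicRanges::start(called)[cand] -
                         GenomicRanges::start(truth)[ti]),
                   abs(GenomicRanges::end(called)[cand] -
                         GenomicRanges::end(truth)[ti]))
      berr[ti] <- min(errs)
    }
  }
  recovered <- !is.na(berr)
  precision <- if (length(called)) {
    mean(IRanges::overlapsAny(called, truth, ignore.strand = TRUE))
  } else NA_real_
  list(recall = mean(recovered),
       precision = precision,
       mean_boundary_error = if (any(recovered)) mean(berr[recovered])
       else NA_real_,
       max_boundary_error = if (any(recovered)) max(berr[recovered])
       else NA_real_,
       frac_within_tol = if (any(recovered))
         mean(berr[recovered] <= boundary_tol) else NA_real_,
       boundary_error = berr)
}
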