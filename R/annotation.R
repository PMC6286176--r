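#' Transcriptional start sites
#'
#' The TSS is the first transcribed base of a transcript: the leftmost base
#' for plus-strand transcripts, the rightmost for minus-strand ones.
#'
#' @param transcripts A \code{GRanges} of transcripts with strand \code{+} or
#'   \code{-}.
#' @return Integer vector of 1-based TSS positions, one per transcript.
#' @export
tss_position <- function(transcripts) {
  str <- as.character(GenomicRanges::strand(transcripts))
  if (any(!str %in% c("+", "-"))) {
    stop("transcripts must be stranded (+ or -)", call. = FALSE)
  }
  ifelse(str == "+", GenomicRanges::start(transcripts),
         GenomicRanges::end(transcripts))
}

#' Promoter scan windows
#'
#' Builds the promoter window around each TSS: \code{up} bases upstream of
#' the TSS plus \code{down} bases downstream, where the downstream segment
#' includes the TSS base itself, so an unclipped window is exactly
#' \code{up + down} bases wide (7000 bp at the defaults of 5000 upstream and
#' 2000 downstream). Windows are strand-aware and clipped to contig bounds;
#' a window that is empty after clipping drops its transcript with a warning.
#' Windows from different transcripts may overlap — overlaps are resolved
#' downstream by site consolidation, not here.
#'
#' @param transcripts A stranded \code{GRanges} of transcripts with a
#'   \code{transcript_id} metadata column.
#' @param contigs A \code{contig_table} used for clipping.
#' @param up Bases upstream of the TSS (default 5000).
#' @param down Bases downstream of the TSS, TSS base included (default 2000).
#' @return A \code{GRanges} of windows with metadata columns
#'   \code{transcript_id} and \code{region_kind = "promoter"}; strand is kept
#'   from the transcript.
#' @export
promoter_windows <- function(transcripts, contigs, up = 5000L, down = 2000L) {
  up <- as.integer(up); down <- as.integer(down)
  if (up < 0L || down < 1L || up + down < 1L) {
    stop("need up >= 0, down >= 1", call. = FALSE)
  }
  if (!length(transcripts)) {
    out <- GenomicRanges::GRanges(seqinfo = contig_seqinfo(contigs))
    out$transcript_id <- character(0)
    out$region_kind <- character(0)
    return(out)
  }
  gr <- transcripts
  GenomeInfoDb::seqlevels(gr) <- names(contigs)
  GenomeInfoDb::seqinfo(gr) <- contig_seqinfo(contigs)
  win <- suppressWarnings(
    GenomicRanges::trim(GenomicRanges::promoters(gr, upstream = up,
                                                 downstream = down)))
  keep <- GenomicRanges::width(win) >= 1L
  if (any(!keep)) {
    warning(sum(!keep), " promoter window(s) empty after clipping to contig ",
            "bounds; transcript(s) skipped", call. = FALSE)
    win <- win[keep]
  }
  win$region_kind <- rep("promoter", length(win))
  win
}

#' Intragenic scan windows
#'
#' The intragenic window of a transcript is its full genomic span,
#' independent of strand.
#'
#' @inheritParams promoter_windows
#' @return A \code{GRanges} of windows with
#'   \code{region_kind = "intragenic"}.
#' @export
intragenic_windows <- function(transcripts, contigs) {
  gr <- transcripts
  if (length(gr)) {
    GenomeInfoDb::seqlevels(gr) <- names(contigs)
    GenomeInfoDb::seqinfo(gr) <- contig_seqinfo(contigs)
  } else {
    gr <- GenomicRanges::GRanges(seqinfo = contig_seqinfo(contigs))
    gr$transcript_id <- character(0)
  }
  gr$region_kind <- rep("intragenic", length(gr))
  gr
}

#' Build scan windows for a region choice
#'
#' @inheritParams promoter_windows
#' @param region One of \code{"promoter"}, \code{"intragenic"},
#'   \code{"both"}.
#' @return A \code{GRanges} of windows.
#' @export
scan_windows <- function(transcripts, contigs,
                         region = c("promoter", "intragenic", "both"),
                         up = 5000L, down = 2000L) {
  region <- match.arg(region)
  prom <- if (region %in% c("promoter", "both")) {
    promoter_windows(transcripts, contigs, up = up, down = down)
  }
  intr <- if (region %in% c("intragenic", "both")) {
    intragenic_windows(transcripts, contigs)
  }
  if (region == "both") c(prom, intr) else if (region == "promoter") prom
  else intr
}
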