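#' Per-base read depth over a scan window
#'
#' Depth at a base is the number of aligned fragments whose span covers it;
#' whole fragment spans are counted (duplicates are assumed removed
#' upstream). Bases of a fragment outside the window contribute nothing.
#'
#' @param alignments A \code{GRanges} of fragment spans.
#' @param window A single-range \code{GRanges} scan window.
#' @return A \code{depth_profile}: list with the \code{window} and an integer
#'   \code{depth} vector, one entry per base of the window.
#' @export
compute_depth <- function(alignments, window) {
  stopifnot(length(window) == 1L)
  w <- GenomicRanges::width(window)
  hits <- alignments[GenomicRanges::seqnames(alignments) ==
                       as.character(GenomicRanges::seqnames(window))]
  r <- IRanges::restrict(GenomicRanges::ranges(hits),
                         start = GenomicRanges::start(window),
                         end = GenomicRanges::end(window))
  r <- r[IRanges::width(r) > 0L]
  r <- IRanges::shift(r, -(GenomicRanges::start(window) - 1L))
  depth <- as.integer(IRanges::coverage(r, width = w))
  structure(list(window = window, depth = depth), class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("depth_profile over ", as.character(GenomicRanges::seqnames(x$window)),
      ":", GenomicRanges::start(x$window) - 1L, "-",
      GenomicRanges::end(x$window), " (", length(x$depth), " bases, max depth ",
      if (length(x$depth)) max(x$depth) else 0L, ")\n", sep = "")
  invisible(x)
}

#' Call methylation peaks from a depth profile
#'
#' The core scan: a methylation peak is a maximal run of consecutive bases
#' whose depth meets the threshold. Consequently the first base of each peak
#' has depth >= threshold and the base immediately after its end has depth
#' below the threshold (or the run reaches the window edge, where the peak is
#' clipped). Runs narrower than \code{min_width} are discarded.
#'
#' @param profile A \code{depth_profile} from \code{\link{compute_depth}}.
#' @param depth_threshold Minimum per-base depth for a base to be inside a
#'   peak (default 10).
#' @param min_width Minimum peak width in bases (default 1).
#' @param sample_id Optional sample label recorded in peak provenance.
#' @return A \code{GRanges} of peaks sorted by start, with a \code{source}
#'   \code{CharacterList} column of provenance entries
#'   \code{"sample|transcript|region_kind"}.
#' @export
call_peaks <- function(profile, depth_threshold = 10L, min_width = 1L,
                       sample_id = NA_character_) {
  stopifnot(inherits(profile, "depth_profile"),
            depth_threshold >= 1L, min_width >= 1L)
  window <- profile$window
  runs <- rle(profile$depth >= depth_threshold)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_width
  if (!any(keep)) {
    out <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(window))
    out$source <- IRanges::CharacterList(vector("list", 0L))
    return(out)
  }
  offset <- GenomicRanges::start(window) - 1L
  n <- sum(keep)
  prov <- provenance_entry(sample_id, window$transcript_id,
                           window$region_kind)
  GenomicRanges::GRanges(
    seqnames = rep(as.character(GenomicRanges::seqnames(window)), n),
    ranges = IRanges::IRanges(start = run_start[keep] + offset,
                              end = run_end[keep] + offset),
    source = IRanges::relist(rep(prov, n),
                             IRanges::PartitioningByEnd(seq_len(n))),
    seqinfo = GenomeInfoDb::seqinfo(window))
}

provenance_entry <- function(sample_id, transcript_id, region_kind) {
  paste(if (is.null(sample_id) || is.na(sample_id)) "." else sample_id,
        if (is.null(transcript_id)) "." else transcript_id,
        if (is.null(region_kind)) "." else region_kind,
        sep = "|")
}

#' Call peaks for one sample over many scan windows
#'
#' Runs \code{\link{call_peaks}} over every window and concatenates the
#' results. Overlapping windows can emit the same interval more than once;
#' exact-duplicate intervals are collapsed into one site whose provenance is
#' the union of the duplicates'.
#'
#' @param alignments A \code{GRanges} of one sample's fragment spans (its
#'   \code{sample_id} column labels the provenance).
#' @param windows A \code{GRanges} of scan windows (may overlap).
#' @param depth_threshold,min_width See \code{\link{call_peaks}}.
#' @return A sorted \code{GRanges} of unique peak intervals with merged
#'   provenance.
#' @export
call_sample_peaks <- function(alignments, windows, depth_threshold = 10L,
                              min_width = 1L) {
  sample_id <- if (length(alignments) && !is.null(alignments$sample_id)) {
    unique(alignments$sample_id)[1L]
  } else NA_character_
  if (!length(windows)) {
    out <- GenomicRanges::GRanges()
    out$source <- IRanges::CharacterList(vector("list", 0L))
    return(out)
  }
  # equivalent to call_peaks(compute_depth(...)) per window, but alignments
  # are split by contig once and a single GRanges is built at the end
  rng_by <- S4Vectors::split(GenomicRanges::ranges(alignments),
                             as.character(GenomicRanges::seqnames(alignments)))
  w_sn <- as.character(GenomicRanges::seqnames(windows))
  w_start <- GenomicRanges::start(windows)
  w_end <- GenomicRanges::end(windows)
  tx_ids <- windows$transcript_id
  kinds <- windows$region_kind
  out_sn <- out_prov <- character(0)
  out_s <- out_e <- integer(0)
  none <- IRanges::IRanges()
  for (i in seq_along(windows)) {
    r <- if (w_sn[i] %in% names(rng_by)) rng_by[[w_sn[i]]] else none
    r <- IRanges::restrict(r, start = w_start[i], end = w_end[i])
    r <- r[IRanges::width(r) > 0L]
    r <- IRanges::shift(r, -(w_start[i] - 1L))
    depth <- as.integer(IRanges::coverage(r, width = w_end[i] - w_start[i] + 1L))
    runs <- rle(depth >= depth_threshold)
    keep <- runs$values & runs$lengths >= min_width
    if (!any(keep)) next
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths + 1L
    offset <- w_start[i] - 1L
    n <- sum(keep)
    out_sn <- c(out_sn, rep(w_sn[i], n))
    out_s <- c(out_s, run_start[keep] + offset)
    out_e <- c(out_e, run_end[keep] + offset)
    prov <- provenance_entry(sample_id,
                             if (is.null(tx_ids)) NULL else tx_ids[i],
                             if (is.null(kinds)) NULL else kinds[i])
    out_prov <- c(out_prov, rep(prov, n))
  }
  if (!length(out_s)) {
    out <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(windows))
    out$source <- IRanges::CharacterList(vector("list", 0L))
    return(out)
  }
  peaks <- GenomicRanges::GRanges(
    seqnames = out_sn,
    ranges = IRanges::IRanges(start = out_s, end = out_e),
    source = IRanges::relist(
      out_prov, IRanges::PartitioningByEnd(seq_along(out_prov))),
    seqinfo = GenomeInfoDb::seqinfo(windows))
  collapse_identical_sites(peaks)
}

# Collapse exactly identical intervals, taking the union of their provenance
# entries; output sorted by (contig, start, end).
collapse_identical_sites <- function(sites) {
  key <- paste(as.character(GenomicRanges::seqnames(sites)),
               GenomicRanges::start(sites), GenomicRanges::end(sites))
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  out <- sites[first]
  src_all <- as.list(sites$source)
  src <- lapply(split(seq_along(sites), grp), function(idx) {
    sort(unique(unlist(src_all[idx], use.names = FALSE)))
  })
  out$source <- IRanges::CharacterList(unname(src))
  sort_sites(out)
}
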