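#' Compile per-sample peak lists into a master list
#'
#' Takes the union of peak intervals across all samples and conditions;
#' exactly identical intervals are collapsed with merged provenance. The
#' result is sorted by (contig, start, end).
#'
#' @param peak_lists A list of \code{GRanges}, one per sample, from
#'   \code{\link{call_sample_peaks}}.
#' @param contigs A \code{contig_table}; sites on unknown contigs are an
#'   error.
#' @return A sorted \code{GRanges} of unique sites.
#' @export
compile_master_list <- function(peak_lists, contigs) {
  stopifnot(is.list(peak_lists))
  peak_lists <- peak_lists[vapply(peak_lists, length, integer(1)) > 0L]
  if (!length(peak_lists)) {
    out <- GenomicRanges::GRanges(seqinfo = contig_seqinfo(contigs))
    out$source <- IRanges::CharacterList(vector("list", 0L))
    return(out)
  }
  all_sites <- suppressWarnings(do.call(c, unname(peak_lists)))
  validate_against_contigs(all_sites, contigs, what = "site")
  GenomeInfoDb::seqlevels(all_sites) <- names(contigs)
  GenomeInfoDb::seqinfo(all_sites) <- contig_seqinfo(contigs)
  collapse_identical_sites(all_sites)
}

# TRUE at [i, j] when sites i and j (same contig) satisfy the direct-merge
# predicate: |start_i - start_j| <= d AND |end_i - end_j| <= d.
direct_mergeable <- function(starts, ends, d) {
  abs(outer(starts, starts, "-")) <= d & abs(outer(ends, ends, "-")) <= d
}

# Connected components of a logical adjacency matrix (single linkage), via
# label propagation to a fixed point.
adjacency_components <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    new_comp <- vapply(seq_len(n),
                       function(i) min(comp[adj[i, ]]), integer(1))
    if (identical(new_comp, comp)) break
    comp <- new_comp
  }
  match(comp, unique(comp))
}

#' Merge near-identical methylation sites
#'
#' Condenses a master list: two sites on the same contig are directly
#' mergeable when their start coordinates differ by at most
#' \code{merge_dist} bases AND their end coordinates differ by at most
#' \code{merge_dist} bases. Merging is applied over the transitive closure of
#' this relation, repeated until a fixed point, so two sites joined through a
#' chain of intermediates merge even when they differ by more than
#' \code{merge_dist} themselves, and the result does not depend on input
#' order. A merged site spans from the most upstream member start to the most
#' downstream member end, with provenance the union of its members'.
#'
#' Note the predicate compares starts to starts and ends to ends — it is not
#' an interval-gap rule, so a short peak does not merge into a distant long
#' one that happens to share a boundary.
#'
#' @param sites A sorted \code{GRanges} of sites (e.g. from
#'   \code{\link{compile_master_list}}).
#' @param merge_dist Maximum start-to-start and end-to-end distance in bases
#'   (default 100); 0 collapses only exactly identical intervals.
#' @return A sorted \code{GRanges} of merged sites. Idempotent: merging its
#'   own output changes nothing.
#' @export
merge_sites <- function(sites, merge_dist = 100L) {
  merge_dist <- as.integer(merge_dist)
  stopifnot(merge_dist >= 0L)
  if (length(sites) <= 1L) return(sort_sites(sites))
  # work on plain vectors; one GRanges is built at the very end
  sn <- as.character(GenomicRanges::seqnames(sites))
  starts <- GenomicRanges::start(sites)
  ends <- GenomicRanges::end(sites)
  src <- if (is.null(sites$source)) {
    rep(list(character(0)), length(sites))
  } else {
    as.list(sites$source)
  }
  repeat {
    merged <- merge_components(sn, starts, ends, src, merge_dist)
    if (length(merged$start) == length(starts)) break
    sn <- merged$contig; starts <- merged$start; ends <- merged$end
    src <- merged$source
  }
  out <- GenomicRanges::GRanges(
    seqnames = merged$contig,
    ranges = IRanges::IRanges(start = merged$start, end = merged$end),
    source = IRanges::CharacterList(merged$source),
    seqinfo = GenomeInfoDb::seqinfo(sites))
  sort_sites(out)
}

# One closure pass: connected components of the direct-merge predicate per
# contig, each component replaced by its spanning interval; plain vectors in
# and out.
merge_components <- function(sn, starts, ends, src, merge_dist) {
  out_sn <- character(0)
  out_s <- out_e <- integer(0)
  out_src <- list()
  for (idx in split(seq_along(sn), sn)) {
    comp <- adjacency_components(
      direct_mergeable(starts[idx], ends[idx], merge_dist))
    members <- split(idx, comp)
    out_sn <- c(out_sn, rep(sn[idx[1L]], length(members)))
    out_s <- c(out_s, vapply(members, function(m) min(starts[m]), integer(1)))
    out_e <- c(out_e, vapply(members, function(m) max(ends[m]), integer(1)))
    out_src <- c(out_src, lapply(members, function(m)
      sort(unique(unlist(src[m], use.names = FALSE)))))
  }
  list(contig = out_sn, start = out_s, end = out_e, source = unname(out_src))
}

#' Count fragments per consolidated site for every sample
#'
#' A fragment counts toward a site when it overlaps it by at least one base;
#' a fragment overlapping two sites increments both (no unique assignment).
#'
#' @param alignments_by_sample Named list of \code{GRanges}, one per sample.
#' @param sites Consolidated sites (\code{GRanges}).
#' @param condition Named character vector mapping each sample to its
#'   condition label (e.g. \code{c(s1 = "M1", s2 = "M2")}).
#' @return A \code{RangedSummarizedExperiment} with integer assay
#'   \code{counts} (sites x samples), site ids as row names, and
#'   \code{condition} in the column data.
#' @export
count_reads_per_site <- function(alignments_by_sample, sites, condition) {
  samples <- names(alignments_by_sample)
  if (is.null(samples) || any(!nzchar(samples))) {
    stop("alignments_by_sample must be a named list", call. = FALSE)
  }
  missing_cond <- setdiff(samples, names(condition))
  if (length(missing_cond)) {
    stop("no condition label for sample(s): ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  condition <- condition[samples]
  if (length(unique(condition)) != 2L) {
    warning("condition labels form ", length(unique(condition)),
            " group(s); the differential screen requires exactly 2",
            call. = FALSE)
  }
  counts <- vapply(alignments_by_sample, function(aln) {
    GenomicRanges::countOverlaps(sites, aln, minoverlap = 1L,
                                 ignore.strand = TRUE)
  }, integer(length(sites)))
  if (length(sites) == 1L) counts <- matrix(counts, nrow = 1L)
  if (length(sites) == 0L) {
    counts <- matrix(integer(0), nrow = 0L, ncol = length(samples))
  }
  colnames(counts) <- samples
  make_count_matrix(sites, counts, condition)
}
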