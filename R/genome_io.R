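#' Read a contig-sizes table
#'
#' Parses a whitespace-delimited two-column text file (contig name, length in
#' bases) into a named integer vector of contig lengths, preserving file
#' order. This is the genome universe against which every interval in the
#' pipeline is validated.
#'
#' @param path Path to the contig-sizes file.
#' @return A named integer vector of class \code{contig_table}; names are
#'   contig names, values are lengths in bases.
#' @examples
#' tf <- tempfile()
#' writeLines(c("chr1\t1000", "chr2\t500"), tf)
#' read_contig_sizes(tf)
#' @export
read_contig_sizes <- function(path) {
  if (!file.exists(path)) {
    stop("contig-sizes file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(contig_table(character(0), integer(0)))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("contig-sizes line ", which(nf < 2L)[1L],
         " does not have two columns", call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  raw_len <- vapply(fields, `[[`, character(1), 2L)
  dup <- duplicated(nm)
  if (any(dup)) {
    stop("duplicate contig '", nm[dup][1L], "' at line ", which(dup)[1L],
         call. = FALSE)
  }
  len <- suppressWarnings(as.numeric(raw_len))
  bad <- is.na(len) | len != floor(len) | len < 1
  if (any(bad)) {
    stop("non-integer or non-positive contig length '", raw_len[bad][1L],
         "' at line ", which(bad)[1L], call. = FALSE)
  }
  contig_table(nm, as.integer(len))
}

#' Construct a contig table
#'
#' @param names Character vector of contig names (unique).
#' @param lengths Integer vector of contig lengths (>= 1 base each).
#' @return Named integer vector of class \code{contig_table}.
#' @export
contig_table <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.integer(lengths)
  stopifnot(length(names) == length(lengths))
  if (anyDuplicated(names)) stop("duplicate contig names", call. = FALSE)
  if (length(lengths) && any(lengths < 1L)) {
    stop("contig lengths must be >= 1", call. = FALSE)
  }
  structure(stats::setNames(lengths, names), class = "contig_table")
}

#' @export
print.contig_table <- function(x, ...) {
  cat("contig_table with", length(x), "contigs\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

# Seqinfo for GRanges construction from a contig table.
contig_seqinfo <- function(contigs) {
  GenomeInfoDb::Seqinfo(seqnames = names(contigs),
                        seqlengths = as.integer(contigs))
}

# Validate that a GRanges lies inside the contig universe; `what` names the
# object kind in error messages.
validate_against_contigs <- function(gr, contigs, what = "interval") {
  sn <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(sn), names(contigs))
  if (length(unknown)) {
    stop(what, " on unknown contig(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  lens <- unname(unclass(contigs)[sn])
  bad <- GenomicRanges::start(gr) < 1L | GenomicRanges::end(gr) > lens
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(what, " ", sn[i], ":", GenomicRanges::start(gr)[i] - 1L, "-",
         GenomicRanges::end(gr)[i], " exceeds contig bounds (length ",
         lens[i], ")", call. = FALSE)
  }
  invisible(gr)
}

#' Read aligned MBD-Seq fragments from a BED file
#'
#' Reads a BED3+ file of aligned, deduplicated fragment spans. Only the first
#' three columns are used; the rest are ignored. Fragments are strandless:
#' MBD capture enriches double-stranded fragments, so read orientation does
#' not affect depth. Coordinates on disk are 0-based half-open (BED); the
#' returned \code{GRanges} uses the usual 1-based closed R convention.
#'
#' @param path Path to the BED file.
#' @param contigs A \code{contig_table}; every interval is validated against
#'   it (unknown contig or out-of-bounds interval is an error).
#' @param sample_id Label attached to every fragment (metadata column
#'   \code{sample_id}).
#' @return A \code{GRanges} of fragment spans in file order.
#' @export
read_alignments_bed <- function(path, contigs, sample_id) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (!file.exists(path)) {
    stop("alignment BED file not found: ", path, call. = FALSE)
  }
  empty <- GenomicRanges::GRanges(seqinfo = contig_seqinfo(contigs))
  empty$sample_id <- character(0)
  if (file.size(path) == 0L) return(empty)
  # parse only the first three tab-separated fields so rows with different
  # numbers of extra columns are accepted (extra columns are ignored)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED input needs at least 3 columns (line ", which(nf < 3L)[1L],
         "): ", path, call. = FALSE)
  }
  contig <- vapply(fields, `[[`, character(1L), 1L)
  s0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 3L)))
  if (anyNA(s0) || anyNA(e0) ||
      any(s0 != floor(s0)) || any(e0 != floor(e0))) {
    stop("non-integer BED coordinates in ", path, call. = FALSE)
  }
  if (any(s0 < 0) || any(e0 <= s0)) {
    i <- which(s0 < 0 | e0 <= s0)[1L]
    stop("invalid BED interval at line ", i, ": start=", s0[i],
         " end=", e0[i], call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = as.integer(s0) + 1L,
                              end = as.integer(e0)))
  validate_against_contigs(gr, contigs, what = "alignment")
  GenomeInfoDb::seqlevels(gr) <- names(contigs)
  GenomeInfoDb::seqinfo(gr) <- contig_seqinfo(contigs)
  gr$sample_id <- rep(sample_id, length(gr))
  gr
}

#' Read transcript records from GTF or BED6
#'
#' GTF input (1-based inclusive on disk) is parsed with
#' \code{rtracklayer::import} and filtered to the requested feature type;
#' BED6 input is read directly. Transcripts on contigs absent from
#' \code{contigs} are dropped with a warning stating how many were dropped.
#'
#' @param path Annotation file path.
#' @param contigs A \code{contig_table}.
#' @param format Either \code{"gtf"} or \code{"bed6"}.
#' @param feature GTF feature type to keep (default \code{"transcript"}).
#' @return A \code{GRanges} of transcripts with metadata column
#'   \code{transcript_id} and strand set to \code{+} or \code{-}.
#' @export
read_transcripts <- function(path, contigs, format = c("gtf", "bed6"),
                             feature = "transcript") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("transcript annotation not found: ", path, call. = FALSE)
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == feature]
    if (length(gr) && (is.null(gr$transcript_id) ||
                       anyNA(gr$transcript_id))) {
      stop("GTF record of type '", feature,
           "' is missing a transcript_id attribute", call. = FALSE)
    }
    tx_id <- if (length(gr)) as.character(gr$transcript_id) else character(0)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             comment.char = "", quote = "",
                             colClasses = c("character", "numeric", "numeric",
                                            "character", "character",
                                            "character"))
    if (ncol(tab) < 6L) stop("BED6 input requires 6 columns", call. = FALSE)
    gr <- GenomicRanges::GRanges(
      seqnames = tab[[1L]],
      ranges = IRanges::IRanges(start = as.integer(tab[[2L]]) + 1L,
                                end = as.integer(tab[[3L]])),
      strand = tab[[6L]])
    tx_id <- tab[[4L]]
  }
  str <- as.character(GenomicRanges::strand(gr))
  if (any(!str %in% c("+", "-"))) {
    bad <- tx_id[!str %in% c("+", "-")][1L]
    stop("transcript '", bad, "' has no strand (must be + or -)",
         call. = FALSE)
  }
  keep <- as.character(GenomicRanges::seqnames(gr)) %in% names(contigs)
  if (any(!keep)) {
    warning(sum(!keep), " transcript(s) on contigs absent from the contig ",
            "table were dropped", call. = FALSE)
    gr <- gr[keep]
    tx_id <- tx_id[keep]
  }
  out <- GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    ranges = GenomicRanges::ranges(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    seqinfo = contig_seqinfo(contigs))
  out$transcript_id <- as.character(tx_id)
  validate_against_contigs(out, contigs, what = "transcript")
  out
}

#' Site identifiers
#'
#' A site id encodes the interval in the on-disk (0-based half-open)
#' convention: \code{"contig:start-end"}.
#'
#' @param sites A \code{GRanges} of methylation sites.
#' @return Character vector of ids.
#' @export
site_id <- function(sites) {
  sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(sites)),
          GenomicRanges::start(sites) - 1L, GenomicRanges::end(sites))
}

#' Write methylation sites as BED4
#'
#' Sites are written in contig-table order then by start, as BED4 with the
#' site id in the name column. Coordinates are converted to BED (0-based
#' half-open) on write.
#'
#' @param sites A \code{GRanges} of sites.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_sites_bed <- function(sites, path) {
  ids <- site_id(sites)
  if (anyDuplicated(ids)) {
    stop("duplicate site id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  sites <- sort_sites(sites)
  lines <- sprintf("%s\t%d\t%d\t%s",
                   as.character(GenomicRanges::seqnames(sites)),
                   GenomicRanges::start(sites) - 1L,
                   GenomicRanges::end(sites), site_id(sites))
  writeLines(lines, path)
  invisible(path)
}

#' Read methylation sites from BED
#'
#' Reads BED3/BED4 site intervals (the counterpart of
#' \code{\link{write_sites_bed}}).
#'
#' @param path BED file path.
#' @param contigs A \code{contig_table}.
#' @return A \code{GRanges} of sites with an empty provenance column.
#' @export
read_sites_bed <- function(path, contigs) {
  gr <- read_alignments_bed(path, contigs, sample_id = "sites")
  gr$sample_id <- NULL
  gr$source <- IRanges::CharacterList(vector("list", length(gr)))
  gr
}

# Sort sites by contig-table (seqlevels) order, then start, then end.
sort_sites <- function(sites) {
  o <- order(as.integer(GenomicRanges::seqnames(sites)),
             GenomicRanges::start(sites), GenomicRanges::end(sites))
  sites[o]
}

#' Write a site-by-sample count matrix as TSV
#'
#' First column is the site id, remaining columns one per sample (integer
#' counts). Sample conditions are stored in a single comment line so the file
#' round-trips through \code{\link{read_count_matrix}} exactly.
#'
#' @param se A \code{RangedSummarizedExperiment} from
#'   \code{\link{count_reads_per_site}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_count_matrix <- function(se, path) {
  counts <- SummarizedExperiment::assay(se, "counts")
  samples <- colnames(se)
  cond <- as.character(SummarizedExperiment::colData(se)$condition)
  ids <- rownames(se)
  if (anyDuplicated(ids)) {
    stop("duplicate site id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# condition: ",
                    paste(samples, cond, sep = "=", collapse = ",")), con)
  writeLines(paste(c("site", samples), collapse = "\t"), con)
  if (nrow(counts)) {
    body <- apply(cbind(ids, counts), 1L, paste, collapse = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a count matrix TSV
#'
#' @param path Path written by \code{\link{write_count_matrix}}.
#' @return A \code{RangedSummarizedExperiment} with assay \code{counts},
#'   row ranges reconstructed from the site ids, and \code{condition} in the
#'   column data.
#' @export
read_count_matrix <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "# condition:")) {
    stop("count matrix is missing its condition header line", call. = FALSE)
  }
  cond_spec <- trimws(sub("^# condition:", "", lines[1L]))
  pairs <- strsplit(strsplit(cond_spec, ",")[[1L]], "=")
  cond <- stats::setNames(vapply(pairs, `[[`, character(1), 2L),
                          vapply(pairs, `[[`, character(1), 1L))
  header <- strsplit(lines[2L], "\t")[[1L]]
  samples <- header[-1L]
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body)) {
    fields <- strsplit(body, "\t")
    ids <- vapply(fields, `[[`, character(1), 1L)
    counts <- t(vapply(fields, function(f) as.integer(f[-1L]),
                       integer(length(samples))))
    if (length(samples) == 1L) counts <- matrix(counts, ncol = 1L)
  } else {
    ids <- character(0)
    counts <- matrix(integer(0), nrow = 0L, ncol = length(samples))
  }
  dimnames(counts) <- list(ids, samples)
  sites <- parse_site_ids(ids)
  make_count_matrix(sites, counts, cond[samples])
}

# "contig:start-end" (0-based half-open) -> GRanges.
parse_site_ids <- function(ids) {
  if (!length(ids)) return(GenomicRanges::GRanges())
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- lengths(m) != 4L
  if (any(bad)) stop("unparseable site id: ", ids[bad][1L], call. = FALSE)
  GenomicRanges::GRanges(
    seqnames = vapply(m, `[[`, character(1), 2L),
    ranges = IRanges::IRanges(
      start = as.integer(vapply(m, `[[`, character(1), 3L)) + 1L,
      end = as.integer(vapply(m, `[[`, character(1), 4L))))
}

# Assemble the count container used throughout the screen module.
make_count_matrix <- function(sites, counts, condition) {
  rownames(counts) <- site_id(sites)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = sites,
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   row.names = colnames(counts)))
  se
}
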