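# Independent brute-force oracles. Each re-derives the quantity from first
# principles so it never shares code with the implementation it checks.

# Per-base depth by explicit membership: for each base of [wstart, wend]
# (1-based closed), count intervals covering it.
oracle_depth <- function(starts, ends, wstart, wend) {
  vapply(wstart:wend, function(pos) {
    sum(starts <= pos & ends >= pos)
  }, integer(1))
}

# Maximal runs of depth >= thr, at least min_width long, by left-to-right
# scanning; returns a data.frame of 1-based [from, to] indices into `depth`.
oracle_max_runs <- function(depth, thr, min_width = 1L) {
  from <- integer(0); to <- integer(0)
  in_run <- FALSE
  start <- 0L
  for (i in seq_along(depth)) {
    if (depth[i] >= thr && !in_run) { in_run <- TRUE; start <- i }
    if (depth[i] < thr && in_run) {
      in_run <- FALSE
      if (i - start >= min_width) { from <- c(from, start); to <- c(to, i - 1L) }
    }
  }
  if (in_run && length(depth) - start + 1L >= min_width) {
    from <- c(from, start); to <- c(to, length(depth))
  }
  data.frame(from = from, to = to)
}

# Transitive-closure merge oracle: build the pairwise mergeable relation
# (|dstart| <= d AND |dend| <= d), take its reflexive-transitive closure by
# Floyd-Warshall reachability, replace each equivalence class by its
# spanning interval, and repeat on the result until a fixed point. Single
# contig; returns a sorted data.frame.
oracle_merge <- function(starts, ends, d) {
  s <- starts; e <- ends
  repeat {
    n <- length(s)
    if (n <= 1L) break
    reach <- vapply(seq_len(n), function(j)
      abs(s - s[j]) <= d & abs(e - e[j]) <= d, logical(n))
    for (k in seq_len(n)) {
      reach <- reach | (matrix(reach[, k], n, n) &
                          matrix(reach[k, ], n, n, byrow = TRUE))
    }
    comp <- apply(reach, 1, function(row) which(row)[1])
    ns <- vapply(split(s, comp), min, numeric(1))
    ne <- vapply(split(e, comp), max, numeric(1))
    if (length(ns) == n) break
    s <- ns; e <- ne
  }
  o <- order(s, e)
  data.frame(start = as.integer(s[o]), end = as.integer(e[o]),
             row.names = NULL)
}

# Per-pair overlap counting: counts[i, j] = number of sample j's intervals
# sharing >= 1 base with site i.
oracle_counts <- function(site_starts, site_ends, site_contig,
                          aln_by_sample) {
  n <- length(site_starts)
  out <- matrix(0L, nrow = n, ncol = length(aln_by_sample),
                dimnames = list(NULL, names(aln_by_sample)))
  for (j in seq_along(aln_by_sample)) {
    a <- aln_by_sample[[j]]
    for (i in seq_len(n)) {
      out[i, j] <- sum(a$contig == site_contig[i] &
                         a$start <= site_ends[i] & a$end >= site_starts[i])
    }
  }
  out
}

# Step-up BH from the definition: sort ascending, q_(i) = p_(i) * m / i,
# enforce monotonicity from the largest down, cap at 1, restore order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Median-of-ratios from the definition: reference = per-site geometric mean
# over samples (sites positive in all samples only); factor = median ratio.
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  m <- counts[keep, , drop = FALSE]
  ref <- apply(m, 1, function(r) prod(r)^(1 / length(r)))
  apply(m, 2, function(col) median(col / ref))
}

# Random helpers -------------------------------------------------------------

random_alignments <- function(n, contig, contig_len, max_len = 400L) {
  starts <- sample.int(contig_len - max_len, n, replace = TRUE)
  lens <- sample.int(max_len, n, replace = TRUE)
  GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = starts, width = lens),
    sample_id = rep("s", n))
}

make_window <- function(contig, start, end, contig_len,
                        transcript_id = "txA", region_kind = "promoter") {
  w <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = start, end = end),
    seqinfo = GenomeInfoDb::Seqinfo(contig, contig_len))
  w$transcript_id <- transcript_id
  w$region_kind <- region_kind
  w
}

make_profile <- function(depth, contig = "chr1", wstart = 1L,
                         contig_len = wstart + length(depth) + 1000L) {
  w <- make_window(contig, wstart, wstart + length(depth) - 1L, contig_len)
  structure(list(window = w, depth = as.integer(depth)),
            class = "depth_profile")
}

# Batch variant of make_profile: one GRanges holds every window, so building
# n profiles costs one constructor call plus n cheap subsets.
make_profiles <- function(depths, contig = "chr1") {
  lens <- lengths(depths)
  w <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = 1L, end = pmax(lens, 1L)),
    seqinfo = GenomeInfoDb::Seqinfo(contig, max(lens) + 1001L))
  w$transcript_id <- rep("txA", length(w))
  w$region_kind <- rep("promoter", length(w))
  lapply(seq_along(depths), function(i)
    structure(list(window = w[i], depth = as.integer(depths[[i]])),
              class = "depth_profile"))
}

make_sites <- function(contig, starts, ends, sources = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = starts, end = ends))
  gr$source <- if (is.null(sources)) {
    IRanges::CharacterList(rep(list(character(0)), length(gr)))
  } else {
    IRanges::CharacterList(sources)
  }
  gr
}

ranges_df <- function(gr) {
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}
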