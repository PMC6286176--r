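test_that("master list is the provenance-merged union across samples", {
  ct <- contig_table(c("chr1", "chr2"), c(100000L, 100000L))

  one <- make_sites("chr1", c(101L, 501L, 901L), c(200L, 600L, 1000L),
                    sources = list("s1|tx1|promoter", "s1|tx2|promoter",
                                   "s1|tx3|promoter"))
  expect_length(compile_master_list(list(one), ct), 3L)

  # identical peak in two samples -> one site with both provenances
  a <- make_sites("chr1", 101L, 200L, sources = list("s1|tx1|promoter"))
  b <- make_sites("chr1", 101L, 200L, sources = list("s2|tx1|promoter"))
  m <- compile_master_list(list(a, b), ct)
  expect_length(m, 1L)
  expect_setequal(unlist(m$source), c("s1|tx1|promoter", "s2|tx1|promoter"))

  # sites on unknown contigs are an error
  bad <- make_sites("chrZ", 1L, 10L)
  expect_error(compile_master_list(list(bad), ct), "chrZ")

  # 8 random lists equal the set-union oracle
  set.seed(501)
  lists <- lapply(1:8, function(s) {
    n <- sample(5:30, 1)
    starts <- sample.int(90000L, n)
    make_sites(sample(c("chr1", "chr2"), n, replace = TRUE), starts,
               starts + sample.int(400L, n),
               sources = as.list(sprintf("s%d|tx|promoter", rep(s, n))))
  })
  m <- compile_master_list(lists, ct)
  df_all <- unique(do.call(rbind, lapply(lists, ranges_df)))
  expect_equal(nrow(unique(ranges_df(m))), nrow(df_all))
  expect_setequal(site_id(m),
                  sprintf("%s:%d-%d", df_all$contig, df_all$start - 1L,
                          df_all$end))
})

test_that("the 100-bp merge rule spans members and closes chains", {
  # a single site is untouched
  s1 <- make_sites("chr1", 1001L, 1300L)
  expect_equal(ranges_df(merge_sites(s1, 100L)), ranges_df(s1))

  # worked example: starts and stops each within 100 bp -> spanning site
  # (0-based [1000,1300) + [1050,1350) -> [1000,1350))
  pair <- make_sites("chr1", c(1001L, 1051L), c(1300L, 1350L))
  m <- merge_sites(pair, 100L)
  expect_length(m, 1L)
  expect_equal(GenomicRanges::start(m), 1001L)
  expect_equal(GenomicRanges::end(m), 1350L)

  # chain closure: A-B and B-C mergeable even though A and C differ by 180
  chain <- make_sites("chr1", c(1L, 91L, 181L), c(200L, 290L, 380L))
  m <- merge_sites(chain, 100L)
  expect_length(m, 1L)
  expect_equal(GenomicRanges::start(m), 1L)
  expect_equal(GenomicRanges::end(m), 380L)

  # sharing one boundary is not enough: both start AND stop must be close
  asym <- make_sites("chr1", c(1001L, 1001L), c(1100L, 2000L))
  expect_length(merge_sites(asym, 100L), 2L)

  # merge_dist 0 collapses only exactly identical intervals
  dup <- make_sites("chr1", c(501L, 501L, 502L), c(600L, 600L, 601L))
  expect_length(merge_sites(dup, 0L), 2L)
})

test_that("merging matches the closure oracle, is idempotent and order-free", {
  set.seed(502)
  for (i in 1:60) {
    n <- sample(2:40, 1)
    starts <- sample.int(3000L, n, replace = TRUE)
    ends <- starts + sample.int(500L, n, replace = TRUE)
    sites <- make_sites("chr1", starts, ends)
    d <- sample(c(0L, 50L, 100L, 200L), 1)
    got <- merge_sites(sites, d)
    want <- oracle_merge(starts, ends, d)
    expect_equal(GenomicRanges::start(got), want$start)
    expect_equal(GenomicRanges::end(got), want$end)

    # idempotence
    again <- merge_sites(got, d)
    expect_equal(ranges_df(again), ranges_df(got))

    # input order must not matter
    perm <- sample.int(n)
    got2 <- merge_sites(sites[perm], d)
    expect_equal(ranges_df(got2), ranges_df(got))

    # every input site is contained in exactly one output site
    within <- IRanges::findOverlaps(sites, got, type = "within")
    expect_equal(length(unique(S4Vectors::queryHits(within))), n)
  }

  # provenance is unioned across merged members
  pr <- make_sites("chr1", c(101L, 151L), c(300L, 350L),
                   sources = list("s1|a|promoter", "s2|b|promoter"))
  m <- merge_sites(pr, 100L)
  expect_setequal(unlist(m$source), c("s1|a|promoter", "s2|b|promoter"))
})

test_that("per-site counting matches the pairwise overlap oracle", {
  ct <- contig_table("chr1", 50000L)
  sites <- make_sites("chr1", c(1001L, 2001L), c(1500L, 2500L))
  cond <- c(s1 = "M1", s2 = "M2")

  # no alignments -> all zeros
  empty <- GenomicRanges::GRanges()
  se <- count_reads_per_site(list(s1 = empty, s2 = empty), sites, cond)
  expect_true(all(SummarizedExperiment::assay(se) == 0L))
  expect_equal(dim(se), c(2L, 2L))

  # one alignment exactly equal to one site -> that cell alone is 1
  a1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001L, 1500L))
  se <- count_reads_per_site(list(s1 = a1, s2 = empty), sites, cond)
  expect_equal(unname(SummarizedExperiment::assay(se)),
               matrix(c(1L, 0L, 0L, 0L), 2L))

  # a fragment spanning two sites increments both
  wide <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1400L, 2100L))
  se <- count_reads_per_site(list(s1 = wide, s2 = empty), sites, cond)
  expect_equal(unname(SummarizedExperiment::assay(se)[, "s1"]), c(1L, 1L))

  # random fixtures against the O(n*m) oracle; order-invariant
  set.seed(503)
  for (i in 1:20) {
    starts <- sort(sample.int(40000L, 10L))
    rsites <- make_sites("chr1", starts, starts + sample.int(800L, 10L))
    aln <- lapply(1:4, function(j) random_alignments(50L, "chr1", 45000L))
    names(aln) <- paste0("s", 1:4)
    cond4 <- setNames(rep(c("M1", "M2"), 2L), names(aln))
    se <- count_reads_per_site(aln, rsites, cond4)
    want <- oracle_counts(
      GenomicRanges::start(rsites), GenomicRanges::end(rsites),
      rep("chr1", 10L),
      lapply(aln, function(g) data.frame(
        contig = as.character(GenomicRanges::seqnames(g)),
        start = GenomicRanges::start(g), end = GenomicRanges::end(g))))
    expect_equal(unname(SummarizedExperiment::assay(se)), unname(want))

    shuf <- lapply(aln, function(g) g[sample.int(length(g))])
    se2 <- count_reads_per_site(shuf, rsites, cond4)
    expect_identical(SummarizedExperiment::assay(se),
                     SummarizedExperiment::assay(se2))
  }

  # a non-two-group condition map only warns here
  expect_warning(count_reads_per_site(list(s1 = a1, s2 = empty), sites,
                                      c(s1 = "M1", s2 = "M1")),
                 "exactly 2")
  expect_error(count_reads_per_site(list(s1 = a1, s2 = empty), sites,
                                    c(s1 = "M1")), "s2")
})
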