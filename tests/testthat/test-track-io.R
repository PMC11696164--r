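test_that("bedGraph round-trips and rejects malformed input", {
  cs <- c(chr1 = 1000L)
  t0 <- signal_track(data.frame(chrom = "chr1",
                                start = c(0L, 100L, 400L),
                                end = c(50L, 200L, 900L),
                                value = c(1.25, 0, 7.5)), cs)
  f <- withr::local_tempfile()
  write_bedgraph(t0, f)
  t1 <- read_bedgraph(f, cs)
  expect_equal(t1$data, t0$data)

  # empty file -> empty track
  writeLines(character(0), f)
  expect_equal(nrow(read_bedgraph(f, cs)$data), 0L)

  # overlapping lines rejected with the line number
  writeLines(c("chr1\t0\t100\t1", "chr1\t50\t150\t2"), f)
  expect_error(read_bedgraph(f, cs), "line 2")
  # unknown chromosome rejected
  writeLines("chrX\t0\t10\t1", f)
  expect_error(read_bedgraph(f, cs), "unknown chromosome")
  # wrong field count rejected
  writeLines("chr1\t0\t10", f)
  expect_error(read_bedgraph(f, cs), "line 1")
})

test_that("adjacent equal-value intervals are run-length merged on write", {
  cs <- c(chr1 = 100L)
  t0 <- signal_track(data.frame(chrom = "chr1", start = c(0L, 10L, 20L),
                                end = c(10L, 20L, 30L), value = c(2, 2, 3)),
                     cs)
  f <- withr::local_tempfile()
  write_bedgraph(t0, f)
  expect_length(readLines(f), 2L)
  # per-base signal unchanged by the merge
  expect_equal(track_values(read_bedgraph(f, cs), "chr1"),
               track_values(t0, "chr1"))
})

test_that("fe arithmetic matches trivial cases", {
  cs <- c(chr1 = 200L)
  d <- data.frame(chrom = "chr1", start = 0L, end = 200L, value = 10)
  t10 <- signal_track(d, cs)
  t5 <- signal_track(transform(d, value = 5), cs)
  expect_equal(fold_enrichment(t10, t10, 0.1)$data$value, 1.0)
  expect_equal(fold_enrichment(t10, t5, 0)$data$value, 2.0)
  # all four primary tracks identical -> ratio of ratios is exactly 1
  fe <- fe_ratio(fold_enrichment(t10, t10, 0.1),
                 fold_enrichment(t10, t10, 0.1), 0.1)
  expect_true(all(fe$data$value == 1.0))
})

test_that("fold-enrichment ratio agrees with the per-base oracle", {
  set.seed(101)
  cs <- c(chrA = 10000L)
  for (i in 1:30) {
    a <- rand_track(cs, 30)
    b <- rand_track(cs, 30)
    p <- sample(c(0.1, 0.5, 1), 1L)
    fe <- fold_enrichment(a, b, p)
    want <- oracle_ratio(a, b, p, "chrA")
    got <- track_values(fe, "chrA")
    cov <- !is.na(want)
    expect_equal(got[cov], want[cov])
    # bases covered by neither input carry no output
    expect_true(all(got[!cov] == 0))
    expect_false(any(per_base_covered(fe, "chrA") & !cov))
  }
})

test_that("binning matches the per-base mean oracle and conserves signal", {
  set.seed(202)
  for (i in 1:30) {
    L <- sample(500:3000, 1L)
    cs <- c(chr1 = L)
    tr <- rand_track(cs, 15)
    bs <- sample(c(7L, 10L, 50L), 1L)
    binned <- bin_track(tr, bs)
    expect_equal(binned$data$value, oracle_bin_means(tr, "chr1", bs))
    # conservation of length-weighted mass
    expect_equal(sum(binned$data$value * (binned$data$end - binned$data$start)),
                 sum(track_values(tr, "chr1")))
  }
  # weighted-mean examples
  cs <- c(chr1 = 20L)
  tr <- signal_track(data.frame(chrom = "chr1", start = 0L, end = 5L,
                                value = 10), cs)
  expect_equal(bin_track(tr, 10L)$data$value, c(5, 0))
  const <- signal_track(data.frame(chrom = "chr1", start = 0L, end = 20L,
                                   value = 3.5), cs)
  expect_true(all(bin_track(const, 10L)$data$value == 3.5))
})

test_that("terminal partial bins are averaged over their actual width", {
  cs <- c(chr1 = 25L)
  tr <- signal_track(data.frame(chrom = "chr1", start = 0L, end = 25L,
                                value = 4), cs)
  b <- bin_track(tr, 10L)
  expect_equal(b$data$end - b$data$start, c(10L, 10L, 5L))
  expect_true(all(b$data$value == 4))
})

test_that("masking zeroes signal inside masks and nowhere else", {
  cs <- c(chr1 = 1000L, MAT = 6000L)
  set.seed(303)
  tr <- rand_track(cs, 20)
  masks <- data.frame(chrom = c("chr1", "MAT"),
                      start = c(100L, 4488L), end = c(300L, 5615L))
  m <- mask_intervals(tr, masks)
  for (ch in names(cs)) {
    v0 <- track_values(tr, ch)
    v1 <- track_values(m, ch)
    inmask <- rep(FALSE, cs[[ch]])
    for (i in which(masks$chrom == ch))
      inmask[(masks$start[i] + 1L):masks$end[i]] <- TRUE
    expect_true(all(v1[inmask] == 0))
    expect_equal(v1[!inmask], v0[!inmask])
    # coverage structure untouched
    expect_equal(per_base_covered(m, ch), per_base_covered(tr, ch))
  }
  # whole-chromosome mask -> all-zero chromosome; empty mask list -> identity
  allmask <- mask_intervals(tr, data.frame(chrom = "chr1", start = 0L,
                                           end = 1000L))
  expect_true(all(track_values(allmask, "chr1") == 0))
  expect_equal(mask_intervals(tr, NULL)$data, tr$data)
})

test_that("default config carries the two alignment masks", {
  cfg <- default_config()
  m <- do.call(rbind, lapply(cfg$masks, as.data.frame))
  expect_true(any(m$chrom == "chrII" & m$start == 2109747L & m$end == 2138781L))
  expect_true(any(m$chrom == "MAT" & m$start == 4488L & m$end == 5615L))
})

test_that("invalid tracks are rejected", {
  cs <- c(chr1 = 100L)
  expect_error(signal_track(data.frame(chrom = "chr1", start = 10L, end = 5L,
                                       value = 1), cs), "start < end")
  expect_error(signal_track(data.frame(chrom = "chr1", start = c(0L, 5L),
                                       end = c(10L, 15L), value = 1), cs),
               "overlapping")
  expect_error(signal_track(data.frame(chrom = "chr2", start = 0L, end = 10L,
                                       value = 1), cs), "unknown chromosome")
  expect_error(signal_track(data.frame(chrom = "chr1", start = 0L, end = 10L,
                                       value = -1), cs), ">= 0")
})
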