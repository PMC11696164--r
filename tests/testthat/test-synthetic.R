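test_that("generated repeat copies realize the requested divergence", {
  tr <- small_truth(seed = 11, divergence = 0.04)
  a <- repeat_copy_seq(tr, "cenH")
  b <- repeat_copy_seq(tr, "dh1")
  mism <- mean(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  expect_equal(mism, 0.04, tolerance = 0.01)
  # zero divergence -> byte-identical copies
  tr0 <- small_truth(seed = 11, divergence = 0)
  expect_identical(repeat_copy_seq(tr0, "cenH"), repeat_copy_seq(tr0, "dh1"))
})

test_that("planted motif clusters are rediscoverable by string search", {
  tr <- small_truth(seed = 23)
  expect_gte(nrow(tr$planted_motifs), 6L)
  for (i in seq_len(nrow(tr$planted_motifs))) {
    p <- tr$planted_motifs[i, ]
    word <- substr(tr$genome[[p$chrom]], p$start + 1L, p$start + 5L)
    expect_true(word %in% c("CCAAT", "ATTGG"))
    expect_identical(word, if (p$strand == "+") "CCAAT" else "ATTGG")
  }
  # clusters are planted outside the repeat copies
  for (i in seq_len(nrow(tr$planted_motif_clusters))) {
    cl <- tr$planted_motif_clusters[i, ]
    rc <- tr$repeat_copies[tr$repeat_copies$chrom == cl$chrom, ]
    if (nrow(rc))
      expect_true(all(cl$end <= rc$start | cl$start >= rc$end))
  }
})

test_that("generation is reproducible and validates its configuration", {
  t1 <- small_truth(seed = 5)
  t2 <- small_truth(seed = 5)
  expect_identical(t1$genome, t2$genome)
  expect_identical(t1$planted_motifs, t2$planted_motifs)
  expect_error(generate_genome(2L, c(1000L), seed = 1),
               "lengths")
  expect_error(generate_genome(1L, 3000L,
                               repeat_spec = list(unit_length = 2000L,
                                                  n_copies = 1L,
                                                  divergence = 0.1),
                               seed = 1),
               "unit_length")
  expect_error(generate_genome(1L, 10000L,
                               repeat_spec = list(unit_length = 100L,
                                                  n_copies = 1L,
                                                  divergence = 1.2),
                               seed = 1),
               "divergence")
})

test_that("chip tracks put enrichment where sites were planted", {
  tr <- small_truth(seed = 31)
  tr <- plant_tf_sites(tr, "php5", 3L, seed = 32)
  tracks <- simulate_chip_tracks(tr, "php5", peak_sd_bp = 50, binsize = 10L,
                                 seed = 33)
  fe <- fe_ratio(fold_enrichment(tracks$ip_tagged, tracks$input_tagged),
                 fold_enrichment(tracks$ip_untagged, tracks$input_untagged))
  for (i in seq_len(nrow(tr$planted_sites))) {
    s <- tr$planted_sites[i, ]
    v <- track_values(fe, s$chrom, s$center - 500L, s$center + 500L)
    peak_at <- s$center - 500L + which.max(v) - 1L
    expect_lte(abs(peak_at - s$center), 100L)  # within 2 * peak_sd_bp
    # empirical IP mean under the peak exceeds background
    ip <- track_values(tracks$ip_tagged, s$chrom, s$center - 50L,
                       s$center + 50L)
    expect_gt(mean(ip), 20)
  }
  # tracks cover every chromosome completely
  for (ch in names(tr$chrom_sizes))
    expect_true(all(per_base_covered(tracks$ip_tagged, ch)))
})

test_that("zero enrichment leaves the IP statistically at background", {
  tr <- small_truth(seed = 41)
  tr <- plant_tf_sites(tr, "php5", 3L, enrichment_height = 0, seed = 42)
  tracks <- simulate_chip_tracks(tr, "php5", background_mean = 5,
                                 binsize = 10L, seed = 43)
  v <- track_values(tracks$ip_tagged, "chr1")
  n_bins <- tr$chrom_sizes[["chr1"]] / 10
  se <- sqrt(5 / n_bins)
  expect_lte(abs(mean(v) - 5), 3 * se)
  # fixed seed -> identical output
  again <- simulate_chip_tracks(tr, "php5", background_mean = 5,
                                binsize = 10L, seed = 43)
  expect_identical(tracks, again)
})

test_that("summits fall at planted centers (with and without jitter)", {
  tr <- small_truth(seed = 51)
  tr <- plant_tf_sites(tr, c("php5", "moc3"), 4L, shared_fraction = 0.5,
                       seed = 52)
  su0 <- simulate_summits(tr, 0, seed = 53)
  for (tf in c("php5", "moc3")) {
    centers <- sort(tr$planted_sites$center[tr$planted_sites$tf == tf])
    expect_equal(sort(su0[[tf]]$start), centers)
  }
  # a shared planted site appears in both TFs' summit sets
  shared <- intersect(tr$planted_sites$center[tr$planted_sites$tf == "php5"],
                      tr$planted_sites$center[tr$planted_sites$tf == "moc3"])
  expect_gte(length(shared), 1L)
  expect_true(all(shared %in% su0$php5$start) &&
                all(shared %in% su0$moc3$start))
  # jittered summits stay near centers; TF without sites -> empty set
  su2 <- simulate_summits(tr, 2, seed = 54, tfs = c("php5", "absent"))
  expect_true(all(abs(sort(su2$php5$start) -
                        sort(tr$planted_sites$center[
                          tr$planted_sites$tf == "php5"])) <= 10))
  expect_equal(nrow(su2$absent), 0L)
})

test_that("small-RNA simulation respects strand bias, lengths and region", {
  tr <- small_truth(seed = 61)
  cen <- tr$repeat_copies[tr$repeat_copies$name == "cenH", ]
  region <- list(chrom = cen$chrom, start = cen$start, end = cen$end)
  reads <- simulate_small_rna(tr, region, 400L, strand_bias = 1.0, seed = 62)
  first <- reads[!duplicated(reads$read_id), ]
  expect_true(all(first$strand == "-"))
  expect_true(all(first$length >= 21L & first$length <= 25L))
  expect_true(all(reads$pos >= cen$start & reads$pos + reads$length <= cen$end |
                    reads$n_best > 1L))
  expect_error(simulate_small_rna(tr, list(chrom = "chr1", start = -5L,
                                           end = 100L), 10L, seed = 1),
               "coordinate error")
})

test_that("multi-mapping annotations reflect local repeat identity", {
  tr <- small_truth(seed = 71, divergence = 0.04)
  rc <- tr$repeat_copies
  cen <- rc[rc$name == "cenH", ]
  dh <- rc[rc$name == "dh1", ]
  region <- list(chrom = cen$chrom, start = cen$start, end = cen$end)
  reads <- simulate_small_rna(tr, region, 500L, strand_bias = 0.5, seed = 72)
  first <- reads[!duplicated(reads$read_id), ]
  expect_gt(sum(first$n_best > 1L), 0L)
  for (i in which(first$n_best > 1L)[1:20]) {
    off <- first$pos[i] - cen$start
    a <- substr(tr$genome[[cen$chrom]], first$pos[i] + 1L,
                first$pos[i] + first$length[i])
    b <- substr(tr$genome[[dh$chrom]], dh$start + off + 1L,
                dh$start + off + first$length[i])
    expect_identical(a, b)  # locally identical over the read length
  }
  # reads flagged unique must differ from the homologous dh substring
  uni <- first[first$n_best == 1L & first$pos + first$length <= cen$end &
                 first$pos >= cen$start, ]
  for (i in seq_len(min(20L, nrow(uni)))) {
    off <- uni$pos[i] - cen$start
    a <- substr(tr$genome[[cen$chrom]], uni$pos[i] + 1L,
                uni$pos[i] + uni$length[i])
    b <- substr(tr$genome[[dh$chrom]], dh$start + off + 1L,
                dh$start + off + uni$length[i])
    expect_false(identical(a, b))
  }
})

test_that("plant_introns writes canonical elements and validates input", {
  set.seed(81)
  bg <- paste(sample(c("A", "C", "G", "T"), 600L, TRUE), collapse = "")
  spec <- data.frame(start_offset = c(50L, 200L), length = c(45L, 60L),
                     strand = c("+", "-"))
  pl <- plant_introns(bg, spec)
  expect_equal(nchar(pl$sequence), nchar(bg))
  ii <- pl$introns
  # plus intron: GT at donor, AG ending at acceptor
  expect_identical(substr(pl$sequence, ii$donor[1] + 1, ii$donor[1] + 2), "GT")
  expect_identical(substr(pl$sequence, ii$acceptor[1], ii$acceptor[1] + 1), "AG")
  # minus intron: transcript-oriented GT/AG = plus-strand AC/CT
  expect_identical(substr(pl$sequence, ii$donor[2], ii$donor[2] + 1), "AC")
  expect_identical(substr(pl$sequence, ii$acceptor[2] + 1, ii$acceptor[2] + 2),
                   "CT")
  # zero introns -> identity
  expect_identical(plant_introns(bg, NULL)$sequence, bg)
  # overlap and short introns rejected
  expect_error(plant_introns(bg, data.frame(start_offset = c(0L, 20L),
                                            length = c(40L, 40L),
                                            strand = "+")), "overlapping")
  expect_error(plant_introns(bg, data.frame(start_offset = 0L, length = 20L,
                                            strand = "+")), ">= 30")
})
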