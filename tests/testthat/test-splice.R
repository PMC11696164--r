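test_that("percent identity handles identity, divergence and symmetry", {
  expect_equal(percent_identity("ACGTACGT", "ACGTACGT")$percent_identity, 100)
  set.seed(666)
  a <- paste(sample(c("A", "C", "G", "T"), 2000L, TRUE), collapse = "")
  ch <- strsplit(a, "")[[1L]]
  pos <- sample.int(2000L, 80L)  # exactly 4% substitutions
  ch[pos] <- vapply(ch[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
  b <- paste(ch, collapse = "")
  pid <- percent_identity(a, b)
  expect_equal(pid$percent_identity, 96, tolerance = 0.011)
  # symmetry
  expect_equal(percent_identity(b, a)$percent_identity, pid$percent_identity)
  # the homology map is monotone and complete for a gap-free alignment
  expect_equal(pid$pairs$source_pos, pid$pairs$target_pos)
  expect_equal(nrow(pid$pairs), 2000L)
  expect_error(percent_identity("", "ACGT"), "non-empty")
  expect_error(percent_identity("ACGT", "ACNT"), "ACGT")
})

test_that("identity accounts for gap columns in the denominator", {
  # deletion of 2 bases: 18 matches over 20 columns = 90%
  a <- "ACGTACGTACGTACGTACGT"
  b <- paste0(substr(a, 1L, 9L), substr(a, 12L, 20L))
  pid <- percent_identity(a, b)
  expect_equal(pid$columns, 20L)
  expect_equal(pid$percent_identity, 90)
})

test_that("planted introns are recovered at exact coordinates", {
  set.seed(777)
  for (strand in c("+", "-")) {
    bg <- paste(sample(c("A", "C", "G", "T"), 2400L, TRUE), collapse = "")
    spec <- data.frame(start_offset = seq(100L, by = 360L, length.out = 6L),
                       length = sample(45:90, 6L, TRUE), strand = strand)
    pl <- plant_introns(bg, spec)
    found <- find_candidate_introns(pl$sequence, strand,
                                    intron_scan_config(mode = "all"))
    expect_true(all(intron_key(pl$introns) %in% intron_key(found)))
    # after splice-site mutation none of the planted set is recovered
    mut <- mutate_splice_sites(pl$sequence, pl$introns)
    expect_equal(nchar(mut), nchar(pl$sequence))
    found_mut <- find_candidate_introns(mut, strand,
                                        intron_scan_config(mode = "all"))
    expect_false(any(intron_key(pl$introns) %in% intron_key(found_mut)))
    # the mutation touches at most donor + acceptor + branch per intron
    dist <- sum(strsplit(mut, "")[[1L]] != strsplit(pl$sequence, "")[[1L]])
    expect_lte(dist, 5L * nrow(pl$introns))
  }
})

test_that("scanner honours length bounds and branch requirements", {
  # GT..AG pair shorter than min_len is not reported
  seq <- paste0("GT", strrep("C", 20L), "AG")
  expect_equal(nrow(find_candidate_introns(seq, "+")), 0L)
  # valid length but no branch consensus -> not reported
  seq2 <- paste0("GT", strrep("C", 50L), "AG")
  expect_equal(nrow(find_candidate_introns(seq2, "+")), 0L)
  # adding CTAAC at branch distance makes it a candidate
  ch <- strsplit(seq2, "")[[1L]]
  acc <- length(ch) - 1L  # 0-based acceptor G
  bpos <- acc - 20L       # branch A
  ch[(bpos - 3L + 1L):(bpos + 2L)] <- c("C", "T", "A", "A", "C")
  found <- find_candidate_introns(paste(ch, collapse = ""), "+")
  expect_equal(nrow(found), 1L)
  expect_equal(found$donor, 0L)
  expect_equal(found$acceptor, acc)
  expect_equal(found$branch, bpos)
})

test_that("greedy overlap resolution prefers the shortest acceptor", {
  # one donor, two possible acceptors with branch support: shortest wins
  ch <- strsplit(paste0("GT", strrep("C", 80L)), "")[[1L]]
  place_acc <- function(ch, acc) {
    ch[(acc):(acc + 1L)] <- c("A", "G")  # 1-based A at acc, G at acc+1
    b <- acc - 20L
    ch[(b - 3L):(b + 1L)] <- c("C", "T", "A", "A", "C")
    ch
  }
  ch <- place_acc(ch, 40L)
  ch <- place_acc(ch, 70L)
  seq <- paste(ch, collapse = "")
  greedy <- find_candidate_introns(seq, "+")
  expect_equal(nrow(greedy), 1L)
  expect_equal(greedy$acceptor, 40L)  # 0-based G of the nearer AG
  all_mode <- find_candidate_introns(seq, "+",
                                     intron_scan_config(mode = "all"))
  expect_gte(nrow(all_mode), 2L)
})

test_that("homology projection keeps intact introns and names lost elements", {
  set.seed(888)
  bg <- paste(sample(c("A", "C", "G", "T"), 1200L, TRUE), collapse = "")
  spec <- data.frame(start_offset = c(100L, 400L, 700L), length = 60L,
                     strand = "-")
  pl <- plant_introns(bg, spec)
  # identity target -> identity mapping
  mp <- map_homologous_introns(pl$sequence, pl$introns, pl$sequence)
  expect_equal(nrow(mp$kept), 3L)
  expect_equal(mp$kept$donor, pl$introns$donor)
  expect_equal(mp$kept$acceptor, pl$introns$acceptor)
  # destroy one donor in the target: that intron is rejected as "donor lost"
  ch <- strsplit(pl$sequence, "")[[1L]]
  d <- pl$introns$donor[2L]  # minus-strand donor G at plus d -> plus "AC" at d-1,d
  ch[(d):(d + 1L)] <- c("T", "G")  # 1-based d,d+1 = 0-based d-1,d
  tgt <- paste(ch, collapse = "")
  mp2 <- map_homologous_introns(pl$sequence, pl$introns, tgt)
  expect_equal(nrow(mp2$kept), 2L)
  expect_equal(mp2$rejected$reason, "donor lost")
  # identity below the floor refuses projection
  rand <- paste(sample(c("A", "C", "G", "T"), 1200L, TRUE), collapse = "")
  expect_error(map_homologous_introns(pl$sequence, pl$introns, rand),
               "below")
})

test_that("strand summary tallies plus and minus introns", {
  d <- data.frame(strand = c("-", "-", "-", "-", "-"))
  expect_equal(intron_strand_summary(d), c(plus = 0L, minus = 5L))
  expect_equal(intron_strand_summary(d[0, , drop = FALSE]),
               c(plus = 0L, minus = 0L))
  set.seed(999)
  s <- sample(c("+", "-"), 40L, TRUE)
  expect_equal(unname(intron_strand_summary(data.frame(strand = s))),
               c(sum(s == "+"), sum(s == "-")))
})

test_that("mutate_splice_sites validates its inputs", {
  set.seed(1001)
  bg <- paste(sample(c("A", "C", "G", "T"), 400L, TRUE), collapse = "")
  pl <- plant_introns(bg, data.frame(start_offset = 50L, length = 60L,
                                     strand = "+"))
  # wrong coordinates -> element-not-found error
  shifted <- pl$introns
  shifted$donor <- shifted$donor + 7L
  expect_error(mutate_splice_sites(pl$sequence, shifted), "donor")
  # zero introns -> identity
  expect_identical(mutate_splice_sites(pl$sequence, pl$introns[0, ]),
                   pl$sequence)
})
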