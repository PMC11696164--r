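# Brute-force reference implementations and fixture builders shared across
# the test files. Oracles work per-base / per-element and stay independent
# of the package's interval algebra.

rand_track <- function(chrom_sizes, n_intervals, max_val = 20, gapped = TRUE) {
  rows <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    cuts <- sort(sample.int(L - 1L, min(n_intervals * 2L, L - 2L)))
    st <- c(0L, cuts)
    en <- c(cuts, L)
    keep <- if (gapped) runif(length(st)) < 0.7 else rep(TRUE, length(st))
    keep[en - st <= 0L] <- FALSE
    data.frame(chrom = ch, start = st[keep], end = en[keep],
               value = round(runif(sum(keep), 0, max_val), 3))
  })
  signal_track(do.call(rbind, rows), chrom_sizes)
}

# per-base oracle for the pseudocount ratio of two tracks, restricted to
# bases covered by at least one input
oracle_ratio <- function(a, b, p, chrom) {
  va <- track_values(a, chrom)
  vb <- track_values(b, chrom)
  ca <- per_base_covered(a, chrom)
  cb <- per_base_covered(b, chrom)
  out <- (va + p) / (vb + p)
  out[!(ca | cb)] <- NA
  out
}

per_base_covered <- function(track, chrom) {
  L <- track$chrom_sizes[[chrom]]
  cov <- logical(L)
  d <- track$data[track$data$chrom == chrom, ]
  for (i in seq_len(nrow(d))) cov[(d$start[i] + 1L):d$end[i]] <- TRUE
  cov
}

oracle_bin_means <- function(track, chrom, binsize) {
  v <- track_values(track, chrom)  # uncovered bases are 0 by definition
  L <- length(v)
  nb <- ceiling(L / binsize)
  vapply(seq_len(nb) - 1L, function(b) {
    mean(v[(b * binsize + 1L):min((b + 1L) * binsize, L)])
  }, numeric(1L))
}

# connected components of expanded summits under the strict-overlap rule
# (>= 1 shared bp; abutting half-open intervals stay separate), computed by
# transitive closure of the pairwise overlap graph
oracle_merge <- function(summits_by_tf, L, half_width = 25L) {
  iv <- do.call(rbind, lapply(summits_by_tf, function(s)
    data.frame(start = pmax(0L, s$start - half_width),
               end = pmin(L, s$start + half_width))))
  n <- nrow(iv)
  if (!n) return(data.frame(start = integer(), end = integer()))
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    iv$start[i] < iv$end[j] & iv$start[j] < iv$end[i])
  reach <- adj
  repeat {
    nxt <- reach | (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      nc <- nc + 1L
      comp[reach[i, ]] <- nc
    }
  }
  out <- data.frame(start = tapply(iv$start, comp, min),
                    end = tapply(iv$end, comp, max))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# transitive closure of the "gap <= max_gap" adjacency graph
oracle_collapse <- function(starts, max_gap, motif_len = 5L) {
  n <- length(starts)
  if (n == 0L) return(0L)
  adj <- outer(starts, starts, function(x, y)
    abs(x - y) - motif_len <= max_gap)
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      nc <- nc + 1L
      comp[reach[i, ]] <- nc
    }
  }
  nc
}

oracle_hyper_tail <- function(shared, na, nb, universe) {
  k <- shared:min(na, nb)
  sum(stats::dhyper(k, na, universe - na, nb))
}

# naive O(n*m) scan for a motif and its reverse complement
oracle_motif_scan <- function(seq, motif) {
  rc <- tfhet::rev_comp(motif)
  m <- nchar(motif)
  hits <- list()
  for (p in seq_len(nchar(seq) - m + 1L)) {
    w <- substr(seq, p, p + m - 1L)
    if (w == motif) hits[[length(hits) + 1L]] <- c(p - 1L, 1L)
    if (rc != motif && w == rc) hits[[length(hits) + 1L]] <- c(p - 1L, 2L)
  }
  if (!length(hits)) return(data.frame(start = integer(), strand = character()))
  m <- do.call(rbind, hits)
  data.frame(start = m[, 1L], strand = c("+", "-")[m[, 2L]])
}

# motif-free background: period-3 ACG repeat contains neither CCAAT nor ATTGG
motif_free_seq <- function(n) {
  paste(rep_len(c("A", "C", "G"), n), collapse = "")
}

small_truth <- function(seed = 7, lengths = c(20000L, 20000L),
                        divergence = 0.04) {
  generate_genome(2L, lengths, 0.36,
                  repeat_spec = list(unit_length = 2000L, n_copies = 2L,
                                     divergence = divergence),
                  motif_spec = list(n_clusters = 3L, motifs_per_cluster = 2L,
                                    gap_range = c(5L, 25L)),
                  seed = seed)
}

repeat_copy_seq <- function(truth, name) {
  rc <- truth$repeat_copies[truth$repeat_copies$name == name, ]
  substr(truth$genome[[rc$chrom]], rc$start + 1L, rc$end)
}

intron_key <- function(d) paste(d$strand, d$donor, d$branch, d$acceptor)
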