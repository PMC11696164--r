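## Seeded synthetic-data generator.
##
## Emulates the statistical structure of the study inputs: a small
## multi-chromosome genome carrying a repeat family (near-identical copies at
## a stated divergence, standing in for the cenH / centromeric dh homology),
## planted CCAAT clusters, planted TF-bound sites with Gaussian ChIP
## enrichment over Poisson background, strand-biased 21-25 nt small-RNA
## reads (some multi-mapping across repeat copies), and planted canonical
## GT..AG introns. Every operation takes a mandatory seed and routes all
## randomness through it.

.DNA <- c("A", "C", "G", "T")

.random_dna <- function(n, gc) {
  paste(sample(.DNA, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.substr_set <- function(seq_chars, start0, repl_chars) {
  seq_chars[start0 + seq_len(length(repl_chars))] <- repl_chars
  seq_chars
}

#' Generate a synthetic genome with planted truth
#'
#' Builds `n_chroms` random chromosomes at the stated GC fraction, plants a
#' repeat family (`n_copies` copies of one unit diverged by point
#' substitutions only; the first copy is named `cenH`, subsequent copies
#' `dh1`, `dh2`, ...), and plants CCAAT-box clusters (each motif written as
#' CCAAT or its reverse complement ATTGG on a random strand) outside the
#' repeat copies. The realized divergence is exact: `round(divergence *
#' unit_length)` positions are substituted, so two copies generated at
#' divergence 0.04 share 96% identity.
#'
#' @param n_chroms number of chromosomes.
#' @param lengths integer vector of chromosome lengths (bp), one per
#'   chromosome; each must exceed twice the repeat unit length.
#' @param gc GC fraction of the random background.
#' @param repeat_spec list with `unit_length`, `n_copies`, `divergence`
#'   (fraction in [0, 1)); `NULL` to plant no repeats.
#' @param motif_spec list with `n_clusters`, `motifs_per_cluster`,
#'   `gap_range` (inclusive range of intervening bp between motif copies);
#'   `NULL` to plant no motif clusters.
#' @param seed mandatory integer seed.
#' @return object of class `SyntheticTruth`: `genome` (named uppercase DNA
#'   strings), `chrom_sizes`, `repeat_copies`, `planted_motif_clusters`,
#'   `planted_motifs`, `planted_sites` (empty until [plant_tf_sites()]),
#'   `planted_introns`, `seed`.
#' @export
generate_genome <- function(n_chroms, lengths, gc = 0.36,
                            repeat_spec = NULL, motif_spec = NULL, seed) {
  stopifnot(n_chroms >= 1L)
  if (length(lengths) != n_chroms)
    stop("configuration error: 'lengths' must have one entry per chromosome")
  if (gc < 0 || gc > 1)
    stop("configuration error: 'gc' must be a fraction in [0, 1]")
  if (!is.null(repeat_spec)) {
    if (!all(c("unit_length", "n_copies", "divergence") %in% names(repeat_spec)))
      stop("configuration error: 'repeat_spec' needs unit_length, n_copies, divergence")
    if (repeat_spec$divergence < 0 || repeat_spec$divergence >= 1)
      stop("configuration error: 'divergence' must satisfy 0 <= divergence < 1")
    if (any(lengths <= 2L * repeat_spec$unit_length))
      stop("configuration error: every entry of 'lengths' must exceed 2 * unit_length")
  }
  withr::with_seed(seed, {
    chrom_names <- paste0("chr", seq_len(n_chroms))
    genome <- lapply(lengths, .random_dna, gc = gc)
    names(genome) <- chrom_names
    occupied <- lapply(chrom_names, function(x)
      data.frame(start = integer(), end = integer()))
    names(occupied) <- chrom_names

    place <- function(chrom, width) {
      ## uniform placement away from chromosome ends, rejecting overlap with
      ## previously placed features
      L <- lengths[[match(chrom, chrom_names)]]
      occ <- occupied[[chrom]]
      for (try in 1:200) {
        s <- sample.int(L - width - 200L, 1L) + 100L
        if (!nrow(occ) || all(s + width <= occ$start | s >= occ$end)) {
          occupied[[chrom]] <<- rbind(occ, data.frame(start = s, end = s + width))
          return(s)
        }
      }
      stop("configuration error: could not place a feature of width ", width,
           " on ", chrom, "; reduce feature count or increase 'lengths'")
    }

    repeat_copies <- data.frame(name = character(), chrom = character(),
                                start = integer(), end = integer(),
                                source_copy = character())
    if (!is.null(repeat_spec) && repeat_spec$n_copies >= 1L) {
      ul <- as.integer(repeat_spec$unit_length)
      unit <- .random_dna(ul, gc)
      for (i in seq_len(repeat_spec$n_copies)) {
        nm <- if (i == 1L) "cenH" else paste0("dh", i - 1L)
        chrom <- chrom_names[(i - 1L) %% n_chroms + 1L]
        s <- place(chrom, ul)
        copy <- unit
        if (i > 1L && repeat_spec$divergence > 0) {
          nmut <- round(repeat_spec$divergence * ul)
          pos <- sample.int(ul, nmut)
          ch <- strsplit(copy, "")[[1L]]
          ch[pos] <- vapply(ch[pos], function(b)
            sample(setdiff(.DNA, b), 1L), character(1L))
          copy <- paste(ch, collapse = "")
        }
        gch <- strsplit(genome[[chrom]], "")[[1L]]
        gch <- .substr_set(gch, s, strsplit(copy, "")[[1L]])
        genome[[chrom]] <- paste(gch, collapse = "")
        repeat_copies <- rbind(repeat_copies, data.frame(
          name = nm, chrom = chrom, start = s, end = s + ul,
          source_copy = if (i == 1L) NA_character_ else "cenH"))
      }
    }

    planted_motif_clusters <- data.frame(chrom = character(), start = integer(),
                                         end = integer(), n_motifs = integer())
    planted_motifs <- data.frame(chrom = character(), start = integer(),
                                 strand = character())
    if (!is.null(motif_spec) && motif_spec$n_clusters >= 1L) {
      gr <- as.integer(motif_spec$gap_range)
      if (length(gr) != 2L || gr[1L] > gr[2L] || gr[1L] < 0L)
        stop("configuration error: 'gap_range' must be a non-negative (lo, hi) pair")
      m <- as.integer(motif_spec$motifs_per_cluster)
      for (k in seq_len(motif_spec$n_clusters)) {
        gaps <- if (m > 1L) sample(gr[1L]:gr[2L], m - 1L, replace = TRUE)
                else integer(0)
        width <- 5L * m + sum(gaps)
        chrom <- sample(chrom_names, 1L)
        s <- place(chrom, width)
        pos <- s + cumsum(c(0L, gaps + 5L))[seq_len(m)]
        strands <- sample(c("+", "-"), m, replace = TRUE)
        gch <- strsplit(genome[[chrom]], "")[[1L]]
        for (j in seq_len(m)) {
          word <- if (strands[j] == "+") c("C", "C", "A", "A", "T")
                  else c("A", "T", "T", "G", "G")
          gch <- .substr_set(gch, pos[j], word)
        }
        genome[[chrom]] <- paste(gch, collapse = "")
        planted_motif_clusters <- rbind(planted_motif_clusters, data.frame(
          chrom = chrom, start = s, end = s + width, n_motifs = m))
        planted_motifs <- rbind(planted_motifs, data.frame(
          chrom = chrom, start = pos, strand = strands))
      }
    }

    structure(list(genome = unlist(genome),
                   chrom_sizes = stats::setNames(as.integer(lengths), chrom_names),
                   repeat_copies = repeat_copies,
                   planted_motif_clusters = planted_motif_clusters,
                   planted_motifs = planted_motifs,
                   planted_sites = data.frame(tf = character(), chrom = character(),
                                              start = integer(), end = integer(),
                                              center = integer(), height = numeric()),
                   planted_introns = .empty_introns(),
                   seed = seed),
              class = "SyntheticTruth")
  })
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf(paste0("SyntheticTruth: %d chromosome(s), %d repeat copies, ",
                     "%d motif clusters, %d planted TF sites, %d planted introns\n"),
              length(x$genome), nrow(x$repeat_copies),
              nrow(x$planted_motif_clusters), nrow(x$planted_sites),
              nrow(x$planted_introns)))
  invisible(x)
}

#' Plant TF-bound sites into a synthetic truth
#'
#' Draws site centers from a regular candidate grid (spacing `spacing` bp,
#' keeping peaks separable) without replacement. A fraction of each TF's
#' sites is drawn from a common shared pool so that merged summit libraries
#' exercise multi-TF sites.
#'
#' @param truth `SyntheticTruth`.
#' @param tf_names character vector of TF names.
#' @param n_sites_per_tf sites planted per TF.
#' @param enrichment_height peak height added to the IP-tagged track mean at
#'   the site center (track counts per bin).
#' @param width site width (bp).
#' @param shared_fraction fraction of each TF's sites drawn from the shared
#'   pool (0 = all private).
#' @param spacing candidate-grid spacing (bp).
#' @param seed mandatory integer seed.
#' @return the truth with `planted_sites` filled in.
#' @export
plant_tf_sites <- function(truth, tf_names, n_sites_per_tf,
                           enrichment_height = 60, width = 50L,
                           shared_fraction = 0, spacing = 1500L, seed) {
  stopifnot(inherits(truth, "SyntheticTruth"),
            shared_fraction >= 0, shared_fraction <= 1)
  withr::with_seed(seed, {
    grid <- do.call(rbind, lapply(names(truth$chrom_sizes), function(ch) {
      L <- truth$chrom_sizes[[ch]]
      centers <- seq(1000L, L - 1000L, by = as.integer(spacing))
      data.frame(chrom = ch, center = as.integer(centers))
    }))
    n_shared <- round(shared_fraction * n_sites_per_tf)
    n_priv <- n_sites_per_tf - n_shared
    need <- n_shared + n_priv * length(tf_names)
    if (need > nrow(grid))
      stop("configuration error: not enough room for ", need,
           " sites; increase 'lengths' or reduce sites per TF")
    pick <- grid[sample.int(nrow(grid), need), , drop = FALSE]
    shared <- pick[seq_len(n_shared), , drop = FALSE]
    rest <- pick[setdiff(seq_len(nrow(pick)), seq_len(n_shared)), , drop = FALSE]
    rows <- list()
    for (i in seq_along(tf_names)) {
      priv <- rest[seq_len(n_priv) + (i - 1L) * n_priv, , drop = FALSE]
      sel <- rbind(shared, priv)
      if (nrow(sel))
        rows[[i]] <- data.frame(tf = tf_names[i], chrom = sel$chrom,
                                start = sel$center - width %/% 2L,
                                end = sel$center - width %/% 2L + width,
                                center = sel$center,
                                height = enrichment_height)
    }
    truth$planted_sites <- do.call(rbind, rows)
    rownames(truth$planted_sites) <- NULL
    truth
  })
}

#' Simulate the four ChIP track types for one TF
#'
#' Input and untagged tracks are Poisson(`background_mean`) per bin; the
#' IP-tagged track additionally carries a Gaussian bump of the planted
#' height (evaluated at bin centers, s.d. `peak_sd_bp`) at each site planted
#' for `tf`. Tracks cover every chromosome completely.
#'
#' @param truth `SyntheticTruth` with planted sites.
#' @param tf TF name whose sites receive enrichment.
#' @param background_mean Poisson mean per bin (> 0).
#' @param peak_sd_bp Gaussian peak s.d. in bp.
#' @param binsize bin width in bp.
#' @param seed mandatory integer seed.
#' @return named list of four `SignalTrack`s: `ip_tagged`, `input_tagged`,
#'   `ip_untagged`, `input_untagged`.
#' @export
simulate_chip_tracks <- function(truth, tf, background_mean = 20,
                                 peak_sd_bp = 50, binsize = 10L, seed) {
  stopifnot(inherits(truth, "SyntheticTruth"), background_mean > 0,
            peak_sd_bp > 0, binsize >= 1L)
  binsize <- as.integer(binsize)
  sites <- truth$planted_sites[truth$planted_sites$tf == tf, , drop = FALSE]
  withr::with_seed(seed, {
    one_track <- function(with_peaks) {
      rows <- lapply(names(truth$chrom_sizes), function(ch) {
        L <- truth$chrom_sizes[[ch]]
        nb <- as.integer(ceiling(L / binsize))
        bs <- (seq_len(nb) - 1L) * binsize
        be <- pmin(bs + binsize, L)
        v <- as.numeric(stats::rpois(nb, background_mean))
        if (with_peaks) {
          bc <- (bs + be) / 2
          for (i in seq_len(nrow(sites))) {
            if (sites$chrom[i] != ch) next
            v <- v + sites$height[i] *
              exp(-0.5 * ((bc - sites$center[i]) / peak_sd_bp)^2)
          }
        }
        data.frame(chrom = ch, start = bs, end = be, value = v)
      })
      tr <- signal_track(do.call(rbind, rows), truth$chrom_sizes)
      tr$binsize <- binsize
      tr
    }
    list(ip_tagged = one_track(TRUE),
         input_tagged = one_track(FALSE),
         ip_untagged = one_track(FALSE),
         input_untagged = one_track(FALSE))
  })
}

#' Simulate per-TF summit records
#'
#' One summit per planted site: a 1-bp interval at the site center plus
#' rounded Gaussian jitter, clamped to the chromosome, scored by the planted
#' enrichment height. TFs with no planted sites yield empty records.
#'
#' @param truth `SyntheticTruth`.
#' @param jitter_sd_bp s.d. of the positional jitter (>= 0).
#' @param seed mandatory integer seed.
#' @param tfs TFs to emit (default: every TF with planted sites).
#' @return named list of data.frames with columns `chrom`, `start`, `end`,
#'   `name`, `score` (0-based half-open 1-bp intervals).
#' @export
simulate_summits <- function(truth, jitter_sd_bp = 0, seed,
                             tfs = unique(truth$planted_sites$tf)) {
  stopifnot(inherits(truth, "SyntheticTruth"), jitter_sd_bp >= 0)
  withr::with_seed(seed, {
    out <- lapply(tfs, function(tf) {
      sites <- truth$planted_sites[truth$planted_sites$tf == tf, , drop = FALSE]
      if (!nrow(sites))
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = numeric()))
      jit <- round(stats::rnorm(nrow(sites), 0, jitter_sd_bp))
      pos <- pmin(pmax(sites$center + as.integer(jit), 0L),
                  truth$chrom_sizes[sites$chrom] - 1L)
      data.frame(chrom = sites$chrom, start = as.integer(pos),
                 end = as.integer(pos) + 1L,
                 name = sprintf("%s_summit_%d", tf, seq_len(nrow(sites))),
                 score = sites$height)
    })
    names(out) <- tfs
    out
  })
}

#' Simulate strand-biased small-RNA reads from a region
#'
#' Reads are placed uniformly within `region` with lengths drawn from
#' `length_dist` over 21..25 nt; a fraction `strand_bias` falls on the minus
#' ("bottom") strand. When `multimap_from_repeat` is set, a read drawn
#' entirely from within a repeat copy is checked against the homologous
#' offset of every other copy; if the local sequence is identical over the
#' read length the alignment is reported at every such position and
#' `n_best` is the number of equally scoring alignments.
#'
#' @param truth `SyntheticTruth`.
#' @param region list or one-row data.frame with `chrom`, `start`, `end`.
#' @param n_reads number of reads.
#' @param strand_bias fraction of reads on the minus strand.
#' @param length_dist named numeric vector of probabilities over read
#'   lengths (default uniform on 21:25).
#' @param multimap_from_repeat annotate repeat-derived reads with all
#'   equally scoring positions across copies.
#' @param seed mandatory integer seed.
#' @return data.frame of alignments (one row per reported alignment):
#'   `read_id`, `chrom`, `pos` (0-based leftmost), `strand`, `length`,
#'   `n_best`, `seq`.
#' @export
simulate_small_rna <- function(truth, region, n_reads, strand_bias = 0.5,
                               length_dist = NULL, multimap_from_repeat = TRUE,
                               seed) {
  stopifnot(inherits(truth, "SyntheticTruth"),
            strand_bias >= 0, strand_bias <= 1, n_reads >= 0)
  chrom <- region$chrom
  if (!chrom %in% names(truth$chrom_sizes))
    stop("coordinate error: unknown chromosome ", chrom)
  L <- truth$chrom_sizes[[chrom]]
  if (region$start < 0 || region$end > L || region$start >= region$end)
    stop("coordinate error: region outside the genome")
  if (is.null(length_dist))
    length_dist <- stats::setNames(rep(1 / 5, 5), 21:25)
  lens <- as.integer(names(length_dist))
  if (any(is.na(lens))) stop("length_dist must be named by read length")
  withr::with_seed(seed, {
    rl <- sample(lens, n_reads, replace = TRUE, prob = length_dist)
    maxs <- region$end - rl
    pos <- region$start +
      floor(stats::runif(n_reads) * (maxs - region$start + 1L))
    strand <- ifelse(stats::runif(n_reads) < strand_bias, "-", "+")
    rows <- vector("list", n_reads)
    rc <- truth$repeat_copies
    for (i in seq_len(max(n_reads, 0L))) {
      p <- as.integer(pos[i]); n <- rl[i]
      plus_seq <- substr(truth$genome[[chrom]], p + 1L, p + n)
      sq <- if (strand[i] == "-") rev_comp(plus_seq) else plus_seq
      aln <- data.frame(chrom = chrom, pos = p, strand = strand[i])
      if (multimap_from_repeat && nrow(rc)) {
        home <- which(rc$chrom == chrom & rc$start <= p & p + n <= rc$end)
        if (length(home) == 1L) {
          off <- p - rc$start[home]
          for (j in setdiff(seq_len(nrow(rc)), home)) {
            tp <- rc$start[j] + off
            if (tp + n > rc$end[j]) next
            tseq <- substr(truth$genome[[rc$chrom[j]]], tp + 1L, tp + n)
            if (identical(tseq, plus_seq))
              aln <- rbind(aln, data.frame(chrom = rc$chrom[j], pos = tp,
                                           strand = strand[i]))
          }
        }
      }
      aln$read_id <- sprintf("read%06d", i)
      aln$length <- n
      aln$n_best <- nrow(aln)
      aln$seq <- sq
      rows[[i]] <- aln
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(chrom = character(), pos = integer(),
                        strand = character(), read_id = character(),
                        length = integer(), n_best = integer(),
                        seq = character())
    out[c("read_id", "chrom", "pos", "strand", "length", "n_best", "seq")]
  })
}

#' Plant canonical introns into a sequence
#'
#' Writes a donor GT, an acceptor AG and a branch-point consensus instance
#' (default CTAAC, matching the fungal CTRAY consensus, with its branch A 20
#' nt upstream of the acceptor G) into the sequence at each requested
#' offset, on the stated strand. Introns must not overlap and must be at
#' least 30 nt long.
#'
#' @param sequence DNA string (plus strand of the host).
#' @param introns data.frame with columns `start_offset` (0-based),
#'   `length`, `strand`.
#' @param branch_instance concrete branch sequence written into the intron.
#' @param branch_offset distance (nt, transcript orientation) from the
#'   branch A to the acceptor G.
#' @return list with the modified `sequence` and `introns`, a data.frame of
#'   intron models in plus-strand coordinates (columns strand, donor,
#'   branch, acceptor, start, end, length).
#' @export
plant_introns <- function(sequence, introns, branch_instance = "CTAAC",
                          branch_offset = 20L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (is.null(introns) || !nrow(introns))
    return(list(sequence = sequence, introns = .empty_introns()))
  stopifnot(all(c("start_offset", "length", "strand") %in% names(introns)))
  if (any(introns$length < 30L))
    stop("configuration error: intron length must be >= 30")
  anchor <- .branch_anchor(branch_instance)
  nc <- nchar(branch_instance)
  L <- nchar(sequence)
  o <- order(introns$start_offset)
  introns <- introns[o, , drop = FALSE]
  s <- as.integer(introns$start_offset)
  len <- as.integer(introns$length)
  if (any(s < 0L) || any(s + len > L))
    stop("configuration error: intron outside the sequence")
  if (nrow(introns) > 1L && any(s[-1L] < (s + len)[-nrow(introns)]))
    stop("configuration error: overlapping introns")
  ch <- strsplit(sequence, "")[[1L]]
  models <- vector("list", nrow(introns))
  for (i in seq_len(nrow(introns))) {
    strand <- introns$strand[i]
    n <- len[i]
    ## transcript coordinates: donor G at 0, acceptor G at n-1,
    ## branch A at n-1-branch_offset
    tdonor <- 0L
    tacc <- n - 1L
    tbranch <- tacc - as.integer(branch_offset)
    tx <- list(
      list(t = c(tdonor, tdonor + 1L), chars = c("G", "T")),
      list(t = c(tacc - 1L, tacc), chars = c("A", "G")),
      list(t = tbranch - anchor + seq_len(nc) - 1L,
           chars = strsplit(branch_instance, "")[[1L]]))
    t2plus <- function(t) if (strand == "+") s[i] + t else s[i] + n - 1L - t
    for (el in tx) {
      p <- t2plus(el$t)
      chars <- if (strand == "-") comp_base(el$chars) else el$chars
      ch[p + 1L] <- chars
    }
    models[[i]] <- data.frame(strand = strand,
                              donor = t2plus(tdonor),
                              branch = t2plus(tbranch),
                              acceptor = t2plus(tacc),
                              start = s[i], end = s[i] + n, length = n)
  }
  list(sequence = paste(ch, collapse = ""),
       introns = do.call(rbind, models))
}

#' Write the genome of a synthetic truth as FASTA
#' @param truth `SyntheticTruth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(truth, path) {
  ss <- Biostrings::DNAStringSet(truth$genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write summit records as 5-column BED
#'
#' chrom, start, end (0-based half-open 1-bp intervals), name, score; no
#' header line.
#'
#' @param summits data.frame as produced by [simulate_summits()] for one TF.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summits_bed <- function(summits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(summits))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%.17g", summits$chrom, summits$start,
                       summits$end, summits$name, summits$score), con)
  invisible(path)
}

#' Read a summit BED file
#' @param path 4- or 5-column BED (chrom, start, end, name[, score]).
#' @return data.frame with columns chrom, start, end, name, score.
#' @export
read_summits_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric()))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED record at line ", which(nf < 3L)[1L], " of ", path)
  mat <- t(vapply(fields, function(f) f[1:5], character(5L)))
  data.frame(chrom = mat[, 1L], start = as.integer(mat[, 2L]),
             end = as.integer(mat[, 3L]),
             name = ifelse(is.na(mat[, 4L]), ".", mat[, 4L]),
             score = suppressWarnings(as.numeric(mat[, 5L])))
}

#' Read a genome FASTA into the named-character representation
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}
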