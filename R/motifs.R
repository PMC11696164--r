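## CCAAT-box counting around peak centers: both-strand motif scan, gap
## collapse (nearby motifs count once), high/low abundance classification.

#' Find motif occurrences on both strands of a region
#'
#' Reports every occurrence of `motif` (plus strand) and of its reverse
#' complement (minus strand) within `region`, in plus-strand coordinates of
#' the 5-mer start, sorted by start. Overlapping occurrences are all
#' reported. For a palindromic motif each position is reported once, on the
#' plus strand.
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open region (defaults to the whole
#'   chromosome).
#' @param motif ACGT string (default `"CCAAT"`, whose reverse complement is
#'   ATTGG).
#' @return data.frame with columns `chrom`, `start`, `strand`.
#' @export
find_motif_hits <- function(genome, chrom, start = 0L, end = NULL,
                            motif = "CCAAT") {
  motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif))
    stop("motif must be a non-empty ACGT string")
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  L <- nchar(genome[[chrom]])
  if (is.null(end)) end <- L
  start <- max(0L, as.integer(start))
  end <- min(L, as.integer(end))
  if (start >= end)
    return(data.frame(chrom = character(), start = integer(),
                      strand = character()))
  seq <- substr(genome[[chrom]], start + 1L, end)
  rc <- rev_comp(motif)
  plus <- .regex_starts0(seq, motif) + start
  hits <- data.frame(chrom = rep(chrom, length(plus)), start = plus,
                     strand = rep("+", length(plus)))
  if (!identical(rc, motif)) {
    minus <- .regex_starts0(seq, rc) + start
    hits <- rbind(hits,
                  data.frame(chrom = rep(chrom, length(minus)), start = minus,
                             strand = rep("-", length(minus))))
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Collapse nearby motif hits into clusters
#'
#' Left-to-right chain over hits sorted by start: a hit joins the current
#' cluster iff the gap to the previous hit is at most `max_gap`. The gap is
#' the intervening sequence length, `next_start - (prev_start + motif
#' length)` (configurable to start-to-start); overlapping hits (negative
#' gap) always collapse. Chaining is transitive, so a cluster's diameter
#' may exceed `max_gap`. A negative `max_gap` disables collapsing and
#' returns the raw count.
#'
#' @param hits data.frame from [find_motif_hits()] (sorted by start).
#' @param max_gap maximum intervening bp (default 25).
#' @param motif_len motif length used for the end coordinate (default 5).
#' @param gap_mode `"end-to-start"` (default) or `"start-to-start"`.
#' @return integer number of clusters.
#' @export
collapse_hits <- function(hits, max_gap = 25L, motif_len = 5L,
                          gap_mode = c("end-to-start", "start-to-start")) {
  gap_mode <- match.arg(gap_mode)
  n <- nrow(hits)
  if (n == 0L) return(0L)
  if (max_gap < 0L) return(n)
  s <- sort(hits$start)
  gaps <- if (gap_mode == "end-to-start") s[-1L] - (s[-n] + motif_len)
          else s[-1L] - s[-n]
  1L + sum(gaps > max_gap)
}

#' Count collapsed CCAAT boxes around a peak center
#'
#' Scans `[center - flank, center + flank)` (clamped at chromosome ends) on
#' both strands; hits whose start lies inside the window are counted even
#' if they straddle its right edge. The collapsed count classifies the
#' locus: `high` iff more than one collapsed box remains.
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom chromosome name.
#' @param center 0-based peak center.
#' @param flank half-window in bp (default 500).
#' @param max_gap collapse rule, see [collapse_hits()].
#' @param motif motif string (default CCAAT).
#' @return one-row data.frame: `chrom`, `window_start`, `window_end`,
#'   `n_raw`, `n_collapsed`, `abundance_class`.
#' @export
count_ccaat_at_peak <- function(genome, chrom, center, flank = 500L,
                                max_gap = 25L, motif = "CCAAT") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  L <- nchar(genome[[chrom]])
  if (center < 0L || center >= L)
    stop("peak center outside chromosome")
  ws <- max(0L, as.integer(center) - as.integer(flank))
  we <- min(L, as.integer(center) + as.integer(flank))
  m <- nchar(motif)
  ## scan past the right edge so straddling hits (start inside) are seen
  hits <- find_motif_hits(genome, chrom, ws, min(L, we + m - 1L), motif)
  hits <- hits[hits$start >= ws & hits$start < we, , drop = FALSE]
  n_raw <- nrow(hits)
  n_collapsed <- collapse_hits(hits, max_gap, motif_len = m)
  data.frame(chrom = chrom, window_start = ws, window_end = we,
             n_raw = n_raw, n_collapsed = n_collapsed,
             abundance_class = if (n_collapsed > 1L) "high" else "low")
}

#' Classify a site library by CCAAT-box abundance
#'
#' Applies [count_ccaat_at_peak()] at each site center and reports the
#' fraction of sites in the `high` class (more than one collapsed box), the
#' statistic summarized across TF-occupied peaks.
#'
#' @param genome named character vector of chromosome sequences.
#' @param sites site library from [build_site_library()] (needs `site_id`,
#'   `chrom`, `center`).
#' @param flank,max_gap,motif see [count_ccaat_at_peak()].
#' @return data.frame (one row per site, `site_id` first) with attribute
#'   `fraction_high`.
#' @export
classify_library <- function(genome, sites, flank = 500L, max_gap = 25L,
                             motif = "CCAAT") {
  rows <- lapply(seq_len(nrow(sites)), function(i)
    cbind(data.frame(site_id = sites$site_id[i]),
          count_ccaat_at_peak(genome, sites$chrom[i], sites$center[i],
                              flank, max_gap, motif)))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(), chrom = character(),
               window_start = integer(), window_end = integer(),
               n_raw = integer(), n_collapsed = integer(),
               abundance_class = character())
  attr(out, "fraction_high") <-
    if (nrow(out)) mean(out$abundance_class == "high") else NA_real_
  out
}
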