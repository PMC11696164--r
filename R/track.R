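#' Genomic signal tracks
#'
#' A `SignalTrack` holds coordinate-addressed non-negative signal: per
#' chromosome, a sorted set of non-overlapping 0-based half-open intervals
#' each carrying a numeric value. It is the substrate of all track math in
#' the package (fold-enrichment ratios, binning, masking, per-site maxima).
#'
#' @param data data.frame with columns `chrom`, `start`, `end`, `value`.
#'   Coordinates are 0-based half-open; values must be finite and >= 0.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param binsize optional fixed bin width; when set, every interval must
#'   have that width except possibly the chromosome-terminal one.
#' @return object of class `SignalTrack`.
#' @export
signal_track <- function(data, chrom_sizes, binsize = NULL) {
  stopifnot(is.data.frame(data))
  need <- c("chrom", "start", "end", "value")
  if (!all(need %in% names(data)))
    stop("track data needs columns chrom, start, end, value")
  data <- data[need]
  data$chrom <- as.character(data$chrom)
  data$start <- as.integer(data$start)
  data$end <- as.integer(data$end)
  data$value <- as.numeric(data$value)
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector of chromosome lengths")
  chrom_sizes <- stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
  bad <- setdiff(unique(data$chrom), names(chrom_sizes))
  if (length(bad))
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  if (nrow(data)) {
    if (any(data$start < 0L) || any(data$end <= data$start))
      stop("intervals must satisfy 0 <= start < end")
    if (any(data$end > chrom_sizes[data$chrom]))
      stop("interval exceeds chromosome bounds")
    if (any(!is.finite(data$value)) || any(data$value < 0))
      stop("signal values must be finite and >= 0")
    data <- data[order(data$chrom, data$start), , drop = FALSE]
    rownames(data) <- NULL
    for (idx in split(seq_len(nrow(data)), data$chrom)) {
      e <- data$end[idx]
      s <- data$start[idx]
      if (length(idx) > 1L && any(s[-1L] < e[-length(e)]))
        stop("overlapping intervals on chromosome ", data$chrom[idx[1L]])
    }
    if (!is.null(binsize)) {
      w <- data$end - data$start
      last <- !duplicated(data$chrom, fromLast = TRUE)
      if (any(w[!last] != binsize) || any(w[last] > binsize))
        stop("intervals inconsistent with fixed binsize ", binsize)
    }
  }
  structure(list(data = data, chrom_sizes = chrom_sizes,
                 binsize = if (is.null(binsize)) NULL else as.integer(binsize)),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack: %d intervals on %d chromosome(s)%s\n",
              nrow(x$data), length(x$chrom_sizes),
              if (!is.null(x$binsize)) sprintf(", fixed binsize %d bp", x$binsize) else ""))
  invisible(x)
}

is_signal_track <- function(x) inherits(x, "SignalTrack")

## value of each query segment [st_i, ...) given sorted disjoint rows `d`;
## the query points must not straddle interval boundaries (callers pass
## breakpoint-aligned segments). Uncovered -> 0.
.value_at <- function(d, st) {
  if (!nrow(d)) return(numeric(length(st)))
  idx <- findInterval(st, d$start)
  hit <- idx > 0L & st < d$end[pmax(idx, 1L)]
  out <- numeric(length(st))
  out[hit] <- d$value[idx[hit]]
  out
}

.covered_at <- function(d, st) {
  if (!nrow(d)) return(logical(length(st)))
  idx <- findInterval(st, d$start)
  idx > 0L & st < d$end[pmax(idx, 1L)]
}

.chrom_rows <- function(track, chrom) {
  track$data[track$data$chrom == chrom, , drop = FALSE]
}

#' Per-base values of a track over a window
#'
#' Expands a track to one value per base over `[start, end)`; positions
#' without coverage get 0. Used for per-site maxima and as the reference
#' representation in brute-force checks.
#'
#' @param track SignalTrack.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open window; defaults to the whole
#'   chromosome.
#' @return numeric vector of length `end - start`.
#' @export
track_values <- function(track, chrom, start = 0L, end = NULL) {
  if (!chrom %in% names(track$chrom_sizes))
    stop("unknown chromosome: ", chrom)
  L <- track$chrom_sizes[[chrom]]
  if (is.null(end)) end <- L
  start <- max(0L, as.integer(start))
  end <- min(L, as.integer(end))
  if (end <= start) return(numeric(0))
  out <- numeric(end - start)
  d <- .chrom_rows(track, chrom)
  d <- d[d$end > start & d$start < end, , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    s <- max(d$start[i], start)
    e <- min(d$end[i], end)
    out[(s - start + 1L):(e - start)] <- d$value[i]
  }
  out
}

## Apply f(value_a, value_b) on the union of breakpoints of two tracks,
## keeping segments covered by at least one input.
.binary_track_op <- function(a, b, f) {
  if (!setequal(names(a$chrom_sizes), names(b$chrom_sizes)))
    stop("tracks must cover the same chromosomes")
  if (!identical(a$chrom_sizes[sort(names(a$chrom_sizes))],
                 b$chrom_sizes[sort(names(b$chrom_sizes))]))
    stop("tracks disagree on chromosome sizes")
  pieces <- lapply(sort(names(a$chrom_sizes)), function(chrom) {
    da <- .chrom_rows(a, chrom)
    db <- .chrom_rows(b, chrom)
    brk <- sort(unique(c(da$start, da$end, db$start, db$end)))
    if (length(brk) < 2L) return(NULL)
    st <- brk[-length(brk)]
    en <- brk[-1L]
    keep <- .covered_at(da, st) | .covered_at(db, st)
    if (!any(keep)) return(NULL)
    data.frame(chrom = chrom, start = st[keep], end = en[keep],
               value = f(.value_at(da, st[keep]), .value_at(db, st[keep])))
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric())
  bs <- if (identical(a$binsize, b$binsize)) a$binsize else NULL
  tr <- signal_track(out, a$chrom_sizes)
  tr$binsize <- bs
  tr
}

#' Fold enrichment of an IP track over its input
#'
#' Per-base `(ip + pseudocount) / (input + pseudocount)` on the union of
#' the two tracks' breakpoints; bases covered by neither track are omitted.
#' The pseudocount guards against division by zero where the input has no
#' signal.
#'
#' @param ip,input_ SignalTrack on the same chromosomes.
#' @param pseudocount small non-negative constant added symmetrically.
#' @return SignalTrack of fold-enrichment values.
#' @export
fold_enrichment <- function(ip, input_, pseudocount = 0.1) {
  stopifnot(is_signal_track(ip), is_signal_track(input_), pseudocount >= 0)
  .binary_track_op(ip, input_, function(x, y) (x + pseudocount) / (y + pseudocount))
}

#' Ratio of tagged over untagged fold enrichment
#'
#' Divides the fold enrichment of the tagged IP/input pair by the fold
#' enrichment of the untagged control pair, giving the enrichment track used
#' by all downstream site analysis. Identical arithmetic to
#' [fold_enrichment()]; kept as its own verb because the two steps have
#' different denominators in the experimental design.
#'
#' @inheritParams fold_enrichment
#' @param fe_tagged,fe_untagged fold-enrichment SignalTracks.
#' @return SignalTrack.
#' @export
fe_ratio <- function(fe_tagged, fe_untagged, pseudocount = 0.1) {
  fold_enrichment(fe_tagged, fe_untagged, pseudocount)
}

#' Mean-bin a track into fixed windows
#'
#' Takes the length-weighted mean of the signal over non-overlapping
#' `binsize` bp windows. Positions without coverage contribute 0, so the
#' output covers every chromosome completely; the chromosome-terminal
#' partial bin is averaged over its actual width.
#'
#' @param track SignalTrack.
#' @param binsize window width in bp (default 10).
#' @return SignalTrack with `binsize` set.
#' @export
bin_track <- function(track, binsize = 10L) {
  stopifnot(is_signal_track(track), binsize >= 1L)
  binsize <- as.integer(binsize)
  pieces <- lapply(sort(names(track$chrom_sizes)), function(chrom) {
    L <- track$chrom_sizes[[chrom]]
    nb <- as.integer(ceiling(L / binsize))
    d <- .chrom_rows(track, chrom)
    edges <- unique(c(seq(0L, L, by = binsize), L))
    brk <- sort(unique(c(edges, d$start, d$end)))
    st <- brk[-length(brk)]
    en <- brk[-1L]
    v <- .value_at(d, st)
    mass <- v * (en - st)
    bin <- st %/% binsize
    m <- numeric(nb)
    agg <- rowsum(mass, bin)
    m[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
    bs <- (seq_len(nb) - 1L) * binsize
    be <- pmin(bs + binsize, L)
    data.frame(chrom = chrom, start = bs, end = be, value = m / (be - bs))
  })
  out <- signal_track(do.call(rbind, pieces), track$chrom_sizes)
  out$binsize <- binsize
  out
}

#' Zero signal inside masked intervals
#'
#' Sets the signal to 0 within each mask (the in-package proxy for masking
#' regions from alignment); coverage structure elsewhere is untouched and the
#' masked intervals stay present with value 0, so downstream binning still
#' sees total coverage. Masks on chromosomes absent from the track are
#' ignored.
#'
#' @param track SignalTrack.
#' @param masks data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return SignalTrack.
#' @export
mask_intervals <- function(track, masks) {
  stopifnot(is_signal_track(track))
  if (is.null(masks) || !nrow(masks)) return(track)
  stopifnot(all(c("chrom", "start", "end") %in% names(masks)))
  if (any(masks$start < 0) || any(masks$end <= masks$start))
    stop("masks must satisfy 0 <= start < end")
  pieces <- lapply(sort(names(track$chrom_sizes)), function(chrom) {
    d <- .chrom_rows(track, chrom)
    if (!nrow(d)) return(NULL)
    L <- track$chrom_sizes[[chrom]]
    m <- masks[masks$chrom == chrom, , drop = FALSE]
    if (!nrow(m)) return(d)
    medge <- c(pmax(0L, pmin(as.integer(m$start), L)),
               pmax(0L, pmin(as.integer(m$end), L)))
    brk <- sort(unique(c(d$start, d$end, medge)))
    st <- brk[-length(brk)]
    en <- brk[-1L]
    keep <- .covered_at(d, st)
    v <- .value_at(d, st)
    inmask <- rep(FALSE, length(st))
    for (i in seq_len(nrow(m)))
      inmask <- inmask | (st >= m$start[i] & en <= m$end[i])
    v[inmask] <- 0
    data.frame(chrom = chrom, start = st[keep], end = en[keep],
               value = v[keep])
  })
  out <- do.call(rbind, pieces)
  tr <- signal_track(out, track$chrom_sizes)
  tr$binsize <- track$binsize
  tr
}

#' Read a bedGraph file into a SignalTrack
#'
#' Four whitespace-separated columns (chrom, start, end, value; 0-based
#' half-open). `track`/`browser`/`#` header lines are skipped. Overlapping
#' intervals and coordinates outside `chrom_sizes` are rejected with the
#' offending line number.
#'
#' @param path file path.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return SignalTrack.
#' @export
read_bedgraph <- function(path, chrom_sizes) {
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines))
    return(signal_track(data.frame(chrom = character(), start = integer(),
                                   end = integer(), value = numeric()),
                        chrom_sizes))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop("malformed bedGraph record at line ", lineno[which(nf != 4L)[1L]],
         " of ", path, " (expected 4 fields)")
  mat <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  d <- data.frame(chrom = mat[, 1L],
                  start = suppressWarnings(as.integer(mat[, 2L])),
                  end = suppressWarnings(as.integer(mat[, 3L])),
                  value = suppressWarnings(as.numeric(mat[, 4L])))
  bad <- which(is.na(d$start) | is.na(d$end) | is.na(d$value))
  if (length(bad))
    stop("malformed bedGraph record at line ", lineno[bad[1L]], " of ", path)
  unknown <- which(!d$chrom %in% names(chrom_sizes))
  if (length(unknown))
    stop("unknown chromosome '", d$chrom[unknown[1L]], "' at line ",
         lineno[unknown[1L]], " of ", path)
  ## overlap detection with line attribution: within each chromosome the
  ## record starting inside an earlier record is reported
  for (ch in unique(d$chrom)) {
    i <- which(d$chrom == ch)
    o <- i[order(d$start[i])]
    if (length(o) > 1L) {
      prev_end <- cummax(d$end[o])[-length(o)]
      clash <- which(d$start[o][-1L] < prev_end)
      if (length(clash))
        stop("overlapping intervals at line ", lineno[o[clash[1L] + 1L]],
             " of ", path)
    }
  }
  signal_track(d, chrom_sizes)
}

#' Write a SignalTrack as bedGraph
#'
#' Adjacent (abutting) intervals with identical values are run-length merged
#' on write; values are printed with full double precision so that
#' `read_bedgraph(write_bedgraph(t))` round-trips exactly.
#'
#' @param track SignalTrack.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(is_signal_track(track))
  d <- track$data
  if (nrow(d)) {
    same <- c(FALSE, d$chrom[-1L] == d$chrom[-nrow(d)] &
                d$start[-1L] == d$end[-nrow(d)] &
                d$value[-1L] == d$value[-nrow(d)])
    grp <- cumsum(!same)
    d <- data.frame(chrom = d$chrom[!same],
                    start = d$start[!same],
                    end = tapply(d$end, grp, max)[as.character(unique(grp))],
                    value = d$value[!same])
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(d))
    writeLines(sprintf("%s\t%d\t%d\t%.17g", d$chrom, d$start, d$end, d$value),
               con)
  invisible(path)
}
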