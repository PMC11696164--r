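## Strand-resolved small-RNA coverage: size selection, multi-mapping
## filters, per-base plus/minus tracks, CP10M normalization, SGR I/O.
##
## Read sets are plain data.frames with one row per reported alignment:
## read_id, chrom, pos (0-based leftmost), strand, length, n_best (the
## number of equally best-scoring alignments of that read, repeated on each
## of its rows).

.check_reads <- function(reads) {
  need <- c("read_id", "chrom", "pos", "strand", "length", "n_best")
  if (!all(need %in% names(reads)))
    stop("read table needs columns ", paste(need, collapse = ", "))
  invisible(reads)
}

#' Retain reads in a length window
#'
#' @param reads alignment data.frame.
#' @param min_len,max_len inclusive bounds in nt (default 21-25, the
#'   size-selected siRNA range).
#' @return filtered data.frame, original order preserved.
#' @export
size_select <- function(reads, min_len = 21L, max_len = 25L) {
  .check_reads(reads)
  if (min_len > max_len) stop("min_len must not exceed max_len")
  reads[reads$length >= min_len & reads$length <= max_len, , drop = FALSE]
}

#' Remove multi-mapping reads
#'
#' Keeps only reads with a single best-scoring alignment (`n_best == 1`).
#'
#' @param reads alignment data.frame.
#' @return filtered data.frame.
#' @export
filter_unique <- function(reads) {
  .check_reads(reads)
  reads[reads$n_best == 1L, , drop = FALSE]
}

#' Reads mapping uniquely within a region
#'
#' [filter_unique()] composed with the requirement that the read's single
#' alignment lies entirely within `region`.
#'
#' @param reads alignment data.frame.
#' @param region list or one-row data.frame with `chrom`, `start`, `end`.
#' @return filtered data.frame.
#' @export
unique_to_region <- function(reads, region) {
  r <- filter_unique(reads)
  r[r$chrom == region$chrom & r$pos >= region$start &
      r$pos + r$length <= region$end, , drop = FALSE]
}

#' Library size for CP10M normalization
#'
#' Number of distinct mapped reads (each read counted once regardless of
#' how many alignments it reports); by convention taken after size
#' selection and before unique filtering.
#'
#' @param reads alignment data.frame.
#' @return integer count.
#' @export
count_library_total <- function(reads) {
  .check_reads(reads)
  length(unique(reads$read_id))
}

#' Strand-resolved per-base coverage over a region
#'
#' Counts full read bodies overlapping each base, split by strand. In
#' `"drop"` mode only uniquely mapping reads contribute; in `"all"` mode
#' every reported alignment is counted, with weight 1 per alignment by
#' default or `1/n_best` when `weight = "fraction"`. A `"5prime"` count
#' mode restricted to the 5' end base is available.
#'
#' @param reads alignment data.frame.
#' @param region list or one-row data.frame with `chrom`, `start`, `end`.
#' @param multimap_mode `"drop"` (unique reads only) or `"all"`.
#' @param weight `"one"` (default) or `"fraction"` (1/n_best per
#'   alignment).
#' @param count_mode `"body"` (default) or `"5prime"`.
#' @return object of class `StrandedCoverage`: `region`, `plus`, `minus`
#'   (numeric per-base arrays), `normalized`, `library_total`.
#' @export
stranded_coverage <- function(reads, region,
                              multimap_mode = c("drop", "all"),
                              weight = c("one", "fraction"),
                              count_mode = c("body", "5prime")) {
  multimap_mode <- match.arg(multimap_mode)
  weight <- match.arg(weight)
  count_mode <- match.arg(count_mode)
  .check_reads(reads)
  if (region$start < 0 || region$end <= region$start)
    stop("invalid region")
  r <- if (multimap_mode == "drop") filter_unique(reads) else reads
  r <- r[r$chrom == region$chrom & r$pos < region$end &
           r$pos + r$length > region$start, , drop = FALSE]
  width <- region$end - region$start
  plus <- numeric(width)
  minus <- numeric(width)
  for (i in seq_len(nrow(r))) {
    w <- if (weight == "fraction") 1 / r$n_best[i] else 1
    if (count_mode == "5prime") {
      p5 <- if (r$strand[i] == "+") r$pos[i] else r$pos[i] + r$length[i] - 1L
      if (p5 < region$start || p5 >= region$end) next
      span <- (p5 - region$start + 1L)
    } else {
      s <- max(r$pos[i], region$start)
      e <- min(r$pos[i] + r$length[i], region$end)
      span <- (s - region$start + 1L):(e - region$start)
    }
    if (r$strand[i] == "+") plus[span] <- plus[span] + w
    else minus[span] <- minus[span] + w
  }
  structure(list(region = list(chrom = region$chrom,
                               start = as.integer(region$start),
                               end = as.integer(region$end)),
                 plus = plus, minus = minus,
                 normalized = FALSE, library_total = NA_integer_),
            class = "StrandedCoverage")
}

#' @export
print.StrandedCoverage <- function(x, ...) {
  cat(sprintf("StrandedCoverage %s:%d-%d (%s): plus sum %.3g, minus sum %.3g\n",
              x$region$chrom, x$region$start, x$region$end,
              if (x$normalized) "CP10M" else "raw",
              sum(x$plus), sum(x$minus)))
  invisible(x)
}

#' Normalize coverage to counts per 10 million mapped reads
#'
#' Scales both strand arrays by `1e7 / library_total`.
#'
#' @param cov `StrandedCoverage`.
#' @param library_total number of mapped reads in the library (> 0); see
#'   [count_library_total()].
#' @return normalized `StrandedCoverage`.
#' @export
normalize_cp10m <- function(cov, library_total) {
  stopifnot(inherits(cov, "StrandedCoverage"))
  if (is.na(library_total) || library_total <= 0)
    stop("library_total must be > 0")
  f <- 1e7 / library_total
  cov$plus <- cov$plus * f
  cov$minus <- cov$minus * f
  cov$normalized <- TRUE
  cov$library_total <- as.integer(library_total)
  cov
}

#' Write stranded coverage as SGR
#'
#' Three tab-separated columns: chrom, 1-based position, value. Minus-strand
#' values are emitted as negative numbers so both strands display
#' simultaneously; a position carrying signal on both strands yields two
#' records. With `zero_suppress = FALSE` (default) every position appears
#' (a single 0 record where both strands are empty), which makes
#' `read_sgr(write_sgr(cov))` exact; with suppression, empty positions are
#' omitted.
#'
#' @param cov `StrandedCoverage`.
#' @param path output file.
#' @param zero_suppress omit zero records.
#' @return `path`, invisibly.
#' @export
write_sgr <- function(cov, path, zero_suppress = FALSE) {
  stopifnot(inherits(cov, "StrandedCoverage"))
  pos1 <- cov$region$start + seq_along(cov$plus)  # 1-based
  lines <- character(0)
  has_p <- cov$plus > 0
  has_m <- cov$minus > 0
  both_zero <- !has_p & !has_m
  recs <- rbind(
    data.frame(pos = pos1[has_p], val = cov$plus[has_p]),
    data.frame(pos = pos1[has_m], val = -cov$minus[has_m]),
    if (!zero_suppress && any(both_zero))
      data.frame(pos = pos1[both_zero], val = 0))
  recs <- recs[order(recs$pos, -recs$val), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(recs))
    writeLines(sprintf("%s\t%d\t%.17g", cov$region$chrom, recs$pos, recs$val),
               con)
  invisible(path)
}

#' Read an SGR file back into stranded coverage
#'
#' Positive values populate the plus strand, negative the minus strand.
#' The region is taken from `region` when given, otherwise inferred from
#' the span of positions in the file (exact for files written without zero
#' suppression).
#'
#' @param path SGR file.
#' @param region optional list with `chrom`, `start`, `end`.
#' @return `StrandedCoverage` (raw; normalization state is not stored in
#'   SGR).
#' @export
read_sgr <- function(path, region = NULL) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    if (is.null(region)) stop("empty SGR file and no region given")
    width <- region$end - region$start
    return(structure(list(region = list(chrom = region$chrom,
                                        start = as.integer(region$start),
                                        end = as.integer(region$end)),
                          plus = numeric(width), minus = numeric(width),
                          normalized = FALSE, library_total = NA_integer_),
                     class = "StrandedCoverage"))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 3L))
    stop("malformed SGR record at line ", lineno[which(nf != 3L)[1L]],
         " of ", path)
  mat <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(mat[, 2L]))
  val <- suppressWarnings(as.numeric(mat[, 3L]))
  bad <- which(is.na(pos) | is.na(val))
  if (length(bad))
    stop("malformed SGR record at line ", lineno[bad[1L]], " of ", path)
  chroms <- unique(mat[, 1L])
  if (length(chroms) > 1L)
    stop("SGR file spans multiple chromosomes; read one region at a time")
  if (is.null(region))
    region <- list(chrom = chroms, start = min(pos) - 1L, end = max(pos))
  width <- region$end - region$start
  plus <- numeric(width)
  minus <- numeric(width)
  idx <- pos - region$start  # 1-based index into arrays
  if (any(idx < 1L | idx > width))
    stop("SGR position outside the stated region")
  pp <- val > 0
  mm <- val < 0
  plus[idx[pp]] <- val[pp]
  minus[idx[mm]] <- -val[mm]
  structure(list(region = list(chrom = region$chrom,
                               start = as.integer(region$start),
                               end = as.integer(region$end)),
                 plus = plus, minus = minus,
                 normalized = FALSE, library_total = NA_integer_),
            class = "StrandedCoverage")
}
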