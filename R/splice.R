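## Cryptic-intron detection, homology projection between diverged repeat
## copies, and splice-site mutagenesis.
##
## Coordinate conventions: all reported positions are 0-based plus-strand
## coordinates of the host sequence. "Top" strand = plus/reference strand,
## "bottom" = minus; a bottom-strand intron is read on the reverse
## complement, so its donor GT sits at the *rightmost* plus coordinates of
## the intron interval.

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_base <- function(x) unname(.COMP[x])

#' Reverse complement of a DNA string
#' @param x character scalar over ACGTN.
#' @return character scalar.
#' @export
rev_comp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  paste(rev(comp_base(strsplit(toupper(x), "")[[1L]])), collapse = "")
}

## IUPAC consensus -> regex character classes (subset needed for branch
## consensi such as CTRAY)
.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
            K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
            H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_regex <- function(consensus) {
  ch <- strsplit(toupper(consensus), "")[[1L]]
  if (any(!ch %in% names(.IUPAC)))
    stop("invalid IUPAC consensus: ", consensus)
  paste(.IUPAC[ch], collapse = "")
}

## 0-based start positions of all (overlapping) matches of a regex
.regex_starts0 <- function(seq, rx) {
  m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

## 0-based positions of the branch-point A: last 'A' of the consensus
.branch_anchor <- function(consensus) {
  ch <- strsplit(toupper(consensus), "")[[1L]]
  a <- max(which(ch == "A"))
  if (!is.finite(a)) stop("branch consensus must contain an A")
  a - 1L
}

#' Configuration for the intron scanner
#'
#' @param donor,acceptor splice-site dinucleotides (transcript orientation).
#' @param branch_consensus IUPAC branch-point consensus; the branch
#'   adenosine is taken as its last A. Default CTRAY, the fungal consensus.
#' @param branch_window allowed distance (nt, transcript orientation) from
#'   the branch A to the acceptor G.
#' @param min_len,max_len intron length bounds, donor G through acceptor G
#'   inclusive.
#' @param mode `"greedy"` resolves overlaps left-to-right preferring the
#'   shortest acceptor; `"all"` reports every candidate.
#' @return list of class `intron_scan_config`.
#' @export
intron_scan_config <- function(donor = "GT", acceptor = "AG",
                               branch_consensus = "CTRAY",
                               branch_window = c(18L, 40L),
                               min_len = 30L, max_len = 120L,
                               mode = c("greedy", "all")) {
  mode <- match.arg(mode)
  stopifnot(nchar(donor) == 2L, nchar(acceptor) == 2L,
            length(branch_window) == 2L, branch_window[1L] <= branch_window[2L],
            min_len < max_len, min_len >= 10L)
  structure(list(donor = toupper(donor), acceptor = toupper(acceptor),
                 branch_consensus = toupper(branch_consensus),
                 branch_window = as.integer(branch_window),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 mode = mode),
            class = "intron_scan_config")
}

.empty_introns <- function() {
  data.frame(strand = character(), donor = integer(), branch = integer(),
             acceptor = integer(), start = integer(), end = integer(),
             length = integer())
}

#' Scan a sequence for candidate cryptic introns
#'
#' Finds (donor, acceptor) pairs on the requested strand whose length lies
#' within the configured bounds, whose boundary dinucleotides match
#' (GT..AG by default) and which carry a branch-point consensus match at the
#' configured distance upstream of the acceptor. All reported coordinates
#' are 0-based plus-strand positions: `donor` is the G of GT, `acceptor`
#' the G of AG, `branch` the branch-point A.
#'
#' @param seq DNA string (plus strand of the host).
#' @param strand `"+"` or `"-"`; for `"-"` the reverse complement is
#'   scanned and coordinates are mapped back.
#' @param config see [intron_scan_config()].
#' @return data.frame with columns strand, donor, branch, acceptor, start,
#'   end, length.
#' @export
find_candidate_introns <- function(seq, strand = c("+", "-"),
                                   config = intron_scan_config()) {
  strand <- match.arg(strand)
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  seq <- toupper(seq)
  L <- nchar(seq)
  t <- if (strand == "-") rev_comp(seq) else seq
  donors <- .regex_starts0(t, config$donor)              # G index
  accG <- .regex_starts0(t, config$acceptor) + 1L        # G index
  anchor <- .branch_anchor(config$branch_consensus)
  nc <- nchar(config$branch_consensus)
  branchA <- .regex_starts0(t, iupac_regex(config$branch_consensus)) + anchor
  bw <- config$branch_window
  res <- list()
  next_allowed <- 0L
  for (d in donors) {
    if (config$mode == "greedy" && d < next_allowed) next
    lo <- d + config$min_len - 1L
    hi <- min(d + config$max_len - 1L, L - 1L)
    cand <- accG[accG >= lo & accG <= hi]
    for (a in sort(cand)) {
      ## branch consensus wholly inside the intron, clear of both splice sites
      b <- branchA[branchA >= a - bw[2L] & branchA <= a - bw[1L]]
      b <- b[b - anchor > d + 1L & b + (nc - 1L - anchor) < a - 1L]
      if (!length(b)) next
      b <- b[length(b)]  # branch closest to the acceptor
      res[[length(res) + 1L]] <- c(d = d, b = b, a = a)
      if (config$mode == "greedy") {
        next_allowed <- a + 1L
        break
      }
    }
  }
  if (!length(res)) return(.empty_introns())
  m <- do.call(rbind, res)
  if (strand == "+") {
    out <- data.frame(strand = "+", donor = m[, "d"], branch = m[, "b"],
                      acceptor = m[, "a"], start = m[, "d"],
                      end = m[, "a"] + 1L)
  } else {
    out <- data.frame(strand = "-", donor = L - 1L - m[, "d"],
                      branch = L - 1L - m[, "b"],
                      acceptor = L - 1L - m[, "a"],
                      start = L - 1L - m[, "a"], end = L - m[, "d"])
  }
  out$length <- out$end - out$start
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## transcript-oriented character at plus-strand position p (0-based)
.tx_char <- function(seq, strand, p) {
  ch <- substr(seq, p + 1L, p + 1L)
  if (strand == "-") comp_base(ch) else ch
}

## transcript-oriented substring of length n whose transcript coordinates
## start at the transcript position of plus-strand position p
.tx_sub <- function(seq, strand, p, n) {
  if (strand == "+") {
    if (p < 0L || p + n > nchar(seq)) return(NA_character_)
    substr(seq, p + 1L, p + n)
  } else {
    if (p - n + 1L < 0L || p >= nchar(seq)) return(NA_character_)
    rev_comp(substr(seq, p - n + 2L, p + 1L))
  }
}

#' Global percent identity and coordinate homology map
#'
#' Needleman-Wunsch global alignment (via Biostrings) under the stated
#' scoring; identity is `100 * matches / alignment columns`, gap columns
#' included in the denominator. Also returns the monotone map of aligned
#' coordinate pairs used to project annotations between homologous
#' sequences.
#'
#' @param seq_a,seq_b non-empty ACGT strings.
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (penalties given as positive numbers).
#' @return list of class `HomologyMap`: `percent_identity`, `columns`,
#'   `matches`, and `pairs` (data.frame `source_pos`, `target_pos`,
#'   `match`; 0-based, aligned columns with a base on both sides only).
#' @export
percent_identity <- function(seq_a, seq_b,
                             scoring = list(match = 1, mismatch = -1,
                                            gap_open = 5, gap_extend = 1)) {
  stopifnot(is.character(seq_a), is.character(seq_b))
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("sequences must be non-empty")
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (grepl("[^ACGT]", seq_a) || grepl("[^ACGT]", seq_b))
    stop("sequences must be ACGT only")
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = sm,
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  cols <- length(pa)
  is_match <- pa == pb & pa != "-"
  ai <- cumsum(pa != "-")
  bi <- cumsum(pb != "-")
  both <- pa != "-" & pb != "-"
  pairs <- data.frame(source_pos = ai[both] - 1L, target_pos = bi[both] - 1L,
                      match = is_match[both])
  structure(list(percent_identity = 100 * sum(is_match) / cols,
                 columns = cols, matches = sum(is_match), pairs = pairs),
            class = "HomologyMap")
}

#' @export
print.HomologyMap <- function(x, ...) {
  cat(sprintf("HomologyMap: %.2f%% identity over %d columns (%d matched)\n",
              x$percent_identity, x$columns, x$matches))
  invisible(x)
}

#' Project annotated introns onto a homologous sequence
#'
#' Aligns source and target, projects each splice-site coordinate through
#' the alignment, and keeps an intron only if the target still carries an
#' intact donor, acceptor, and branch-point consensus at the projected
#' positions. Rejected introns are reported with the reason
#' (`"unaligned"`, `"donor lost"`, `"acceptor lost"`, `"branch lost"`).
#'
#' @param source_seq,target_seq DNA strings.
#' @param source_introns data.frame as produced by
#'   [find_candidate_introns()] or [plant_introns()].
#' @param config [intron_scan_config()] supplying the element definitions.
#' @param scoring alignment scoring, see [percent_identity()].
#' @param min_identity floor (percent) below which projection is refused.
#' @return list with `kept` and `rejected` data.frames and the
#'   `homology` map.
#' @export
map_homologous_introns <- function(source_seq, source_introns, target_seq,
                                   config = intron_scan_config(),
                                   scoring = list(match = 1, mismatch = -1,
                                                  gap_open = 5, gap_extend = 1),
                                   min_identity = 80) {
  hm <- percent_identity(source_seq, target_seq, scoring)
  if (hm$percent_identity < min_identity)
    stop(sprintf(paste0("alignment identity %.1f%% is below the %.1f%% floor; ",
                        "coordinate projection would be unreliable"),
                 hm$percent_identity, min_identity))
  proj <- rep(NA_integer_, nchar(source_seq))
  proj[hm$pairs$source_pos + 1L] <- hm$pairs$target_pos
  nc <- nchar(config$branch_consensus)
  anchor <- .branch_anchor(config$branch_consensus)
  brx <- iupac_regex(config$branch_consensus)
  kept <- list(); rejected <- list()
  for (i in seq_len(nrow(source_introns))) {
    intr <- source_introns[i, ]
    pd <- proj[intr$donor + 1L]
    pb <- proj[intr$branch + 1L]
    pa <- proj[intr$acceptor + 1L]
    reason <- NULL
    if (is.na(pd) || is.na(pb) || is.na(pa)) {
      reason <- "unaligned"
    } else if (!identical(.tx_sub(target_seq, intr$strand, pd, 2L),
                          config$donor)) {
      reason <- "donor lost"
    } else {
      acc <- if (intr$strand == "+")
        .tx_sub(target_seq, "+", pa - 1L, 2L)
      else
        .tx_sub(target_seq, "-", pa + 1L, 2L)
      if (!identical(acc, config$acceptor)) {
        reason <- "acceptor lost"
      } else {
        br <- if (intr$strand == "+")
          .tx_sub(target_seq, "+", pb - anchor, nc)
        else
          .tx_sub(target_seq, "-", pb + anchor, nc)
        if (is.na(br) || !grepl(paste0("^", brx, "$"), br))
          reason <- "branch lost"
      }
    }
    if (is.null(reason)) {
      row <- data.frame(strand = intr$strand, donor = pd, branch = pb,
                        acceptor = pa,
                        start = min(pd, pa), end = max(pd, pa) + 1L)
      row$length <- row$end - row$start
      kept[[length(kept) + 1L]] <- row
    } else {
      rej <- intr[c("strand", "donor", "branch", "acceptor", "start",
                    "end", "length")]
      rej$reason <- reason
      rejected[[length(rejected) + 1L]] <- rej
    }
  }
  kept <- if (length(kept)) do.call(rbind, kept) else .empty_introns()
  rejected <- if (length(rejected)) do.call(rbind, rejected) else
    cbind(.empty_introns(), data.frame(reason = character()))
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected, homology = hm)
}

## fixed non-functional substitutions (transcript orientation):
##   donor     GT -> CA
##   acceptor  AG -> GC
##   branch A  A  -> C
.MUT_DONOR <- c("C", "A")
.MUT_ACCEPTOR <- c("G", "C")
.MUT_BRANCH <- "C"

#' Disable splice sites of annotated introns
#'
#' Replaces the donor GT with CA, the acceptor AG with GC, and the
#' branch-point A with C (all in transcript orientation), leaving sequence
#' length and every other position untouched. The elements must be present
#' at the stated coordinates; overlapping elements across introns are an
#' error.
#'
#' @param seq DNA string (plus strand).
#' @param introns data.frame of intron models (see
#'   [find_candidate_introns()]).
#' @return mutated sequence (character scalar).
#' @export
mutate_splice_sites <- function(seq, introns) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nrow(introns)) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  touched <- integer(0)
  for (i in seq_len(nrow(introns))) {
    intr <- introns[i, ]
    s <- intr$strand
    if (s == "+") {
      don <- c(intr$donor, intr$donor + 1L)
      acc <- c(intr$acceptor - 1L, intr$acceptor)
    } else {
      don <- c(intr$donor, intr$donor - 1L)
      acc <- c(intr$acceptor + 1L, intr$acceptor)
    }
    if (!identical(.tx_sub(seq, s, intr$donor, 2L), "GT"))
      stop("no donor GT at stated coordinates of intron ", i)
    accseq <- if (s == "+") .tx_sub(seq, "+", intr$acceptor - 1L, 2L)
              else .tx_sub(seq, "-", intr$acceptor + 1L, 2L)
    if (!identical(accseq, "AG"))
      stop("no acceptor AG at stated coordinates of intron ", i)
    if (!identical(.tx_char(seq, s, intr$branch), "A"))
      stop("no branch-point A at stated coordinates of intron ", i)
    pos <- c(don, acc, intr$branch)
    if (any(pos %in% touched))
      stop("overlapping splice elements between introns")
    touched <- c(touched, pos)
    repl <- c(.MUT_DONOR, .MUT_ACCEPTOR, .MUT_BRANCH)
    if (s == "-") repl <- comp_base(repl)
    ch[pos + 1L] <- repl
  }
  paste(ch, collapse = "")
}

#' Count introns per strand
#'
#' @param introns data.frame with a `strand` column.
#' @return named integer vector `c(plus = , minus = )`; "bottom" strand =
#'   minus.
#' @export
intron_strand_summary <- function(introns) {
  c(plus = sum(introns$strand == "+"),
    minus = sum(introns$strand == "-"))
}
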