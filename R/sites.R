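## TF binding-site library: summit expansion, transitive merging, per-site
## signal extraction into the sites x TFs occupancy matrix.

#' Build a merged TF binding-site library from per-TF summits
#'
#' Each 1-bp summit is expanded symmetrically by `half_width` bp to a
#' uniform-width site; sites sharing at least one bp are then merged
#' transitively (abutting half-open intervals are *not* merged). Each merged
#' site records the union of contributing TFs and is identified by its
#' coordinate string `chrom:start-end`. Expansion is clamped at chromosome
#' ends.
#'
#' @param summits_by_tf named list (TF -> data.frame with `chrom`, `start`;
#'   `start` is the 0-based summit position).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param half_width bp added on each side of a summit (default 25, giving
#'   50 bp sites).
#' @return data.frame of sites sorted by (chrom, start): `site_id`,
#'   `chrom`, `start`, `end`, `center` (floor midpoint), `width`,
#'   `member_tfs` (list column), `n_tfs`.
#' @export
build_site_library <- function(summits_by_tf, chrom_sizes, half_width = 25L) {
  stopifnot(is.list(summits_by_tf), !is.null(names(summits_by_tf)))
  half_width <- as.integer(half_width)
  ivs <- list()
  for (tf in names(summits_by_tf)) {
    s <- summits_by_tf[[tf]]
    if (is.null(s) || !nrow(s)) next
    stopifnot(all(c("chrom", "start") %in% names(s)))
    if (any(!s$chrom %in% names(chrom_sizes)))
      stop("summit on unknown chromosome for TF ", tf)
    L <- chrom_sizes[s$chrom]
    if (any(s$start < 0L) || any(s$start >= L))
      stop("summit outside chromosome bounds for TF ", tf)
    ivs[[tf]] <- data.frame(chrom = as.character(s$chrom),
                            start = pmax(0L, as.integer(s$start) - half_width),
                            end = pmin(as.integer(L), as.integer(s$start) + half_width),
                            tf = tf)
  }
  d <- do.call(rbind, ivs)
  if (is.null(d) || !nrow(d))
    return(data.frame(site_id = character(), chrom = character(),
                      start = integer(), end = integer(), center = integer(),
                      width = integer(), member_tfs = I(list()),
                      n_tfs = integer()))
  d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
  out <- list()
  for (ch in unique(d$chrom)) {
    x <- d[d$chrom == ch, , drop = FALSE]
    cur_s <- x$start[1L]; cur_e <- x$end[1L]; cur_tfs <- x$tf[1L]
    flush <- function() {
      tfs <- sort(unique(cur_tfs))
      out[[length(out) + 1L]] <<- data.frame(
        site_id = sprintf("%s:%d-%d", ch, cur_s, cur_e),
        chrom = ch, start = cur_s, end = cur_e,
        center = (cur_s + cur_e) %/% 2L, width = cur_e - cur_s,
        member_tfs = I(list(tfs)), n_tfs = length(tfs))
    }
    for (i in seq_len(nrow(x))[-1L]) {
      if (x$start[i] < cur_e) {        # >=1 bp shared; abutting stays split
        cur_e <- max(cur_e, x$end[i])
        cur_tfs <- c(cur_tfs, x$tf[i])
      } else {
        flush()
        cur_s <- x$start[i]; cur_e <- x$end[i]; cur_tfs <- x$tf[i]
      }
    }
    flush()
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Signal strength of a track at one site
#'
#' Maximum track value over a window of `window` bp straddling the site
#' center (`[center - window/2, center + window/2)`, clamped at chromosome
#' ends); positions without coverage count as 0.
#'
#' @param track SignalTrack covering the site's chromosome.
#' @param site one-row data.frame or list with `chrom` and `center`.
#' @param window window width in bp (default 1000).
#' @return numeric scalar.
#' @export
site_signal <- function(track, site, window = 1000L) {
  stopifnot(is_signal_track(track), window >= 1L)
  v <- track_values(track, site$chrom,
                    site$center - window %/% 2L,
                    site$center + window %/% 2L)
  if (!length(v)) 0 else max(v)
}

#' Occupancy-strength matrix over sites and TFs
#'
#' One row per site (coordinate order), one column per TF (lexicographic);
#' entries are [site_signal()] maxima of each TF's enrichment track over the
#' site-centered window.
#'
#' @param tracks_by_tf named list TF -> SignalTrack.
#' @param sites site library from [build_site_library()].
#' @param window see [site_signal()].
#' @param tfs TFs to extract (default: every TF in `tracks_by_tf`); a TF
#'   without a track is an error naming it.
#' @return numeric matrix with `site_id` rownames and TF colnames.
#' @export
build_signal_matrix <- function(tracks_by_tf, sites, window = 1000L,
                                tfs = sort(names(tracks_by_tf))) {
  stopifnot(is.list(tracks_by_tf), !is.null(names(tracks_by_tf)))
  tfs <- sort(tfs)
  mat <- matrix(0, nrow = nrow(sites), ncol = length(tfs),
                dimnames = list(sites$site_id, tfs))
  for (tf in tfs) {
    tr <- tracks_by_tf[[tf]]
    if (is.null(tr)) stop("missing track for TF ", tf)
    for (i in seq_len(nrow(sites)))
      mat[i, tf] <- site_signal(tr, sites[i, ], window)
  }
  mat
}

#' Assign library sites back to the TFs whose summits built them
#'
#' A site is assigned to every TF that contributed at least one summit to
#' it; these per-TF site sets are the inputs of the co-occupancy analysis.
#'
#' @param sites site library from [build_site_library()] (built from these
#'   summits).
#' @param summits_by_tf the same summit records used to build the library.
#' @return named list TF -> character vector of `site_id`s (sorted,
#'   unique). TFs with no summits map to an empty vector.
#' @export
assign_sites_to_tf <- function(sites, summits_by_tf) {
  out <- lapply(names(summits_by_tf), function(tf) {
    s <- summits_by_tf[[tf]]
    if (is.null(s) || !nrow(s)) return(character(0))
    ids <- character(0)
    for (ch in unique(s$chrom)) {
      lib <- sites[sites$chrom == ch, , drop = FALSE]
      if (!nrow(lib)) next
      pos <- s$start[s$chrom == ch]
      idx <- findInterval(pos, lib$start)
      hit <- idx > 0L & pos < lib$end[pmax(idx, 1L)]
      ids <- c(ids, lib$site_id[idx[hit]])
    }
    sort(unique(ids))
  })
  names(out) <- names(summits_by_tf)
  out
}
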