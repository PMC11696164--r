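## End-to-end orchestration: a validated config, staged subcommands over
## the module functions, deterministic outputs under a single seed, and a
## JSON run manifest with parameter values and output checksums.

#' Default pipeline configuration
#'
#' Every tunable parameter of the pipeline with its default. The two
#' alignment masks carried by default are the silent mating-type region on
#' chromosome 2 (chrII:2,109,748-2,138,781) and the mat1M locus on the
#' 40 kb MAT contig (MAT:4,489-5,615), stored 0-based half-open; masks on
#' chromosomes absent from a track are ignored, so they are inert on the
#' synthetic genome.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @return nested named list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genome = list(n_chroms = 2L, lengths = c(50000L, 50000L), gc = 0.36,
                  repeat_spec = list(unit_length = 2000L, n_copies = 2L,
                                     divergence = 0.04),
                  motif_spec = list(n_clusters = 10L, motifs_per_cluster = 3L,
                                    gap_range = c(5L, 60L))),
    tfs = list(names = c("atf1", "moc3", "pcr1", "php2", "php3", "php5"),
               sites_per_tf = 10L, enrichment_height = 60,
               shared_fraction = 0.3),
    chip = list(background_mean = 20, peak_sd_bp = 50, binsize = 10L,
                pseudocount = 0.1),
    summits = list(jitter_sd_bp = 2),
    masks = list(list(chrom = "chrII", start = 2109747L, end = 2138781L),
                 list(chrom = "MAT", start = 4488L, end = 5615L)),
    sites = list(half_width = 25L, site_window = 1000L),
    motifs = list(motif = "CCAAT", flank = 500L, max_gap = 25L),
    cluster = list(k = 3L, transform = "none", method = "ward.D2"),
    smallrna = list(n_reads = 3000L, strand_bias = 0.8, min_len = 21L,
                    max_len = 25L, multimap_mode = "drop"),
    introns = list(n = 6L, length = 60L, strand = "-", min_len = 30L,
                   max_len = 120L, branch_consensus = "CTRAY",
                   branch_window = c(18L, 40L))
  )
}

#' Validate a pipeline configuration
#'
#' Checks the config against the default skeleton: unknown keys are
#' rejected, and the parameters that drive compute are type- and
#' range-checked before any stage runs.
#'
#' @param config nested named list (as from [default_config()], possibly
#'   loaded from YAML).
#' @return the config, invisibly, or an error.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  check_keys <- function(cfg, refpart, path) {
    if (!is.list(cfg)) return(invisible())
    unknown <- setdiff(names(cfg), names(refpart))
    if (length(unknown))
      stop("unknown config key", if (length(unknown) > 1L) "s", ": ",
           paste(paste0(path, unknown), collapse = ", "))
    for (k in names(cfg))
      if (is.list(refpart[[k]]) && !is.null(names(refpart[[k]])))
        check_keys(cfg[[k]], refpart[[k]], paste0(path, k, "$"))
  }
  check_keys(config, ref, "")
  with(config, {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    if (genome$gc < 0 || genome$gc > 1) stop("genome$gc must be in [0, 1]")
    if (chip$background_mean <= 0) stop("chip$background_mean must be > 0")
    if (chip$pseudocount < 0) stop("chip$pseudocount must be >= 0")
    if (sites$half_width < 1L) stop("sites$half_width must be >= 1")
    if (motifs$flank < 1L) stop("motifs$flank must be >= 1")
    if (smallrna$min_len > smallrna$max_len)
      stop("smallrna$min_len must not exceed smallrna$max_len")
    if (cluster$k < 1L || cluster$k > length(tfs$names))
      stop("cluster$k must lie in [1, number of TFs]")
    if (introns$min_len >= introns$max_len)
      stop("introns$min_len must be below introns$max_len")
  })
  invisible(config)
}

#' Read a YAML pipeline configuration
#'
#' Values present in the file override the defaults; the merged config is
#' validated.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_into <- function(base, over) {
    for (k in names(over)) {
      if (is.list(over[[k]]) && is.list(base[[k]]) && !is.null(names(base[[k]])))
        base[[k]] <- merge_into(base[[k]], over[[k]])
      else base[[k]] <- over[[k]]
    }
    base
  }
  cfg <- merge_into(default_config(), user)
  validate_config(cfg)
  cfg
}

.masks_df <- function(masks) {
  if (is.null(masks) || !length(masks))
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  do.call(rbind, lapply(masks, function(m)
    data.frame(chrom = m$chrom, start = m$start, end = m$end)))
}

.stage_seed <- function(config, stage) {
  offs <- c(simulate = 101L, tracks = 211L, smallrna = 307L, introns = 401L)
  (as.integer(config$seed) * 1009L + offs[[stage]]) %% 2147483647L
}

.need_file <- function(path, stage, hint) {
  if (!file.exists(path))
    stop("stage '", stage, "' needs ", path, "; run '", hint, "' first")
  path
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

## ---- stages ---------------------------------------------------------------

.stage_simulate <- function(config, outdir) {
  g <- config$genome
  truth <- generate_genome(g$n_chroms, g$lengths, g$gc, g$repeat_spec,
                           g$motif_spec, seed = .stage_seed(config, "simulate"))
  truth <- plant_tf_sites(truth, config$tfs$names, config$tfs$sites_per_tf,
                          enrichment_height = config$tfs$enrichment_height,
                          shared_fraction = config$tfs$shared_fraction,
                          seed = .stage_seed(config, "simulate") + 1L)
  ## plant cryptic introns on the bottom strand of the dh-like copy
  rc <- truth$repeat_copies
  dh <- rc[rc$name == "dh1", , drop = FALSE]
  if (nrow(dh) == 1L && config$introns$n > 0L) {
    ul <- dh$end - dh$start
    n <- config$introns$n
    len <- config$introns$length
    gap <- max(5L, (ul - n * len) %/% (n + 1L))
    offs <- gap + (seq_len(n) - 1L) * (len + gap)
    spec <- data.frame(start_offset = offs, length = len,
                       strand = config$introns$strand)
    copy_seq <- substr(truth$genome[[dh$chrom]], dh$start + 1L, dh$end)
    planted <- plant_introns(copy_seq, spec)
    gch <- strsplit(truth$genome[[dh$chrom]], "")[[1L]]
    gch <- .substr_set(gch, dh$start, strsplit(planted$sequence, "")[[1L]])
    truth$genome[[dh$chrom]] <- paste(gch, collapse = "")
    intr <- planted$introns
    for (col in c("donor", "branch", "acceptor", "start", "end"))
      intr[[col]] <- intr[[col]] + dh$start
    truth$planted_introns <- intr
  }
  write_genome_fasta(truth, file.path(outdir, "genome.fa"))
  .write_tsv(truth$repeat_copies, file.path(outdir, "repeat_copies.tsv"))
  .write_tsv(truth$planted_sites, file.path(outdir, "planted_sites.tsv"))
  .write_tsv(truth$planted_motifs, file.path(outdir, "planted_motifs.tsv"))
  .write_tsv(truth$planted_introns, file.path(outdir, "planted_introns.tsv"))
  .write_tsv(data.frame(chrom = names(truth$chrom_sizes),
                        size = as.integer(truth$chrom_sizes)),
             file.path(outdir, "chrom_sizes.tsv"))
  summits <- simulate_summits(truth, config$summits$jitter_sd_bp,
                              seed = .stage_seed(config, "simulate") + 2L,
                              tfs = config$tfs$names)
  dir.create(file.path(outdir, "summits"), showWarnings = FALSE)
  for (tf in names(summits))
    write_summits_bed(summits[[tf]], file.path(outdir, "summits",
                                               paste0(tf, "_summits.bed")))
  dir.create(file.path(outdir, "tracks"), showWarnings = FALSE)
  for (i in seq_along(config$tfs$names)) {
    tf <- config$tfs$names[i]
    tr <- simulate_chip_tracks(truth, tf, config$chip$background_mean,
                               config$chip$peak_sd_bp, config$chip$binsize,
                               seed = .stage_seed(config, "tracks") + i)
    for (kind in names(tr))
      write_bedgraph(tr[[kind]], file.path(outdir, "tracks",
                                           sprintf("%s_%s.bedGraph", tf, kind)))
  }
  cen <- rc[rc$name == "cenH", , drop = FALSE]
  if (nrow(cen) == 1L) {
    reads <- simulate_small_rna(
      truth, list(chrom = cen$chrom, start = cen$start, end = cen$end),
      config$smallrna$n_reads, config$smallrna$strand_bias,
      seed = .stage_seed(config, "smallrna"))
    dir.create(file.path(outdir, "smallrna"), showWarnings = FALSE)
    .write_tsv(reads[c("read_id", "chrom", "pos", "strand", "length", "n_best")],
               file.path(outdir, "smallrna", "alignments.tsv"))
    uniq <- !duplicated(reads$read_id)
    writeLines(sprintf(">%s\n%s", reads$read_id[uniq], reads$seq[uniq]),
               file.path(outdir, "smallrna", "reads.fa"))
    .log_stage("simulate", "%d small-RNA reads (%d alignment records)",
               sum(uniq), nrow(reads))
  }
  .log_stage("simulate", "%d chromosomes, %d planted sites, %d introns",
             length(truth$genome), nrow(truth$planted_sites),
             nrow(truth$planted_introns))
  invisible(truth)
}

.read_chrom_sizes <- function(outdir) {
  d <- utils::read.delim(.need_file(file.path(outdir, "chrom_sizes.tsv"),
                                    "tracks", "simulate"))
  stats::setNames(as.integer(d$size), d$chrom)
}

.stage_tracks <- function(config, outdir) {
  cs <- .read_chrom_sizes(outdir)
  masks <- .masks_df(config$masks)
  p <- config$chip$pseudocount
  for (tf in config$tfs$names) {
    pre <- file.path(outdir, "tracks", paste0(tf, "_"))
    four <- lapply(c("ip_tagged", "input_tagged", "ip_untagged",
                     "input_untagged"), function(kind)
      read_bedgraph(.need_file(paste0(pre, kind, ".bedGraph"),
                               "tracks", "simulate"), cs))
    names(four) <- c("ip_tagged", "input_tagged", "ip_untagged",
                     "input_untagged")
    fe_t <- fold_enrichment(four$ip_tagged, four$input_tagged, p)
    fe_u <- fold_enrichment(four$ip_untagged, four$input_untagged, p)
    fe <- fe_ratio(fe_t, fe_u, p)
    fe <- mask_intervals(fe, masks)
    fe <- bin_track(fe, config$chip$binsize)
    write_bedgraph(fe, paste0(pre, "fe.bedGraph"))
    .log_stage("tracks", "%s: FE ratio track with %d bins", tf, nrow(fe$data))
  }
  invisible(NULL)
}

.read_summits <- function(config, outdir) {
  out <- lapply(config$tfs$names, function(tf)
    read_summits_bed(.need_file(
      file.path(outdir, "summits", paste0(tf, "_summits.bed")),
      "sites", "simulate")))
  names(out) <- config$tfs$names
  out
}

.read_sites <- function(outdir) {
  d <- utils::read.delim(.need_file(file.path(outdir, "sites.tsv"),
                                    "downstream analysis", "sites"))
  d$member_tfs <- strsplit(as.character(d$member_tfs), ",", fixed = TRUE)
  d
}

.stage_sites <- function(config, outdir) {
  cs <- .read_chrom_sizes(outdir)
  summits <- .read_summits(config, outdir)
  sites <- build_site_library(summits, cs, config$sites$half_width)
  flat <- sites
  flat$member_tfs <- vapply(sites$member_tfs, paste, character(1L),
                            collapse = ",")
  .write_tsv(flat, file.path(outdir, "sites.tsv"))
  tracks <- lapply(config$tfs$names, function(tf)
    read_bedgraph(.need_file(file.path(outdir, "tracks",
                                       paste0(tf, "_fe.bedGraph")),
                             "sites", "tracks"), cs))
  names(tracks) <- config$tfs$names
  mat <- build_signal_matrix(tracks, sites, config$sites$site_window)
  .write_tsv(cbind(data.frame(site_id = rownames(mat)), as.data.frame(mat)),
             file.path(outdir, "signal_matrix.tsv"))
  .log_stage("sites", "%d summits merged into %d sites",
             sum(vapply(summits, nrow, integer(1L))), nrow(sites))
  invisible(sites)
}

.stage_motifs <- function(config, outdir) {
  genome <- read_genome_fasta(.need_file(file.path(outdir, "genome.fa"),
                                         "motifs", "simulate"))
  sites <- .read_sites(outdir)
  counts <- classify_library(genome, sites, config$motifs$flank,
                             config$motifs$max_gap, config$motifs$motif)
  .write_tsv(counts, file.path(outdir, "motif_counts.tsv"))
  .log_stage("motifs", "%d/%d sites (%.1f%%) in the high-abundance class",
             sum(counts$abundance_class == "high"), nrow(counts),
             100 * attr(counts, "fraction_high"))
  invisible(counts)
}

.stage_overlap <- function(config, outdir) {
  sites <- .read_sites(outdir)
  summits <- .read_summits(config, outdir)
  assignments <- assign_sites_to_tf(sites, summits)
  res <- overlap_analysis(assignments, universe = nrow(sites))
  .write_tsv(res$pairwise, file.path(outdir, "overlap_pairwise.tsv"))
  .write_tsv(data.frame(signature = names(res$region_counts),
                        n_sites = res$region_counts),
             file.path(outdir, "overlap_regions.tsv"))
  .log_stage("overlap", "%d TF pairs over a universe of %d sites",
             nrow(res$pairwise), res$universe)
  invisible(res)
}

.stage_cluster <- function(config, outdir) {
  d <- utils::read.delim(.need_file(file.path(outdir, "signal_matrix.tsv"),
                                    "cluster", "sites"))
  mat <- as.matrix(d[, -1L, drop = FALSE])
  rownames(mat) <- d$site_id
  mat <- transform_for_clustering(mat, config$cluster$transform)
  res <- cluster_tfs(mat, config$cluster$k, config$cluster$method)
  .write_tsv(data.frame(tf = names(res$labels), cluster = res$labels),
             file.path(outdir, "cluster_labels.tsv"))
  .write_tsv(data.frame(merge_a = res$hclust$merge[, 1L],
                        merge_b = res$hclust$merge[, 2L],
                        height = res$hclust$height),
             file.path(outdir, "cluster_tree.tsv"))
  .log_stage("cluster", "%d TFs cut into %d clusters", length(res$labels),
             res$k)
  invisible(res)
}

.stage_smallrna <- function(config, outdir) {
  reads <- utils::read.delim(.need_file(
    file.path(outdir, "smallrna", "alignments.tsv"), "smallrna", "simulate"))
  rc <- utils::read.delim(.need_file(file.path(outdir, "repeat_copies.tsv"),
                                     "smallrna", "simulate"))
  cen <- rc[rc$name == "cenH", , drop = FALSE]
  region <- list(chrom = cen$chrom, start = cen$start, end = cen$end)
  sel <- size_select(reads, config$smallrna$min_len, config$smallrna$max_len)
  total <- count_library_total(sel)
  uniq <- unique_to_region(sel, region)
  cov <- stranded_coverage(uniq, region, multimap_mode = "drop")
  write_sgr(cov, file.path(outdir, "smallrna", "cenH_raw.sgr"))
  norm <- normalize_cp10m(cov, total)
  write_sgr(norm, file.path(outdir, "smallrna", "cenH_cp10m.sgr"))
  .log_stage("smallrna",
             "%d alignments -> %d size-selected reads -> %d unique to cenH",
             length(unique(reads$read_id)), total,
             length(unique(uniq$read_id)))
  invisible(norm)
}

.stage_introns <- function(config, outdir) {
  genome <- read_genome_fasta(.need_file(file.path(outdir, "genome.fa"),
                                         "introns", "simulate"))
  rc <- utils::read.delim(.need_file(file.path(outdir, "repeat_copies.tsv"),
                                     "introns", "simulate"))
  dh <- rc[rc$name == "dh1", , drop = FALSE]
  cen <- rc[rc$name == "cenH", , drop = FALSE]
  cfg <- intron_scan_config(branch_consensus = config$introns$branch_consensus,
                            branch_window = config$introns$branch_window,
                            min_len = config$introns$min_len,
                            max_len = config$introns$max_len, mode = "all")
  dh_seq <- substr(genome[[dh$chrom]], dh$start + 1L, dh$end)
  cen_seq <- substr(genome[[cen$chrom]], cen$start + 1L, cen$end)
  found <- find_candidate_introns(dh_seq, config$introns$strand, cfg)
  .write_tsv(found, file.path(outdir, "dh_introns.tsv"))
  mapped <- map_homologous_introns(dh_seq, found, cen_seq, cfg)
  .write_tsv(mapped$kept, file.path(outdir, "cenH_introns.tsv"))
  .write_tsv(mapped$rejected, file.path(outdir, "cenH_introns_rejected.tsv"))
  strands <- intron_strand_summary(found)
  .log_stage("introns",
             "%d candidates on dh (%d+, %d-); %d project intact onto cenH",
             nrow(found), strands[["plus"]], strands[["minus"]],
             nrow(mapped$kept))
  invisible(mapped)
}

## ---- entry point ----------------------------------------------------------

#' Run the analysis pipeline
#'
#' Executes one stage (or `"all"`) over an output directory. Stages consume
#' the files earlier stages wrote, so they can be re-run individually;
#' missing inputs fail fast with the name of the file and the stage that
#' produces it. Outputs are deterministic given the config seed; a run
#' manifest (parameters, package version, md5 checksum of every output
#' file) is written at the end.
#'
#' @param subcommand one of `"simulate"`, `"tracks"`, `"sites"`,
#'   `"motifs"`, `"overlap"`, `"cluster"`, `"smallrna"`, `"introns"`,
#'   `"all"`.
#' @param config validated config list (see [default_config()],
#'   [read_config()]).
#' @param outdir output directory (created if absent).
#' @return invisibly, the path to the manifest.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "tracks", "sites",
                                        "motifs", "overlap", "cluster",
                                        "smallrna", "introns"),
                         config = default_config(), outdir) {
  subcommand <- match.arg(subcommand)
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (subcommand == "all")
    c("simulate", "tracks", "sites", "motifs", "overlap", "cluster",
      "smallrna", "introns")
  else subcommand
  runners <- list(simulate = .stage_simulate, tracks = .stage_tracks,
                  sites = .stage_sites, motifs = .stage_motifs,
                  overlap = .stage_overlap, cluster = .stage_cluster,
                  smallrna = .stage_smallrna, introns = .stage_introns)
  for (st in stages) runners[[st]](config, outdir)
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package = "tfhet",
    version = as.character(utils::packageVersion("tfhet")),
    subcommand = subcommand,
    config = config,
    outputs = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(file.path(outdir, f)))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(outdir, "manifest.json"))
}
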