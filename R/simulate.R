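# Seeded synthetic-data generator. Plants non-overlapping loci on a genome,
# derives isoforms by exon skipping, and emits transcript FASTA, annotation
# GFF3, and alignment GFF3 records directly (no aligner involved), plus a
# ground-truth table and a manifest of every planted feature. Additional
# genomes are coordinate-jittered copies emulating the reference genome of a
# related species: the transcripts are identical but their alignment blocks
# drift by up to `coordinate_jitter` bp, as cross-species spliced alignment
# would.

#' Simulation configuration
#'
#' @param seed integer RNG seed; a single RNG stream keyed by this seed
#'   drives the whole bundle.
#' @param n_loci number of gene loci to plant.
#' @param exons_per_locus integer range `c(min, max)` of exons per locus.
#' @param isoforms_per_locus integer range of isoforms per locus; isoform 1 is
#'   always the full exon chain, further isoforms each skip one distinct
#'   internal exon (so siblings always share >= 2 exons). Requires
#'   `max(isoforms) - 1 <= min(exons) - 2`.
#' @param n_genomes number of genomes; genome 1 is the home genome with exact
#'   alignments, genomes 2..n are jittered related-species copies.
#' @param coordinate_jitter max absolute per-block coordinate shift (bp) on
#'   related genomes.
#' @param fragment_rate,chimera_rate,contaminant_rate planting rates in
#'   \[0, 1): `round(rate * n_loci)` single-exon fragments / two-locus
#'   chimeras / unalignable contaminant transcripts.
#' @param exon_len,intron_len,intergenic_len integer ranges (bp).
#' @return list of class `"SimConfig"`.
#' @export
sim_config <- function(seed = 1L, n_loci = 20L,
                       exons_per_locus = c(4L, 7L),
                       isoforms_per_locus = c(1L, 3L),
                       n_genomes = 1L, coordinate_jitter = 0L,
                       fragment_rate = 0, chimera_rate = 0,
                       contaminant_rate = 0,
                       exon_len = c(80L, 300L), intron_len = c(100L, 400L),
                       intergenic_len = c(500L, 1000L)) {
  cfg <- list(seed = as.integer(seed), n_loci = as.integer(n_loci),
              exons_per_locus = as.integer(exons_per_locus),
              isoforms_per_locus = as.integer(isoforms_per_locus),
              n_genomes = as.integer(n_genomes),
              coordinate_jitter = as.integer(coordinate_jitter),
              fragment_rate = fragment_rate, chimera_rate = chimera_rate,
              contaminant_rate = contaminant_rate,
              exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
              intergenic_len = as.integer(intergenic_len))
  rates <- c(cfg$fragment_rate, cfg$chimera_rate, cfg$contaminant_rate)
  if (any(rates < 0 | rates >= 1))
    stop("rates must lie in [0, 1)")
  for (r in c("exons_per_locus", "isoforms_per_locus", "exon_len",
              "intron_len", "intergenic_len")) {
    v <- cfg[[r]]
    if (length(v) != 2 || any(v < 1) || v[1] > v[2])
      stop("invalid range for ", r)
  }
  if (cfg$n_loci < 1 || cfg$n_genomes < 1)
    stop("n_loci and n_genomes must be >= 1")
  if (cfg$isoforms_per_locus[2] - 1L > cfg$exons_per_locus[1] - 2L)
    stop("not enough internal exons to give every extra isoform a distinct ",
         "skipped exon: need max(isoforms) - 1 <= min(exons) - 2")
  structure(cfg, class = "SimConfig")
}

sample_range <- function(range) {
  if (range[1] == range[2]) return(range[1])
  sample(seq(range[1], range[2]), 1L)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

gff3_export <- function(df, path) {
  # df: seq_id, start, end, strand, type, ID, Name, Parent (NA for top level),
  # optional identity/coverage
  gr <- GenomicRanges::GRanges(df$seq_id,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Name <- df$Name
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), NA_character_, df$Parent)
  if (!is.null(df$identity)) {
    S4Vectors::mcols(gr)$identity <- df$identity
    S4Vectors::mcols(gr)$coverage <- df$coverage
  }
  rtracklayer::export(gr, path, format = "gff3")
  # drop run-dependent comment lines so equal configs give byte-equal files
  lines <- readLines(path)
  keep <- !startsWith(lines, "##date") & !startsWith(lines, "##source-version")
  writeLines(lines[keep], path)
  invisible(path)
}

#' Generate a synthetic data bundle
#'
#' Writes, under `out_dir`: `genome_<g>.fasta`, `annotation_<g>.gff3` and
#' `alignments_<g>.gff3` per genome, `transcripts.fasta`, `species_map.tsv`,
#' `truth.tsv` (locus_id, transcript_id for genuine isoforms) and
#' `manifest.json` listing every planted feature. Deterministic: the same
#' config yields a byte-identical bundle.
#'
#' Planted noise: fragments are single-exon truncations of a locus; chimeras
#' fuse the full exon sets of two distinct loci and appear exactly once (the
#' singleton condition articulation-point detection requires); contaminants
#' are random sequences with no alignment records.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `paths` (named file paths), `truth`
#'   (a [TrueClustering()]), and `manifest` (the manifest list).
#' @export
simulate_bundle <- function(config, out_dir) {
  stopifnot(is(config, "SimConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  # ---- locus layout on one chromosome -------------------------------------
  loci <- vector("list", config$n_loci)
  cursor <- 0L
  for (l in seq_len(config$n_loci)) {
    cursor <- cursor + sample_range(config$intergenic_len)
    k <- sample_range(config$exons_per_locus)
    starts <- ends <- integer(k)
    for (e in seq_len(k)) {
      if (e > 1) cursor <- cursor + sample_range(config$intron_len)
      w <- sample_range(config$exon_len)
      starts[e] <- cursor + 1L
      ends[e] <- cursor + w
      cursor <- cursor + w
    }
    loci[[l]] <- list(locus_id = sprintf("L%03d", l), exon_start = starts,
                      exon_end = ends)
  }
  genome_len <- cursor + sample_range(config$intergenic_len)
  genome_seq <- random_dna(genome_len)

  # ---- isoforms by exon skipping ------------------------------------------
  transcripts <- list()   # id -> list(locus (or NA), exon_idx, blocks start/end)
  truth_groups <- list()
  for (l in seq_len(config$n_loci)) {
    loc <- loci[[l]]
    k <- length(loc$exon_start)
    n_iso <- sample_range(config$isoforms_per_locus)
    skip_pool <- if (k > 2) sample(2:(k - 1)) else integer()
    ids <- character(n_iso)
    for (m in seq_len(n_iso)) {
      idx <- if (m == 1) seq_len(k) else setdiff(seq_len(k), skip_pool[m - 1])
      id <- sprintf("%s.iso%d", loc$locus_id, m)
      transcripts[[id]] <- list(locus = loc$locus_id,
                                start = loc$exon_start[idx],
                                end = loc$exon_end[idx])
      ids[m] <- id
    }
    truth_groups[[loc$locus_id]] <- ids
  }

  # ---- planted noise -------------------------------------------------------
  n_frag <- round(config$fragment_rate * config$n_loci)
  frag_ids <- character()
  if (n_frag > 0) {
    frag_loci <- sample(config$n_loci, n_frag)
    for (f in seq_len(n_frag)) {
      loc <- loci[[frag_loci[f]]]
      e <- sample(length(loc$exon_start), 1L)
      id <- sprintf("frag%03d", f)
      transcripts[[id]] <- list(locus = NA_character_,
                                start = loc$exon_start[e], end = loc$exon_end[e])
      frag_ids <- c(frag_ids, id)
    }
  }
  n_chi <- round(config$chimera_rate * config$n_loci)
  chi_ids <- character()
  if (n_chi > 0) {
    if (2L * n_chi > config$n_loci)
      stop("chimera_rate too high: need 2 distinct loci per chimera")
    pool <- sample(config$n_loci, 2L * n_chi)
    for (x in seq_len(n_chi)) {
      a <- loci[[pool[2 * x - 1]]]; b <- loci[[pool[2 * x]]]
      id <- sprintf("chim%03d", x)
      transcripts[[id]] <- list(locus = NA_character_,
                                start = c(a$exon_start, b$exon_start),
                                end = c(a$exon_end, b$exon_end))
      chi_ids <- c(chi_ids, id)
    }
  }
  n_con <- round(config$contaminant_rate * config$n_loci)
  con_ids <- if (n_con > 0) sprintf("cont%03d", seq_len(n_con)) else character()
  con_seqs <- vapply(seq_len(n_con),
                     function(i) random_dna(sample_range(c(300L, 1500L))),
                     character(1))

  # ---- sequences -----------------------------------------------------------
  tx_ids <- names(transcripts)
  tx_seqs <- vapply(transcripts, function(tr) {
    ord <- order(tr$start)
    paste(substring(genome_seq, tr$start[ord], tr$end[ord]), collapse = "")
  }, character(1))
  all_seqs <- Biostrings::DNAStringSet(c(tx_seqs, setNames(con_seqs, con_ids)))

  paths <- list(transcripts = file.path(out_dir, "transcripts.fasta"),
                truth = file.path(out_dir, "truth.tsv"),
                species_map = file.path(out_dir, "species_map.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  Biostrings::writeXStringSet(all_seqs, paths$transcripts, width = 70L)

  # ---- per-genome files ----------------------------------------------------
  j <- config$coordinate_jitter
  genome_paths <- annotation_paths <- alignment_paths <- character(config$n_genomes)
  for (g in seq_len(config$n_genomes)) {
    gtag <- sprintf("genome_%d", g)
    genome_paths[g] <- file.path(out_dir, paste0(gtag, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(genome_seq, "chr1")),
      genome_paths[g], width = 70L)

    ann <- list()
    for (l in seq_len(config$n_loci)) {
      loc <- loci[[l]]
      iso <- truth_groups[[loc$locus_id]]
      ann[[length(ann) + 1]] <- data.frame(
        start = min(loc$exon_start), end = max(loc$exon_end), type = "gene",
        ID = loc$locus_id, Name = loc$locus_id, Parent = NA_character_)
      for (id in iso) {
        tr <- transcripts[[id]]
        ann[[length(ann) + 1]] <- data.frame(
          start = min(tr$start), end = max(tr$end), type = "mRNA",
          ID = id, Name = id, Parent = loc$locus_id)
        ann[[length(ann) + 1]] <- data.frame(
          start = tr$start, end = tr$end, type = "exon",
          ID = NA_character_, Name = NA_character_, Parent = id)
      }
    }
    ann <- do.call(rbind, ann)
    ann$seq_id <- "chr1"; ann$strand <- "+"
    annotation_paths[g] <- file.path(out_dir, paste0("annotation_", g, ".gff3"))
    gff3_export(ann, annotation_paths[g])

    aln <- list()
    for (id in tx_ids) {
      tr <- transcripts[[id]]
      s <- tr$start; e <- tr$end
      if (g > 1 && j > 0) {
        delta <- vapply(seq_along(s), function(i) sample_range(c(-j, j)), integer(1))
        s <- pmax(1L, s + delta)
        e <- pmin(genome_len, e + delta)
      }
      pid <- paste0(id, ".path1")
      aln[[length(aln) + 1]] <- data.frame(
        start = min(s), end = max(e), type = "mRNA",
        ID = pid, Name = id, Parent = NA_character_,
        identity = 100, coverage = 100)
      aln[[length(aln) + 1]] <- data.frame(
        start = s, end = e, type = "exon",
        ID = NA_character_, Name = NA_character_, Parent = pid,
        identity = NA_real_, coverage = NA_real_)
    }
    alignment_paths[g] <- file.path(out_dir, paste0("alignments_", g, ".gff3"))
    if (length(aln)) {
      aln <- do.call(rbind, aln)
      aln$seq_id <- "chr1"; aln$strand <- "+"
      gff3_export(aln, alignment_paths[g])
    } else {
      writeLines("##gff-version 3", alignment_paths[g])
    }
  }

  # ---- truth, species map, manifest ---------------------------------------
  truth <- TrueClustering(truth_groups, "gff3_loci")
  truth_df <- data.frame(
    locus_id = rep(names(truth$groups), lengths(truth$groups)),
    transcript_id = unlist(truth$groups, use.names = FALSE))
  utils::write.table(truth_df, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(transcript_id = c(tx_ids, con_ids), species_tag = "simsp"),
    paths$species_map, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)

  manifest <- list(
    seed = config$seed, n_loci = config$n_loci, n_genomes = config$n_genomes,
    coordinate_jitter = config$coordinate_jitter,
    genome_length = genome_len,
    n_transcripts = length(tx_ids) + length(con_ids),
    isoforms = unname(unlist(truth$groups)),
    fragments = frag_ids, chimeras = chi_ids, contaminants = con_ids,
    loci = lapply(loci, function(l) list(locus_id = l$locus_id,
                                         n_exons = length(l$exon_start)))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)

  paths$genomes <- genome_paths
  paths$annotations <- annotation_paths
  paths$alignments <- alignment_paths
  invisible(list(paths = paths, truth = truth, manifest = manifest))
}

#' Simulate a transcript-level count matrix
#'
#' Negative-binomial counts with log-normal per-transcript baselines;
#' deterministic per seed.
#'
#' @param transcript_ids character vector of transcript ids (or a
#'   [TrueClustering()], whose members are used).
#' @param n_samples number of sample columns.
#' @param seed RNG seed.
#' @param meanlog,sdlog log-normal baseline parameters.
#' @param size negative-binomial dispersion parameter.
#' @return integer matrix, transcripts x samples (`sample_1`, ...).
#' @export
simulate_counts <- function(transcript_ids, n_samples = 6L, seed = 1L,
                            meanlog = 4, sdlog = 1, size = 2) {
  if (is(transcript_ids, "TrueClustering"))
    transcript_ids <- unlist(transcript_ids$groups, use.names = FALSE)
  set.seed(seed)
  mu <- stats::rlnorm(length(transcript_ids), meanlog, sdlog)
  m <- matrix(stats::rnbinom(length(transcript_ids) * n_samples,
                             mu = rep(mu, n_samples), size = size),
              nrow = length(transcript_ids), ncol = n_samples,
              dimnames = list(transcript_ids,
                              sprintf("sample_%d", seq_len(n_samples))))
  m
}
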