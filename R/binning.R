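# Bin seeding. A bin is a genomic interval on one sequence of one genome that
# collects the identifiers of transcripts whose exon alignments fall within
# it. Bins can be seeded de novo from the alignments themselves or pre-seeded
# from a reference annotation's exon coordinates (then frozen).

#' Construct a BinIndex
#'
#' @param bins data.frame with columns `bin_id`, `genome_id`, `seq_id`,
#'   `start`, `end`, `origin` (`"denovo"` or `"preseeded"`).
#' @param membership data.frame with columns `bin_id`, `transcript_id`; the
#'   exact (transcript, bin) incidence relation.
#' @return object of class `"BinIndex"`.
#' @export
BinIndex <- function(bins, membership) {
  bins <- as.data.frame(bins, stringsAsFactors = FALSE)
  membership <- as.data.frame(membership, stringsAsFactors = FALSE)
  stopifnot(all(c("bin_id", "genome_id", "seq_id", "start", "end", "origin") %in% names(bins)),
            all(c("bin_id", "transcript_id") %in% names(membership)))
  if (nrow(bins) && any(bins$end < bins$start))
    stop("bin with end < start")
  if (nrow(membership) && !all(membership$bin_id %in% bins$bin_id))
    stop("membership references unknown bin_id")
  membership <- unique(membership[c("bin_id", "transcript_id")])
  membership <- membership[order(membership$bin_id, membership$transcript_id), ,
                           drop = FALSE]
  rownames(bins) <- rownames(membership) <- NULL
  structure(list(bins = bins[order(bins$bin_id), , drop = FALSE],
                 membership = membership),
            class = "BinIndex")
}

#' @export
print.BinIndex <- function(x, ...) {
  cat(sprintf("BinIndex: %d bins on %d sequence(s), %d (transcript, bin) incidences, %d transcripts\n",
              nrow(x$bins), nrow(unique(x$bins[c("genome_id", "seq_id")])),
              nrow(x$membership), length(unique(x$membership$transcript_id))))
  invisible(x)
}

# Default multi-path policy: secondary alignment paths inflate a transcript's
# bin denominator and dilute its co-occurrence proportions, so only
# path_rank == 1 per (transcript, genome) is kept unless multipath = TRUE.
filter_paths <- function(placements, multipath = FALSE) {
  if (multipath || !nrow(placements)) return(placements)
  placements[placements$path_rank == 1L, , drop = FALSE]
}

# One bin space per (genome, sequence); with stranded = TRUE, per strand
# (unknown-strand placements then form their own space).
space_key <- function(placements, stranded) {
  if (stranded)
    paste(placements$genome_id, placements$seq_id, placements$strand, sep = "\r")
  else
    paste(placements$genome_id, placements$seq_id, sep = "\r")
}

# Merge blocks within one space into maximal bins: blocks overlapping by
# >= min_overlap bp share a bin, and the closure is taken so that no two
# resulting bins themselves overlap by >= min_overlap.
merge_blocks <- function(starts, ends, min_overlap) {
  ir <- IRanges::IRanges(start = starts, end = ends)
  if (min_overlap <= 1L) {
    red <- IRanges::reduce(ir)
    hits <- IRanges::findOverlaps(ir, red)
    return(list(start = BiocGenerics::start(red), end = BiocGenerics::end(red),
                block_bin = S4Vectors::subjectHits(hits)))
  }
  # general overlap criterion: components of the >= min_overlap overlap graph,
  # then a fixpoint merge of component ranges that still overlap enough
  comp <- seq_along(ir)
  rng_start <- starts; rng_end <- ends
  repeat {
    u <- sort(unique(comp))
    cs <- vapply(u, function(k) min(rng_start[comp == k]), numeric(1))
    ce <- vapply(u, function(k) max(rng_end[comp == k]), numeric(1))
    cir <- IRanges::IRanges(cs, ce)
    hits <- IRanges::findOverlaps(cir, minoverlap = min_overlap,
                                  drop.self = TRUE, drop.redundant = TRUE)
    # also components joined by individual blocks overlapping >= min_overlap
    bh <- IRanges::findOverlaps(ir, minoverlap = min_overlap,
                                drop.self = TRUE, drop.redundant = TRUE)
    pairs <- rbind(
      cbind(u[S4Vectors::queryHits(hits)], u[S4Vectors::subjectHits(hits)]),
      cbind(comp[S4Vectors::queryHits(bh)], comp[S4Vectors::subjectHits(bh)]))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (!nrow(pairs)) {
      ord <- order(cs, ce)
      return(list(start = as.integer(cs[ord]), end = as.integer(ce[ord]),
                  block_bin = match(comp, u[ord])))
    }
    relabel <- setNames(u, u)
    for (r in seq_len(nrow(pairs))) {
      a <- relabel[as.character(pairs[r, 1])]
      b <- relabel[as.character(pairs[r, 2])]
      m <- min(a, b)
      relabel[relabel %in% c(a, b)] <- m
    }
    comp <- unname(relabel[as.character(comp)])
  }
}

seed_space <- function(placements, min_overlap) {
  mb <- merge_blocks(placements$start, placements$end, min_overlap)
  list(bins = data.frame(start = mb$start, end = mb$end,
                         stringsAsFactors = FALSE),
       membership = unique(data.frame(local_bin = mb$block_bin,
                                      transcript_id = placements$transcript_id,
                                      stringsAsFactors = FALSE)))
}

finalise_index <- function(space_bins) {
  # space_bins: list of per-space lists with genome_id, seq_id, origin, bins,
  # membership(local_bin, transcript_id). Assigns global, deterministic ids.
  all_bins <- do.call(rbind, lapply(space_bins, function(s) {
    if (!nrow(s$bins)) return(NULL)
    data.frame(genome_id = s$genome_id, seq_id = s$seq_id,
               start = s$bins$start, end = s$bins$end, origin = s$origin,
               space = s$space, local_bin = seq_len(nrow(s$bins)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(all_bins) || !nrow(all_bins))
    return(BinIndex(data.frame(bin_id = integer(), genome_id = character(),
                               seq_id = character(), start = integer(),
                               end = integer(), origin = character(),
                               stringsAsFactors = FALSE),
                    data.frame(bin_id = integer(), transcript_id = character(),
                               stringsAsFactors = FALSE)))
  ord <- order(all_bins$genome_id, all_bins$seq_id, all_bins$start,
               all_bins$end, all_bins$origin)
  all_bins <- all_bins[ord, , drop = FALSE]
  all_bins$bin_id <- seq_len(nrow(all_bins))
  key <- paste(all_bins$space, all_bins$local_bin, sep = "\r")
  mem <- do.call(rbind, lapply(space_bins, function(s) {
    if (!nrow(s$membership)) return(NULL)
    data.frame(key = paste(s$space, s$membership$local_bin, sep = "\r"),
               transcript_id = s$membership$transcript_id,
               stringsAsFactors = FALSE)
  }))
  membership <- data.frame(bin_id = all_bins$bin_id[match(mem$key, key)],
                           transcript_id = mem$transcript_id,
                           stringsAsFactors = FALSE)
  BinIndex(all_bins[c("bin_id", "genome_id", "seq_id", "start", "end", "origin")],
           membership)
}

#' Seed bins de novo from transcript alignments
#'
#' Each exon alignment block either founds a new bin or joins (and extends)
#' every bin it overlaps by at least `min_overlap` bp on the same
#' (genome, sequence); bins that come to overlap after extension are merged.
#' The result is independent of input order.
#'
#' @param placements an [exon_placements()] table (alignment filters already
#'   applied).
#' @param min_overlap minimum block/bin overlap in bp (default 1).
#' @param stranded keep separate bin spaces per strand (default `FALSE`:
#'   bins are strandless).
#' @param multipath keep secondary alignment paths (default `FALSE`: only
#'   `path_rank == 1` per transcript and genome).
#' @return a [BinIndex()].
#' @export
seed_bins_denovo <- function(placements, min_overlap = 1L, stranded = FALSE,
                             multipath = FALSE) {
  placements <- filter_paths(placements, multipath)
  if (!nrow(placements)) return(finalise_index(list()))
  keys <- space_key(placements, stranded)
  spaces <- lapply(split(seq_len(nrow(placements)), keys), function(idx) {
    p <- placements[idx, , drop = FALSE]
    s <- seed_space(p, min_overlap)
    c(s, list(genome_id = p$genome_id[1], seq_id = p$seq_id[1],
              origin = "denovo", space = keys[idx][1]))
  })
  finalise_index(spaces)
}

#' Seed bins from a reference annotation, then assign transcript alignments
#'
#' Bins are founded from annotated exon blocks (overlapping annotated exons
#' merged, origin `"preseeded"`) and their coordinates frozen. Each transcript
#' exon block then joins every frozen bin it overlaps by at least
#' `min_overlap` bp without extending it. Transcript blocks overlapping no
#' frozen bin seed new de novo bins, so novel loci are not lost. Frozen bins
#' that collect no transcript are dropped.
#'
#' @param annotation_placements placements from [read_annotation_loci()].
#' @param transcript_placements transcript alignment placements.
#' @inheritParams seed_bins_denovo
#' @return a [BinIndex()].
#' @export
seed_bins_preseeded <- function(annotation_placements, transcript_placements,
                                min_overlap = 1L, stranded = FALSE,
                                multipath = FALSE) {
  transcript_placements <- filter_paths(transcript_placements, multipath)
  akeys <- space_key(annotation_placements, stranded)
  tkeys <- space_key(transcript_placements, stranded)
  spaces <- list()
  leftover_idx <- integer()
  for (key in unique(c(akeys, tkeys))) {
    a <- annotation_placements[akeys == key, , drop = FALSE]
    tp <- transcript_placements[tkeys == key, , drop = FALSE]
    t_idx <- which(tkeys == key)
    if (!nrow(a)) { leftover_idx <- c(leftover_idx, t_idx); next }
    frozen <- merge_blocks(a$start, a$end, 1L)
    fir <- IRanges::IRanges(frozen$start, frozen$end)
    meta <- list(genome_id = a$genome_id[1], seq_id = a$seq_id[1],
                 origin = "preseeded", space = key)
    if (nrow(tp)) {
      tir <- IRanges::IRanges(tp$start, tp$end)
      hits <- IRanges::findOverlaps(tir, fir, minoverlap = min_overlap)
      mem <- unique(data.frame(
        local_bin = S4Vectors::subjectHits(hits),
        transcript_id = tp$transcript_id[S4Vectors::queryHits(hits)],
        stringsAsFactors = FALSE))
      unhit <- setdiff(seq_len(nrow(tp)), S4Vectors::queryHits(hits))
      leftover_idx <- c(leftover_idx, t_idx[unhit])
    } else {
      mem <- data.frame(local_bin = integer(), transcript_id = character(),
                        stringsAsFactors = FALSE)
    }
    keep <- sort(unique(mem$local_bin))
    bins <- data.frame(start = frozen$start, end = frozen$end)[keep, , drop = FALSE]
    mem$local_bin <- match(mem$local_bin, keep)
    spaces[[key]] <- c(list(bins = bins, membership = mem), meta)
  }
  leftover <- transcript_placements[sort(leftover_idx), , drop = FALSE]
  if (nrow(leftover)) {
    lkeys <- space_key(leftover, stranded)
    for (key in unique(lkeys)) {
      p <- leftover[lkeys == key, , drop = FALSE]
      s <- seed_space(p, min_overlap)
      spaces[[paste0(key, "\rdenovo")]] <-
        c(s, list(genome_id = p$genome_id[1], seq_id = p$seq_id[1],
                  origin = "denovo", space = paste0(key, "\rdenovo")))
    }
  }
  finalise_index(spaces)
}

#' Bins a transcript occurs within
#'
#' @param index a [BinIndex()].
#' @param transcript_id transcript identifier.
#' @return integer vector of bin ids (empty when the transcript is unbinned).
#' @export
bins_of <- function(index, transcript_id) {
  stopifnot(is(index, "BinIndex"))
  sort(index$membership$bin_id[index$membership$transcript_id == transcript_id])
}

#' Transcripts with zero bin memberships
#'
#' @param index a [BinIndex()].
#' @param all_transcripts character vector of every input transcript id.
#' @return sorted character vector of unbinned transcript ids.
#' @export
unbinned_transcripts <- function(index, all_transcripts) {
  stopifnot(is(index, "BinIndex"))
  sort(setdiff(all_transcripts, unique(index$membership$transcript_id)))
}

#' Dump bins as a BED-like TSV for genome-browser inspection
#'
#' Columns: `seq_id`, 0-based `start`, `end`, `bin_id`, `origin`,
#' `member_count` (the only place a 0-based coordinate appears; for BED
#' compatibility).
#'
#' @param index a [BinIndex()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bin_bed <- function(index, path) {
  b <- index$bins
  counts <- table(index$membership$bin_id)
  out <- data.frame(seq_id = b$seq_id, start = b$start - 1L, end = b$end,
                    bin_id = b$bin_id, origin = b$origin,
                    member_count = as.integer(counts[as.character(b$bin_id)]),
                    stringsAsFactors = FALSE)
  out$member_count[is.na(out$member_count)] <- 0L
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
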