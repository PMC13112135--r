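# Fallback clustering for transcripts that aligned to no genome. A bespoke
# greedy incremental algorithm mirrors CD-HIT's -c/-aS/-aL acceptance
# semantics so that tests need no external binary; thin readers for CD-HIT
# .clstr and MMseqs2 cluster-TSV output are provided, plus an adapter that
# invokes the external tools when they are installed.

#' Greedy clustering parameters
#'
#' Defaults are the optimised locus-clustering values for plant/animal data:
#' 98% identity with 40% coverage of both the short and the long sequence.
#' The `"microbial"` preset keeps 98% identity but raises both coverages
#' to 80%.
#'
#' @param preset `"plant_animal"` (default) or `"microbial"`.
#' @param min_identity minimum identity over the aligned region, in (0, 1].
#' @param min_short_coverage,min_long_coverage minimum fraction of the
#'   shorter/longer sequence covered by the aligned region, in (0, 1].
#'   Defaults depend on `preset`.
#' @return list of class `"GreedyParams"`.
#' @export
greedy_params <- function(preset = c("plant_animal", "microbial"),
                          min_identity = 0.98,
                          min_short_coverage = NULL,
                          min_long_coverage = NULL) {
  preset <- match.arg(preset)
  cov_default <- if (preset == "microbial") 0.8 else 0.4
  if (is.null(min_short_coverage)) min_short_coverage <- cov_default
  if (is.null(min_long_coverage)) min_long_coverage <- cov_default
  p <- list(preset = preset, min_identity = min_identity,
            min_short_coverage = min_short_coverage,
            min_long_coverage = min_long_coverage)
  if (any(unlist(p[-1]) <= 0) || any(unlist(p[-1]) > 1))
    stop("greedy parameters must lie in (0, 1]")
  structure(p, class = "GreedyParams")
}

kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

# Local alignment statistics between a candidate and a representative.
alignment_stats <- function(cand, rep) {
  aln <- Biostrings::pairwiseAlignment(cand, rep, type = "local",
                                       gapOpening = 5, gapExtension = 2)
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  alen <- nchar(as.character(p))
  if (alen == 0)
    return(list(identity = 0, cov_cand = 0, cov_rep = 0))
  list(identity = Biostrings::nmatch(aln) / alen,
       cov_cand = (BiocGenerics::end(p) - BiocGenerics::start(p) + 1L) / nchar(cand),
       cov_rep = (BiocGenerics::end(s) - BiocGenerics::start(s) + 1L) / nchar(rep))
}

#' Greedy identity/coverage clustering of unbinned transcripts
#'
#' Sequences are processed longest-first (ties broken by identifier sort);
#' each sequence joins the first existing cluster whose representative it
#' matches at `min_identity` over the locally aligned region, with the
#' aligned region covering at least `min_short_coverage` of the shorter and
#' `min_long_coverage` of the longer sequence; otherwise it founds a new
#' cluster with itself as representative. A shared 15-mer prefilter skips
#' hopeless pairs (sequences shorter than the k-mer size always proceed to
#' alignment). Deterministic given the input set.
#'
#' @param seqs named `DNAStringSet` or named character vector of nucleotide
#'   sequences over \{A, C, G, T, N\}.
#' @param params a [greedy_params()] object.
#' @param kmer prefilter k-mer size (default 15).
#' @return a [Clustering()] with flag `"unbinned"`; cluster representatives
#'   (the founding, longest members) are recorded in the
#'   `"representatives"` attribute.
#' @export
greedy_cluster <- function(seqs, params = greedy_params(), kmer = 15L) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (!length(seqs)) return(Clustering())
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  seqs <- toupper(seqs)
  if (any(grepl("[^ACGTN]", seqs)))
    stop("non-nucleotide symbol in sequence: ",
         names(seqs)[grepl("[^ACGTN]", seqs)][1])
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character()      # representative sequence per cluster
  rep_ids <- character()
  rep_kmers <- list()
  assign <- setNames(integer(length(seqs)), names(seqs))
  p <- params
  for (idx in seq_along(seqs)) {
    cand <- seqs[[idx]]
    ck <- kmer_set(cand, kmer)
    placed <- 0L
    for (ci in seq_along(reps)) {
      if (length(ck) && length(rep_kmers[[ci]]) &&
          !any(ck %in% rep_kmers[[ci]])) next
      st <- alignment_stats(cand, reps[[ci]])
      # representative is never shorter than the candidate (longest-first)
      if (st$identity >= p$min_identity &&
          st$cov_cand >= p$min_short_coverage &&
          st$cov_rep >= p$min_long_coverage) {
        placed <- ci
        break
      }
    }
    if (!placed) {
      reps <- c(reps, cand)
      rep_ids <- c(rep_ids, names(seqs)[idx])
      rep_kmers <- c(rep_kmers, list(ck))
      placed <- length(reps)
    }
    assign[idx] <- placed
  }
  members <- split(names(assign), assign)
  members <- members[as.character(seq_along(reps))]  # founding order, not factor order
  names(members) <- sprintf("U%04d", seq_along(members))
  out <- clustering_from_list(members, flag = "unbinned")
  attr(out, "representatives") <-
    setNames(rep_ids, sprintf("U%04d", seq_along(rep_ids)))
  out
}

#' Merge binned and unbinned clusterings
#'
#' Concatenates the two clusterings under globally unique cluster ids
#' (`cluster_0001`, ... in binned-then-unbinned order), preserving flags and
#' combining the filtered reports.
#'
#' @param binned,unbinned [Clustering()] objects with disjoint members.
#' @return a single [Clustering()].
#' @export
merge_clusterings <- function(binned, unbinned) {
  stopifnot(is(binned, "Clustering"), is(unbinned, "Clustering"))
  overlap <- intersect(binned$clusters$transcript_id,
                       unbinned$clusters$transcript_id)
  if (length(overlap))
    stop("transcript present in both clusterings: ", overlap[1])
  # relabel each side independently: ids may collide between the inputs
  relabel <- function(df, offset) {
    old <- unique(df$cluster_id)
    map <- setNames(sprintf("cluster_%04d", offset + seq_along(old)), old)
    if (nrow(df)) df$cluster_id <- unname(map[df$cluster_id])
    df
  }
  n_binned <- length(unique(binned$clusters$cluster_id))
  df <- rbind(relabel(binned$clusters, 0L),
              relabel(unbinned$clusters, n_binned))
  Clustering(df, rbind(binned$filtered, unbinned$filtered))
}

#' Read a CD-HIT `.clstr` file as a Clustering
#'
#' @param path `.clstr` text output of CD-HIT/CD-HIT-EST.
#' @param flag cluster flag to assign (default `"unbinned"`).
#' @return a [Clustering()].
#' @export
read_cdhit_clstr <- function(path, flag = "unbinned") {
  lines <- readLines(path)
  cluster <- cumsum(startsWith(lines, ">Cluster"))
  member <- !startsWith(lines, ">Cluster") & nzchar(lines)
  ids <- sub("^.*>", "", sub("\\.\\.\\..*$", "", lines[member]))
  members <- split(ids, cluster[member])
  names(members) <- sprintf("U%04d", seq_along(members))
  clustering_from_list(members, flag = flag)
}

#' Read an MMseqs2 cluster TSV as a Clustering
#'
#' Two columns: representative id, member id (the representative also appears
#' as its own member).
#'
#' @param path MMseqs2 `createtsv` output.
#' @param flag cluster flag to assign (default `"unbinned"`).
#' @return a [Clustering()].
#' @export
read_mmseqs_tsv <- function(path, flag = "unbinned") {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("rep", "member"))
  members <- split(as.character(df$member), as.character(df$rep))
  members <- members[order(names(members))]
  names(members) <- sprintf("U%04d", seq_along(members))
  clustering_from_list(members, flag = flag)
}

#' Cluster unbinned transcripts with an external tool
#'
#' Interface adapter around CD-HIT-EST or MMseqs2. Parameters are mapped from
#' [greedy_params()] (CD-HIT: `-c/-aS/-aL`; MMseqs2: `--min-seq-id/-c`). The
#' tool binary must be on the `PATH`; tests never require it.
#'
#' @param tool `"cdhit"` or `"mmseqs2"`.
#' @param fasta_path FASTA of sequences to cluster.
#' @param params a [greedy_params()] object.
#' @param work_dir scratch directory for tool output.
#' @return a [Clustering()] with flag `"unbinned"`.
#' @export
external_tool_adapter <- function(tool = c("cdhit", "mmseqs2"), fasta_path,
                                  params = greedy_params(),
                                  work_dir = tempfile("extclust")) {
  tool <- match.arg(tool)
  binary <- c(cdhit = "cd-hit-est", mmseqs2 = "mmseqs")[[tool]]
  if (!nzchar(Sys.which(binary)))
    stop("external tool '", binary, "' not found on PATH; use the internal ",
         "greedy algorithm (greedy_cluster) instead")
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
  if (tool == "cdhit") {
    out <- file.path(work_dir, "cdhit_out")
    status <- system2(binary, c("-i", fasta_path, "-o", out,
                                "-c", params$min_identity,
                                "-aS", params$min_short_coverage,
                                "-aL", params$min_long_coverage, "-G", "0"),
                      stdout = FALSE)
    if (status != 0) stop("cd-hit-est failed with status ", status)
    read_cdhit_clstr(paste0(out, ".clstr"))
  } else {
    db <- file.path(work_dir, "db")
    res <- file.path(work_dir, "res")
    tsv <- file.path(work_dir, "clusters.tsv")
    for (args in list(c("createdb", fasta_path, db),
                      c("cluster", db, res, file.path(work_dir, "tmp"),
                        "--min-seq-id", params$min_identity,
                        "-c", params$min_short_coverage),
                      c("createtsv", db, db, res, tsv))) {
      status <- system2(binary, args, stdout = FALSE)
      if (status != 0) stop("mmseqs ", args[1], " failed with status ", status)
    }
    read_mmseqs_tsv(tsv)
  }
}
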