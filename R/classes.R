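# Lightweight S3 containers shared across the package. Coordinates are GFF3
# style throughout: 1-based, inclusive on both ends. No half-open conversions
# are exposed anywhere in the API.

CLUSTER_FLAGS <- c("binned", "unbinned")
FILTER_REASONS <- c("fragment", "chimera")

#' Construct a Clustering object
#'
#' A `Clustering` is a partition of transcript identifiers into clusters, each
#' flagged `binned` (placed via genome alignment bins) or `unbinned`
#' (sequence-identity fallback), together with a report of transcripts removed
#' by the fragment/chimera filters.
#'
#' @param clusters data.frame with columns `cluster_id`, `transcript_id`,
#'   `flag` (one of `"binned"`, `"unbinned"`). May have zero rows.
#' @param filtered data.frame with columns `transcript_id`, `reason` (one of
#'   `"fragment"`, `"chimera"`). Defaults to an empty report.
#' @return An object of class `"Clustering"`.
#' @examples
#' cl <- Clustering(data.frame(cluster_id = "c1",
#'                             transcript_id = c("t1", "t2"),
#'                             flag = "binned"))
#' n_clusters(cl)
#' @export
Clustering <- function(clusters = empty_clusters_df(), filtered = empty_filtered_df()) {
  clusters <- as.data.frame(clusters, stringsAsFactors = FALSE)
  filtered <- as.data.frame(filtered, stringsAsFactors = FALSE)
  need <- c("cluster_id", "transcript_id", "flag")
  if (!all(need %in% names(clusters)))
    stop("`clusters` must have columns: ", paste(need, collapse = ", "))
  if (!all(c("transcript_id", "reason") %in% names(filtered)))
    stop("`filtered` must have columns: transcript_id, reason")
  clusters <- data.frame(
    cluster_id = as.character(clusters$cluster_id),
    transcript_id = as.character(clusters$transcript_id),
    flag = as.character(clusters$flag),
    stringsAsFactors = FALSE
  )
  filtered <- data.frame(
    transcript_id = as.character(filtered$transcript_id),
    reason = as.character(filtered$reason),
    stringsAsFactors = FALSE
  )
  if (nrow(clusters) && !all(clusters$flag %in% CLUSTER_FLAGS))
    stop("unknown cluster flag: ",
         paste(setdiff(unique(clusters$flag), CLUSTER_FLAGS), collapse = ", "))
  if (nrow(filtered) && !all(filtered$reason %in% FILTER_REASONS))
    stop("unknown filter reason: ",
         paste(setdiff(unique(filtered$reason), FILTER_REASONS), collapse = ", "))
  if (anyDuplicated(clusters$transcript_id)) {
    dup <- clusters$transcript_id[duplicated(clusters$transcript_id)][1]
    stop("transcript assigned to more than one cluster: ", dup)
  }
  if (anyDuplicated(filtered$transcript_id))
    stop("duplicate transcript in filtered report")
  bad <- intersect(clusters$transcript_id, filtered$transcript_id)
  if (length(bad))
    stop("transcript both clustered and filtered: ", bad[1])
  ord <- order(clusters$cluster_id, clusters$transcript_id)
  clusters <- clusters[ord, , drop = FALSE]
  rownames(clusters) <- NULL
  filtered <- filtered[order(filtered$transcript_id), , drop = FALSE]
  rownames(filtered) <- NULL
  structure(list(clusters = clusters, filtered = filtered), class = "Clustering")
}

empty_clusters_df <- function() {
  data.frame(cluster_id = character(), transcript_id = character(),
             flag = character(), stringsAsFactors = FALSE)
}

empty_filtered_df <- function() {
  data.frame(transcript_id = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Clustering from a list of member vectors
#'
#' @param members named list; each element a character vector of transcript
#'   ids, names become cluster ids (auto-generated when absent).
#' @param flag `"binned"` or `"unbinned"`, recycled across clusters.
#' @param filtered optional filtered-transcript report.
#' @return A [Clustering()] object.
#' @export
clustering_from_list <- function(members, flag = "binned", filtered = empty_filtered_df()) {
  if (!length(members))
    return(Clustering(filtered = filtered))
  ids <- names(members)
  if (is.null(ids)) ids <- sprintf("cluster_%04d", seq_along(members))
  flag <- rep_len(flag, length(members))
  df <- data.frame(
    cluster_id = rep(ids, lengths(members)),
    transcript_id = unlist(members, use.names = FALSE),
    flag = rep(flag, lengths(members)),
    stringsAsFactors = FALSE
  )
  Clustering(df, filtered)
}

#' @export
print.Clustering <- function(x, ...) {
  cl <- x$clusters
  cat(sprintf("Clustering: %d transcripts in %d clusters (%d binned, %d unbinned); %d filtered\n",
              nrow(cl), length(unique(cl$cluster_id)),
              length(unique(cl$cluster_id[cl$flag == "binned"])),
              length(unique(cl$cluster_id[cl$flag == "unbinned"])),
              nrow(x$filtered)))
  invisible(x)
}

#' Number of clusters in a Clustering
#' @param x a [Clustering()] object.
#' @return integer cluster count.
#' @export
n_clusters <- function(x) {
  stopifnot(is(x, "Clustering"))
  length(unique(x$clusters$cluster_id))
}

#' Cluster membership as a named vector
#'
#' @param x a `Clustering` or `TrueClustering`.
#' @return named character vector mapping transcript id to cluster/group id.
#' @export
partition_of <- function(x) {
  if (is(x, "Clustering"))
    return(setNames(x$clusters$cluster_id, x$clusters$transcript_id))
  if (is(x, "TrueClustering")) {
    g <- x$groups
    return(setNames(rep(names(g), lengths(g)), unlist(g, use.names = FALSE)))
  }
  if (is.character(x) && !is.null(names(x)))
    return(x)
  stop("cannot interpret object as a partition")
}

#' Construct a TrueClustering (reference partition)
#'
#' Ground-truth locus groups, either gene loci from a GFF3 annotation
#' (isoforms grouped under their parent gene) or connected components of a
#' one-to-one ortholog-pair graph.
#'
#' @param groups named list mapping locus/group id to a character vector of
#'   transcript (or gene) identifiers. Groups must be non-empty and pairwise
#'   disjoint.
#' @param provenance `"gff3_loci"` or `"ortholog_pairs"`.
#' @return An object of class `"TrueClustering"`.
#' @export
TrueClustering <- function(groups, provenance = c("gff3_loci", "ortholog_pairs")) {
  provenance <- match.arg(provenance)
  if (is.null(names(groups)) && length(groups))
    stop("groups must be named by locus id")
  groups <- lapply(groups, function(g) sort(unique(as.character(g))))
  if (any(lengths(groups) == 0))
    stop("empty true-cluster group")
  all_ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("transcript in more than one true group: ",
         all_ids[duplicated(all_ids)][1])
  structure(list(groups = groups, provenance = provenance),
            class = "TrueClustering")
}

#' @export
print.TrueClustering <- function(x, ...) {
  cat(sprintf("TrueClustering (%s): %d groups, %d members\n",
              x$provenance, length(x$groups),
              sum(lengths(x$groups))))
  invisible(x)
}

# Exon placements are plain data.frames with one row per alignment block and
# the columns below; helper validates structural invariants.
PLACEMENT_COLS <- c("transcript_id", "genome_id", "seq_id", "start", "end",
                    "strand", "identity", "coverage", "path_rank")

#' Construct an exon-placement table
#'
#' One row per exon-level alignment block. A *placement* is one alignment path
#' of one transcript on one genome (all rows sharing `transcript_id`,
#' `genome_id`, `path_rank`); its blocks must be sorted by start and
#' non-overlapping.
#'
#' @param df data.frame with columns `transcript_id`, `genome_id`, `seq_id`,
#'   `start`, `end`, `strand` (`"+"`, `"-"` or `"*"` for unknown), `identity`,
#'   `coverage` (fractions in \[0,1\]), `path_rank` (integer >= 1).
#' @return the validated data.frame, block-sorted within each placement.
#' @export
exon_placements <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(PLACEMENT_COLS, names(df))
  if (length(missing))
    stop("placement table missing columns: ", paste(missing, collapse = ", "))
  if (!nrow(df)) return(df[PLACEMENT_COLS])
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$end < df$start))
    stop("placement block with end < start")
  if (any(df$identity < 0 | df$identity > 1 | df$coverage < 0 | df$coverage > 1))
    stop("identity/coverage must lie in [0, 1]")
  if (any(df$path_rank < 1))
    stop("path_rank must be >= 1")
  df$strand[!df$strand %in% c("+", "-")] <- "*"
  key <- paste(df$transcript_id, df$genome_id, df$path_rank, sep = "\r")
  ord <- order(key, df$start, df$end)
  df <- df[ord, , drop = FALSE]
  # non-overlap within one placement path
  same <- key[ord][-1] == key[ord][-length(key)]
  if (any(same & df$start[-1] <= df$end[-nrow(df)]))
    stop("overlapping blocks within a single placement")
  rownames(df) <- NULL
  df[union(PLACEMENT_COLS, names(df))]
}

empty_placements <- function() {
  exon_placements(data.frame(
    transcript_id = character(), genome_id = character(), seq_id = character(),
    start = integer(), end = integer(), strand = character(),
    identity = numeric(), coverage = numeric(), path_rank = integer(),
    stringsAsFactors = FALSE))
}
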