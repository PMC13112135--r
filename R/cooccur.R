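# Clustering by co-occurrence: the core algorithm. Transcripts are nodes; the
# directed co-occurrence proportion prop(i -> j) is the number of bins shared
# by i and j divided by the number of bins i occurs in. An undirected edge is
# formed when either direction reaches the threshold. Components of the graph,
# after fragment and chimera filtering, are the binned locus clusters.

#' Directed co-occurrence proportion of one transcript with another
#'
#' `cooccurrence(index, i, j)` = |bins(i) intersect bins(j)| / |bins(i)|: the
#' proportion of the bins of the *current* transcript `i` in which the other
#' transcript `j` is also found. `cooccurrence(index, i, i)` is defined as 1.
#'
#' @param index a [BinIndex()].
#' @param i,j transcript identifiers; `i` must occur in at least one bin.
#' @return fraction in \[0, 1\].
#' @export
cooccurrence <- function(index, i, j) {
  bi <- bins_of(index, i)
  if (!length(bi))
    stop("transcript has no bins: ", i)
  if (identical(i, j)) return(1)
  length(intersect(bi, bins_of(index, j))) / length(bi)
}

#' Build the co-occurrence graph
#'
#' Only transcript pairs sharing at least one bin are evaluated (never
#' all-pairs). An undirected edge \{i, j\} exists iff
#' `prop(i -> j) >= t` **or** `prop(j -> i) >= t`.
#'
#' @param index a [BinIndex()].
#' @param t co-occurrence proportion threshold in (0, 1]; default 0.66.
#' @return object of class `"CooccurrenceGraph"`: list with `nodes` (sorted
#'   ids of all binned transcripts), `n_bins` (named bin counts), `pairs`
#'   (data.frame `i`, `j`, `shared`, `prop_ij`, `prop_ji`, `edge`; `i < j`),
#'   and `threshold`.
#' @export
build_graph <- function(index, t = 0.66) {
  stopifnot(is(index, "BinIndex"), t > 0, t <= 1)
  mem <- index$membership
  nodes <- sort(unique(mem$transcript_id))
  n_bins <- table(mem$transcript_id)
  n_bins <- setNames(as.integer(n_bins), names(n_bins))[nodes]
  if (nrow(mem)) {
    m2 <- merge(mem, mem, by = "bin_id")
    m2 <- m2[m2$transcript_id.x < m2$transcript_id.y, , drop = FALSE]
    if (nrow(m2)) {
      key <- paste(m2$transcript_id.x, m2$transcript_id.y, sep = "\r")
      shared <- table(key)
      ij <- strsplit(names(shared), "\r", fixed = TRUE)
      pairs <- data.frame(
        i = vapply(ij, `[`, character(1), 1L),
        j = vapply(ij, `[`, character(1), 2L),
        shared = as.integer(shared),
        stringsAsFactors = FALSE
      )
    } else pairs <- NULL
  } else pairs <- NULL
  if (is.null(pairs)) {
    pairs <- data.frame(i = character(), j = character(), shared = integer(),
                        prop_ij = numeric(), prop_ji = numeric(),
                        edge = logical(), stringsAsFactors = FALSE)
  } else {
    pairs$prop_ij <- pairs$shared / n_bins[pairs$i]
    pairs$prop_ji <- pairs$shared / n_bins[pairs$j]
    pairs$edge <- pairs$prop_ij >= t | pairs$prop_ji >= t
    pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(nodes = nodes, n_bins = n_bins, pairs = pairs, threshold = t),
            class = "CooccurrenceGraph")
}

#' @export
print.CooccurrenceGraph <- function(x, ...) {
  cat(sprintf("CooccurrenceGraph: %d nodes, %d edges (threshold %.2f)\n",
              length(x$nodes), sum(x$pairs$edge), x$threshold))
  invisible(x)
}

edge_table <- function(graph) graph$pairs[graph$pairs$edge, , drop = FALSE]

#' Detect probable fragment transcripts
#'
#' A *relationship* of node i is any edge \{i, j\}; it is one-sided against i
#' when `prop(i -> j) >= t` but `prop(j -> i) < t` (i co-occurs with j, j does
#' not reciprocate — the signature of a fragment sitting inside a longer
#' transcript's bins). Transcripts whose one-sided relationships account for
#' at least 50% of their relationships are returned as probable fragments; a
#' tie at exactly 50% is removed. Nodes with no relationships are never
#' fragments.
#'
#' @param graph a [build_graph()] result.
#' @return sorted character vector of fragment transcript ids.
#' @export
detect_fragments <- function(graph) {
  e <- edge_table(graph)
  if (!nrow(e)) return(character())
  t <- graph$threshold
  one_sided_i <- e$prop_ij >= t & e$prop_ji < t  # against i
  one_sided_j <- e$prop_ji >= t & e$prop_ij < t  # against j
  nodes <- c(e$i, e$j)
  against <- c(one_sided_i, one_sided_j)
  rel <- table(nodes)
  bad <- tapply(against, nodes, sum)
  frac <- bad[names(rel)] / as.integer(rel)
  sort(names(rel)[frac >= 0.5])
}

as_igraph <- function(graph, exclude = character()) {
  keep <- setdiff(graph$nodes, exclude)
  e <- edge_table(graph)
  e <- e[e$i %in% keep & e$j %in% keep, , drop = FALSE]
  igraph::graph_from_data_frame(e[c("i", "j")], directed = FALSE,
                                vertices = keep)
}

#' Detect probable chimeric transcripts
#'
#' Chimeras erroneously fuse two loci and surface as articulation points of a
#' graph component: their removal disconnects otherwise unrelated subgraphs.
#' Detection is a single simultaneous pass (no iterative re-detection after
#' removal). Call after fragment removal. Components of size <= 2 yield none.
#'
#' @param graph a [build_graph()] result.
#' @param exclude transcripts already removed (e.g. fragments).
#' @return sorted character vector of chimera transcript ids.
#' @export
detect_chimeras <- function(graph, exclude = character()) {
  g <- as_igraph(graph, exclude)
  if (!igraph::vcount(g)) return(character())
  sort(names(igraph::articulation_points(g)))
}

#' Extract binned locus clusters from the filtered graph
#'
#' Connected components of the co-occurrence graph, after removing fragments
#' and chimeras, become "binned" locus clusters; isolated surviving nodes
#' become singleton binned clusters. Filtered transcripts are recorded with
#' their reason and excluded from all clusters.
#'
#' @param graph a [build_graph()] result.
#' @param fragments ids from [detect_fragments()].
#' @param chimeras ids from [detect_chimeras()].
#' @return a [Clustering()] with flag `"binned"`.
#' @export
extract_binned_clusters <- function(graph, fragments = character(),
                                    chimeras = character()) {
  chimeras <- setdiff(chimeras, fragments)
  g <- as_igraph(graph, c(fragments, chimeras))
  filtered <- data.frame(
    transcript_id = c(fragments, chimeras),
    reason = c(rep("fragment", length(fragments)),
               rep("chimera", length(chimeras))),
    stringsAsFactors = FALSE
  )
  if (!igraph::vcount(g))
    return(Clustering(filtered = filtered))
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  members <- members[order(vapply(members, `[`, character(1), 1L))]
  names(members) <- sprintf("B%04d", seq_along(members))
  clustering_from_list(members, flag = "binned", filtered = filtered)
}

#' Write the co-occurrence edge list as TSV (debugging aid)
#'
#' One row per evaluated pair with both directed proportions and the edge
#' indicator.
#'
#' @param graph a [build_graph()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(graph, path) {
  utils::write.table(graph$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
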