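# Partition-agreement evaluation. A test clustering is compared to a true
# clustering (annotation loci or ortholog components) over the transcripts
# present in BOTH partitions; dropped items are counted and reported. RI/ARI
# are pair-counting metrics; NMI/AMI are information-theoretic, normalised by
# the arithmetic mean of the two entropies, with the expected mutual
# information under the hypergeometric model used for the AMI adjustment.
# Natural logarithms throughout.

common_contingency <- function(test, truth) {
  pt <- partition_of(test)
  pv <- partition_of(truth)
  common <- intersect(names(pt), names(pv))
  list(
    tab = if (length(common)) table(test = pt[common], truth = pv[common]) else NULL,
    n = length(common),
    dropped_test = length(pt) - length(common),
    dropped_truth = length(pv) - length(common),
    n_test_clusters = length(unique(pt[common])),
    n_true_groups = length(unique(pv[common]))
  )
}

#' Pair-confusion counts between a test and a true partition
#'
#' Over the items present in both partitions, counts the C(n, 2) item pairs:
#' `a` together in both, `b` together only in the test partition, `c`
#' together only in the true partition, `d` apart in both.
#'
#' @param test a [Clustering()] (or named membership vector).
#' @param truth a [TrueClustering()] (or named membership vector).
#' @return list with `a`, `b`, `c`, `d`, `n` (items compared) and dropped-item
#'   counts `dropped_test`, `dropped_truth`.
#' @export
pair_confusion <- function(test, truth) {
  cc <- common_contingency(test, truth)
  if (cc$n < 2)
    stop("need at least 2 items shared by both partitions (have ", cc$n, ")")
  nij <- as.vector(cc$tab)
  ai <- rowSums(cc$tab)
  bj <- colSums(cc$tab)
  a <- sum(choose(nij, 2))
  b <- sum(choose(ai, 2)) - a
  c <- sum(choose(bj, 2)) - a
  d <- choose(cc$n, 2) - a - b - c
  list(a = a, b = b, c = c, d = d, n = cc$n,
       dropped_test = cc$dropped_test, dropped_truth = cc$dropped_truth)
}

entropy_nat <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

mutual_information <- function(tab, n) {
  ai <- rowSums(tab)
  bj <- colSums(tab)
  nij <- as.vector(tab)
  e <- outer(ai, bj)
  terms <- nij / n * log(n * nij / as.vector(e))
  sum(terms[nij > 0])
}

# Expected mutual information under the hypergeometric (permutation) model.
expected_mi <- function(ai, bj, n) {
  lgn <- lgamma(n + 1)
  emi <- 0
  for (a in ai) {
    for (b in bj) {
      lo <- max(1L, a + b - n)
      hi <- min(a, b)
      if (hi < lo) next
      k <- lo:hi
      lp <- lgamma(a + 1) + lgamma(b + 1) + lgamma(n - a + 1) + lgamma(n - b + 1) -
        lgn - lgamma(k + 1) - lgamma(a - k + 1) - lgamma(b - k + 1) -
        lgamma(n - a - b + k + 1)
      emi <- emi + sum(k / n * log(n * k / (a * b)) * exp(lp))
    }
  }
  emi
}

#' Partition-agreement metrics (RI, ARI, NMI, AMI)
#'
#' * RI = (a + d) / C(n, 2) from the [pair_confusion()] counts.
#' * ARI is the permutation-model chance-adjusted Rand index from the
#'   contingency table.
#' * NMI = MI / mean(H(test), H(truth)) (arithmetic mean).
#' * AMI = (MI - E\[MI\]) / (mean entropy - E\[MI\]), E\[MI\] under the
#'   hypergeometric model.
#'
#' Identical partitions give all four metrics 1 (including the degenerate
#' one-cluster-vs-one-cluster case); 0/0 situations otherwise resolve to 0.
#' ARI and AMI can be negative and are reported as computed, not clamped.
#'
#' @inheritParams pair_confusion
#' @return list of class `"PartitionMetrics"` with fields `ri`, `ari`, `nmi`,
#'   `ami`, `n_test_clusters`, `n_true_groups`, `n_items_compared`,
#'   `dropped_test`, `dropped_truth`.
#' @export
compute_metrics <- function(test, truth) {
  cc <- common_contingency(test, truth)
  if (cc$n < 2)
    stop("need at least 2 items shared by both partitions (have ", cc$n, ")")
  tab <- cc$tab
  n <- cc$n
  ai <- rowSums(tab)
  bj <- colSums(tab)
  sum_nij <- sum(choose(as.vector(tab), 2))
  sum_ai <- sum(choose(ai, 2))
  sum_bj <- sum(choose(bj, 2))
  total <- choose(n, 2)
  ri <- (total + 2 * sum_nij - sum_ai - sum_bj) / total

  exp_idx <- sum_ai * sum_bj / total
  max_idx <- (sum_ai + sum_bj) / 2
  ari <- if (max_idx == exp_idx) {
    # both partitions place every pair identically (e.g. all-singletons vs
    # all-singletons, or single-cluster vs single-cluster)
    1
  } else {
    (sum_nij - exp_idx) / (max_idx - exp_idx)
  }

  hu <- entropy_nat(ai, n)
  hv <- entropy_nat(bj, n)
  mi <- mutual_information(tab, n)
  mean_h <- (hu + hv) / 2
  nmi <- if (mean_h == 0) 1 else mi / mean_h  # both trivial => identical
  ami <- if (mean_h == 0) {
    1
  } else {
    emi <- expected_mi(ai, bj, n)
    denom <- mean_h - emi
    if (denom == 0) 0 else (mi - emi) / denom
  }

  structure(list(ri = ri, ari = ari, nmi = nmi, ami = ami,
                 n_test_clusters = cc$n_test_clusters,
                 n_true_groups = cc$n_true_groups,
                 n_items_compared = n,
                 dropped_test = cc$dropped_test,
                 dropped_truth = cc$dropped_truth),
            class = "PartitionMetrics")
}

#' @export
print.PartitionMetrics <- function(x, ...) {
  cat(sprintf(paste0("PartitionMetrics over %d items ",
                     "(%d test clusters vs %d true groups):\n",
                     "  RI = %.6f  ARI = %.6f  NMI = %.6f  AMI = %.6f\n"),
              x$n_items_compared, x$n_test_clusters, x$n_true_groups,
              x$ri, x$ari, x$nmi, x$ami))
  if (x$dropped_test || x$dropped_truth)
    cat(sprintf("  dropped: %d test-only, %d truth-only items\n",
                x$dropped_test, x$dropped_truth))
  invisible(x)
}

#' Subset a clustering to one species' transcripts
#'
#' Each cluster is intersected with the transcripts carrying the given
#' species tag; clusters with an empty intersection are dropped. Used for the
#' per-species evaluation of a multispecies clustering.
#'
#' @param clustering a [Clustering()].
#' @param species_map data.frame with columns `transcript_id`, `species_tag`
#'   (e.g. from [read_species_map()] or [read_transcripts()]).
#' @param species_tag tag to keep; must be present in `species_map`.
#' @return a [Clustering()] containing only that species' transcripts.
#' @export
subset_by_species <- function(clustering, species_map, species_tag) {
  stopifnot(is(clustering, "Clustering"))
  known <- sort(unique(species_map$species_tag))
  if (!species_tag %in% known)
    stop("unknown species tag '", species_tag, "'; known tags: ",
         paste(known, collapse = ", "))
  keep_ids <- species_map$transcript_id[species_map$species_tag == species_tag]
  cl <- clustering$clusters
  cl <- cl[cl$transcript_id %in% keep_ids, , drop = FALSE]
  fl <- clustering$filtered
  fl <- fl[fl$transcript_id %in% keep_ids, , drop = FALSE]
  Clustering(cl, fl)
}

#' Write an evaluation report TSV
#'
#' One row per evaluated (label, metrics) entry with a deterministic column
#' order: `label`, `ri`, `ari`, `nmi`, `ami`, `n_test_clusters`,
#' `n_true_groups`, `n_items_compared`.
#'
#' @param metrics_list named list of [compute_metrics()] results; names become
#'   the `label` column.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
evaluation_report <- function(metrics_list, path) {
  cols <- c("ri", "ari", "nmi", "ami", "n_test_clusters", "n_true_groups",
            "n_items_compared")
  labels <- names(metrics_list) %||% sprintf("eval_%d", seq_along(metrics_list))
  rows <- lapply(metrics_list, function(m) as.data.frame(m[cols]))
  df <- do.call(rbind, c(list(data.frame()), rows))
  df <- cbind(data.frame(label = labels), df)
  if (!nrow(df))
    df <- data.frame(label = character(),
                     ri = numeric(), ari = numeric(), nmi = numeric(),
                     ami = numeric(), n_test_clusters = integer(),
                     n_true_groups = integer(), n_items_compared = integer())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
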