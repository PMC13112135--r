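# Representative selection, transcript -> cluster mapping export, and
# locus-level aggregation of transcript count matrices (salmon-style
# estimated counts; values may be fractional and are never rounded).

#' Select the longest transcript of each cluster as its representative
#'
#' Ties in length are broken by the lexicographically smallest identifier.
#'
#' @param clustering a [Clustering()].
#' @param lengths named numeric vector of transcript lengths (bp); every
#'   cluster member must be present.
#' @return named character vector mapping `cluster_id` to the representative
#'   `transcript_id`.
#' @export
select_representatives <- function(clustering, lengths) {
  stopifnot(is(clustering, "Clustering"))
  cl <- clustering$clusters
  missing <- setdiff(cl$transcript_id, names(lengths))
  if (length(missing))
    stop("no length known for transcript: ", missing[1])
  reps <- vapply(split(cl$transcript_id, cl$cluster_id), function(members) {
    len <- lengths[members]
    best <- members[len == max(len)]
    sort(best)[1]
  }, character(1))
  reps[sort(names(reps))]
}

#' Read / write a transcript-level count matrix TSV
#'
#' First column holds transcript ids, remaining columns one sample each.
#' Values are non-negative reals (estimated counts may be fractional).
#'
#' @param path TSV path.
#' @return `read_counts()` returns a numeric matrix with transcript rownames;
#'   `write_counts()` returns `path` invisibly.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) stop("duplicate transcript id in counts")
  if (anyDuplicated(colnames(m))) stop("duplicate sample id in counts")
  if (any(m < 0)) stop("negative count value")
  m
}

#' @rdname read_counts
#' @param counts numeric matrix, transcripts x samples.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(transcript_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate transcript counts to the cluster (locus) level
#'
#' Each cluster's count per sample is the sum of its member transcripts'
#' counts. Rows for filtered transcripts are dropped with a warning; a row
#' that is neither clustered nor filtered is an error. Per-sample totals are
#' conserved up to dropped rows.
#'
#' @param counts numeric matrix (transcripts x samples), e.g. from
#'   [read_counts()].
#' @param clustering a [Clustering()].
#' @return numeric matrix with one row per cluster id.
#' @export
aggregate_counts <- function(counts, clustering) {
  stopifnot(is(clustering, "Clustering"), is.matrix(counts))
  cl <- clustering$clusters
  ids <- rownames(counts)
  unknown <- setdiff(ids, c(cl$transcript_id, clustering$filtered$transcript_id))
  if (length(unknown))
    stop("transcript in count matrix but in no cluster and not filtered: ",
         unknown[1])
  drop <- intersect(ids, clustering$filtered$transcript_id)
  if (length(drop))
    warning(length(drop), " filtered transcript row(s) dropped from counts")
  keep <- setdiff(ids, drop)
  counts <- counts[keep, , drop = FALSE]
  groups <- cl$cluster_id[match(keep, cl$transcript_id)]
  out <- rowsum(counts, group = groups, reorder = TRUE)
  out
}

#' Write a tximport-style transcript-to-gene map
#'
#' Two columns, `TXNAME` and `GENEID` (the cluster id), one row per clustered
#' transcript, sorted by cluster then transcript. Filtered transcripts are
#' absent.
#'
#' @param clustering a [Clustering()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_tx2gene <- function(clustering, path) {
  stopifnot(is(clustering, "Clustering"))
  cl <- clustering$clusters
  df <- data.frame(TXNAME = cl$transcript_id, GENEID = cl$cluster_id,
                   stringsAsFactors = FALSE)
  df <- df[order(df$GENEID, df$TXNAME), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Emit a pre-configured R count-import script
#'
#' Generates a small, self-contained R script that loads salmon-style
#' quantifications with tximport, aggregates them to the locus level via the
#' tx2gene map, and writes a locus-level count table. The output is generated
#' from a fixed template and is deterministic for fixed inputs.
#'
#' @param tx2gene_path path to the tx2gene TSV (written into the script).
#' @param quant_dirs character vector of per-sample quantification
#'   directories (each expected to contain `quant.sf`).
#' @param path output script path.
#' @return `path`, invisibly.
#' @export
emit_import_script <- function(tx2gene_path, quant_dirs, path) {
  dirs <- paste(sprintf('  "%s"', quant_dirs), collapse = ",\n")
  script <- sprintf(
'# Locus-level count import (generated; edit paths as needed)
library(tximport)

tx2gene <- read.delim("%s", stringsAsFactors = FALSE)
quant_dirs <- c(
%s
)
names(quant_dirs) <- basename(quant_dirs)
files <- file.path(quant_dirs, "quant.sf")
stopifnot(all(file.exists(files)))

txi <- tximport(files, type = "salmon", tx2gene = tx2gene,
                countsFromAbundance = "no")
write.table(data.frame(cluster_id = rownames(txi$counts), txi$counts,
                       check.names = FALSE),
            "locus_counts.tsv", sep = "\\t", quote = FALSE, row.names = FALSE)
', tx2gene_path, dirs)
  writeLines(script, path)
  invisible(path)
}
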