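# Shared fixture builders and independent brute-force oracles. The oracles
# deliberately avoid the code paths (and libraries) they are checking.

# ---- bin-layout fixtures ----------------------------------------------------

# Build a BinIndex directly from a named list transcript_id -> integer bin ids
# (bins get arbitrary distinct, non-overlapping coordinates).
bin_index_from_members <- function(members, genome_id = "G1", seq_id = "chr1") {
  bin_ids <- sort(unique(unlist(members)))
  if (!length(bin_ids))
    return(BinIndex(data.frame(bin_id = integer(), genome_id = character(),
                               seq_id = character(), start = integer(),
                               end = integer(), origin = character()),
                    data.frame(bin_id = integer(), transcript_id = character())))
  bins <- data.frame(
    bin_id = bin_ids, genome_id = genome_id, seq_id = seq_id,
    start = bin_ids * 1000L + 1L, end = bin_ids * 1000L + 100L,
    origin = "denovo", stringsAsFactors = FALSE)
  membership <- data.frame(
    bin_id = unlist(members, use.names = FALSE),
    transcript_id = rep(names(members), lengths(members)),
    stringsAsFactors = FALSE)
  BinIndex(bins, membership)
}

# Random bin layout: <= max_tx transcripts over <= max_bins bins.
random_bin_layout <- function(case, max_tx = 40L, max_bins = 30L) {
  set.seed(2000L + case)
  nt <- sample(2:max_tx, 1)
  nb <- sample(2:max_bins, 1)
  members <- lapply(seq_len(nt), function(i)
    sort(sample(nb, sample(min(nb, 8L), 1))))
  names(members) <- sprintf("t%02d", seq_len(nt))
  members
}

# Brute-force all-pairs evaluation of the co-occurrence edge rule.
oracle_edges <- function(members, t) {
  ids <- sort(names(members))
  out <- character()
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (a >= b) next
      sh <- length(intersect(members[[ids[a]]], members[[ids[b]]]))
      if (sh > 0 &&
          (sh / length(members[[ids[a]]]) >= t ||
           sh / length(members[[ids[b]]]) >= t))
        out <- c(out, paste(ids[a], ids[b]))
    }
  }
  sort(out)
}

graph_edges <- function(graph) {
  e <- graph$pairs[graph$pairs$edge, , drop = FALSE]
  sort(paste(e$i, e$j))
}

# ---- placement fixtures -----------------------------------------------------

make_placements <- function(tid, blocks, genome_id = "G1", seq_id = "chr1",
                            strand = "+", identity = 1, coverage = 1,
                            path_rank = 1L) {
  exon_placements(data.frame(
    transcript_id = tid, genome_id = genome_id, seq_id = seq_id,
    start = blocks[, 1], end = blocks[, 2], strand = strand,
    identity = identity, coverage = coverage, path_rank = path_rank,
    stringsAsFactors = FALSE))
}

rbind_placements <- function(...) do.call(rbind, list(...))

# Hand-written GMAP-style GFF3 (mRNA/exon dialect).
write_gmap_fixture <- function(paths, file) {
  lines <- "##gff-version 3"
  for (p in paths) {
    attrs <- sprintf("ID=%s;Name=%s", p$path_id, p$tid)
    if (!is.null(p$identity))
      attrs <- paste0(attrs, sprintf(";coverage=%s;identity=%s",
                                     p$coverage, p$identity))
    span <- c(min(p$blocks[, 1]), max(p$blocks[, 2]))
    lines <- c(lines, paste("chr1", "gmap", "mRNA", span[1], span[2],
                            ".", "+", ".", attrs, sep = "\t"))
    for (r in seq_len(nrow(p$blocks)))
      lines <- c(lines, paste("chr1", "gmap", "exon",
                              p$blocks[r, 1], p$blocks[r, 2], ".", "+", ".",
                              sprintf("Parent=%s", p$path_id), sep = "\t"))
  }
  writeLines(lines, file)
  file
}

write_fasta <- function(seqs, file) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), file)
  file
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                    collapse = "")

# ---- partition fixtures and oracles ----------------------------------------

# Mirrors scripts/make_metrics_reference.py input generation exactly.
random_partition_pair <- function(case) {
  set.seed(1000L + case)
  n <- sample(5:30, 1)
  k1 <- sample(1:n, 1)
  k2 <- sample(1:n, 1)
  items <- sprintf("it%02d", seq_len(n))
  list(u = setNames(sprintf("u%d", sample(k1, n, replace = TRUE)), items),
       v = setNames(sprintf("v%d", sample(k2, n, replace = TRUE)), items))
}

# Exhaustive pair enumeration oracle for the pair-confusion counts.
oracle_pair_counts <- function(u, v) {
  items <- intersect(names(u), names(v))
  a <- b <- cc <- d <- 0L
  for (x in seq_along(items)) {
    for (y in seq_along(items)) {
      if (x >= y) next
      su <- u[items[x]] == u[items[y]]
      sv <- v[items[x]] == v[items[y]]
      if (su && sv) a <- a + 1L
      else if (su && !sv) b <- b + 1L
      else if (!su && sv) cc <- cc + 1L
      else d <- d + 1L
    }
  }
  list(a = a, b = b, c = cc, d = d)
}

# Plain union-find over ortholog pairs.
oracle_components <- function(pairs_df) {
  nodes <- sort(unique(c(pairs_df$a, pairs_df$b)))
  parent <- setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (r in seq_len(nrow(pairs_df))) {
    ra <- find(pairs_df$a[r]); rb <- find(pairs_df$b[r])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  roots <- vapply(nodes, find, character(1))
  unname(lapply(split(nodes, roots), sort))
}

# Canonical form of a partition: sorted list of sorted member vectors.
canonical_partition <- function(x) {
  p <- partition_of(x)
  groups <- lapply(split(names(p), p), sort)
  unname(groups[order(vapply(groups, `[`, character(1), 1L))])
}

# NCBI gene_orthologs-style TSV.
write_ortholog_fixture <- function(pairs_df, file) {
  df <- data.frame(tax_id = pairs_df$tax_a, GeneID = pairs_df$a,
                   relationship = "Ortholog",
                   Other_tax_id = pairs_df$tax_b, Other_GeneID = pairs_df$b)
  names(df)[1] <- "#tax_id"
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  file
}

# The constructed fragment fixture: F in one bin, A and B spanning three.
fragment_fixture_members <- function() {
  list(A = 1:3, B = 1:3, F = 1L)
}

# The constructed 7-transcript two-locus chimera fixture: two 3-isoform loci
# plus one chimera X spanning all bins of both.
chimera_fixture_members <- function() {
  list(A1 = 1:2, A2 = 1:2, A3 = 1:2,
       B1 = 4:5, B2 = 4:5, B3 = 4:5,
       X = c(1:2, 4:5))
}
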