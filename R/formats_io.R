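# Readers/writers for the external formats the tool touches: transcript FASTA,
# GMAP-style spliced-alignment GFF3, reference annotation GFF3, NCBI-style
# ortholog pair TSV, and the cluster TSV produced by the pipeline. Everything
# is normalised into the domain types in classes.R.

#' Read transcript records from a FASTA file
#'
#' @param fasta_path path to a nucleotide FASTA of transcripts.
#' @param species_map optional path to (or data.frame of) a two-column TSV
#'   `transcript_id<TAB>species` assigning species tags. When absent, a tag is
#'   taken from the identifier prefix before the first `|`, else left empty.
#' @param source provenance of the sequences, `"de_novo"` (default) or
#'   `"gene_model"`.
#' @return data.frame with columns `transcript_id`, `species_tag`, `length`,
#'   `source`; one row per FASTA entry, `length` equal to sequence length.
#' @export
read_transcripts <- function(fasta_path, species_map = NULL,
                             source = c("de_novo", "gene_model")) {
  source <- match.arg(source)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (!length(seqs))
    stop("empty FASTA: ", fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate transcript identifier in FASTA: ",
         ids[duplicated(ids)][1])
  tags <- species_tags_for(ids, species_map)
  data.frame(transcript_id = ids, species_tag = tags,
             length = Biostrings::width(seqs), source = source,
             stringsAsFactors = FALSE)
}

#' Read a species map TSV
#'
#' @param path two-column TSV `transcript_id<TAB>species`, no header required
#'   (a `transcript_id` header line is tolerated).
#' @return data.frame with columns `transcript_id`, `species_tag`.
#' @export
read_species_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("transcript_id", "species_tag"))
  df <- df[df$transcript_id != "transcript_id", , drop = FALSE]
  df$transcript_id <- as.character(df$transcript_id)
  df$species_tag <- as.character(df$species_tag)
  df
}

species_tags_for <- function(ids, species_map) {
  if (!is.null(species_map)) {
    if (is.character(species_map)) species_map <- read_species_map(species_map)
    tags <- species_map$species_tag[match(ids, species_map$transcript_id)]
    tags[is.na(tags)] <- ""
    return(tags)
  }
  has_bar <- grepl("|", ids, fixed = TRUE)
  tags <- character(length(ids))
  tags[has_bar] <- sub("\\|.*$", "", ids[has_bar])
  tags
}

# Pre-scan GFF3 lines so a malformed coordinate (end < start) is skipped with
# a warning rather than aborting the GRanges import.
sanitise_gff3 <- function(gff3_path) {
  lines <- readLines(gff3_path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) {
    length(f) >= 8 && !is.na(suppressWarnings(as.numeric(f[4]))) &&
      !is.na(suppressWarnings(as.numeric(f[5]))) &&
      as.numeric(f[5]) >= as.numeric(f[4])
  }, logical(1))
  if (all(ok)) return(gff3_path)
  warning(sum(!ok), " malformed GFF3 feature(s) skipped (end < start or short line)")
  keep <- lines
  keep[body][!ok] <- NA
  tmp <- tempfile(fileext = ".gff3")
  writeLines(keep[!is.na(keep)], tmp)
  tmp
}

first_parent <- function(parent_col) {
  vapply(as.list(parent_col), function(p) {
    if (length(p)) as.character(p)[1] else NA_character_
  }, character(1))
}

# identity/coverage attributes arrive as percentages from GMAP (e.g. 99.2) or
# as fractions in hand-made files; normalise to fractions.
as_fraction <- function(x) {
  x <- suppressWarnings(as.numeric(x))
  ifelse(!is.na(x) & x > 1, x / 100, x)
}

#' Read GMAP-style spliced alignments from GFF3
#'
#' Accepts both the `mRNA`/`exon` hierarchy and the flat `cDNA_match`
#' representation. `identity` and `coverage` attributes (percentages or
#' fractions) are read from the path-level feature; when absent they default
#' to 1.0 with a warning so hand-made fixtures remain valid. Alignment paths
#' failing either filter are dropped (count reported via `message()`).
#'
#' @param gff3_path path to the alignment GFF3.
#' @param min_identity,min_coverage retention filters in \[0,1\]; defaults
#'   0.90 / 0.70.
#' @param genome_id label for the genome these alignments refer to; defaults
#'   to the file name without extension.
#' @return an [exon_placements()] data.frame (possibly zero rows), one
#'   placement per retained alignment path with `path_rank` preserved from
#'   input order.
#' @export
read_gmap_gff3 <- function(gff3_path, min_identity = 0.90, min_coverage = 0.70,
                           genome_id = NULL) {
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1)
  if (is.null(genome_id))
    genome_id <- tools::file_path_sans_ext(basename(gff3_path))
  gr <- rtracklayer::import(sanitise_gff3(gff3_path), format = "gff3")
  m <- S4Vectors::mcols(gr)
  type <- as.character(m$type)

  paths <- NULL
  blocks <- NULL
  if (any(type %in% c("mRNA", "transcript"))) {
    is_path <- type %in% c("mRNA", "transcript")
    pid <- as.character(m$ID[is_path])
    tid <- if (!is.null(m$Name)) as.character(m$Name[is_path]) else rep(NA, sum(is_path))
    tid <- ifelse(is.na(tid) | !nzchar(tid),
                  sub("\\.(mrna|path)[0-9]+$", "", pid), tid)
    paths <- data.frame(
      path_id = pid, transcript_id = tid,
      seq_id = as.character(GenomicRanges::seqnames(gr[is_path])),
      strand = as.character(BiocGenerics::strand(gr[is_path])),
      identity = extract_fraction_attr(m, is_path, "identity"),
      coverage = extract_fraction_attr(m, is_path, "coverage"),
      stringsAsFactors = FALSE
    )
    is_exon <- type == "exon"
    blocks <- data.frame(
      path_id = first_parent(m$Parent[is_exon]),
      start = BiocGenerics::start(gr[is_exon]),
      end = BiocGenerics::end(gr[is_exon]),
      stringsAsFactors = FALSE
    )
  } else if (any(type == "cDNA_match")) {
    is_b <- type == "cDNA_match"
    pid <- as.character(m$ID[is_b])
    tgt <- if (!is.null(m$Target)) as.character(m$Target[is_b]) else rep(NA, sum(is_b))
    tid <- ifelse(!is.na(tgt) & nzchar(tgt), sub("\\s.*$", "", tgt),
                  sub("\\.(mrna|path)[0-9]+$", "", pid))
    firsts <- !duplicated(pid)
    paths <- data.frame(
      path_id = pid[firsts], transcript_id = tid[firsts],
      seq_id = as.character(GenomicRanges::seqnames(gr[is_b]))[firsts],
      strand = as.character(BiocGenerics::strand(gr[is_b]))[firsts],
      identity = extract_fraction_attr(m, is_b, "identity")[firsts],
      coverage = extract_fraction_attr(m, is_b, "coverage")[firsts],
      stringsAsFactors = FALSE
    )
    blocks <- data.frame(
      path_id = pid,
      start = BiocGenerics::start(gr[is_b]),
      end = BiocGenerics::end(gr[is_b]),
      stringsAsFactors = FALSE
    )
  } else {
    return(empty_placements())
  }

  if (anyNA(paths$identity) || anyNA(paths$coverage))
    warning("identity/coverage attribute absent for ",
            sum(is.na(paths$identity) | is.na(paths$coverage)),
            " alignment path(s); defaulting to 1.0")
  paths$identity[is.na(paths$identity)] <- 1.0
  paths$coverage[is.na(paths$coverage)] <- 1.0

  # path_rank: order of first appearance within each transcript
  paths$path_rank <- stats::ave(seq_len(nrow(paths)), paths$transcript_id,
                                FUN = seq_along)
  keep <- paths$identity >= min_identity & paths$coverage >= min_coverage
  if (any(!keep))
    message(sum(!keep), " alignment path(s) dropped by identity/coverage filters")
  paths <- paths[keep, , drop = FALSE]
  if (!nrow(paths)) return(empty_placements())

  blocks <- blocks[blocks$path_id %in% paths$path_id, , drop = FALSE]
  i <- match(blocks$path_id, paths$path_id)
  out <- data.frame(
    transcript_id = paths$transcript_id[i],
    genome_id = genome_id,
    seq_id = paths$seq_id[i],
    start = blocks$start, end = blocks$end,
    strand = paths$strand[i],
    identity = paths$identity[i], coverage = paths$coverage[i],
    path_rank = paths$path_rank[i],
    stringsAsFactors = FALSE
  )
  exon_placements(out)
}

extract_fraction_attr <- function(m, idx, name) {
  if (name %in% names(m)) as_fraction(as.character(m[[name]][idx]))
  else rep(NA_real_, sum(idx))
}

#' Read reference gene loci from an annotation GFF3
#'
#' Parses the `gene -> mRNA -> exon` hierarchy. Each gene with at least one
#' mRNA child becomes one true-cluster group holding its isoforms; annotated
#' exons are also synthesised into exon placements (identity = coverage = 1,
#' `path_rank` = 1) for bin pre-seeding. An mRNA without a gene parent is
#' treated as its own locus with a warning.
#'
#' @param gff3_path annotation GFF3 path.
#' @param genome_id genome label; defaults to file name without extension.
#' @return list with elements `truth` (a [TrueClustering()], provenance
#'   `"gff3_loci"`) and `placements` (an [exon_placements()] table).
#' @export
read_annotation_loci <- function(gff3_path, genome_id = NULL) {
  if (is.null(genome_id))
    genome_id <- tools::file_path_sans_ext(basename(gff3_path))
  gr <- rtracklayer::import(sanitise_gff3(gff3_path), format = "gff3")
  m <- S4Vectors::mcols(gr)
  type <- as.character(m$type)
  gene_ids <- as.character(m$ID[type == "gene"])

  is_rna <- type %in% c("mRNA", "transcript")
  rna_id <- as.character(m$ID[is_rna])
  rna_parent <- first_parent(m$Parent[is_rna])
  orphan <- is.na(rna_parent) | !(rna_parent %in% gene_ids)
  if (any(orphan)) {
    warning(sum(orphan), " mRNA(s) without a gene parent; treated as own locus")
    rna_parent[orphan] <- rna_id[orphan]
  }
  groups <- split(rna_id, rna_parent)
  truth <- TrueClustering(groups, "gff3_loci")

  is_exon <- type == "exon"
  exon_parent <- first_parent(m$Parent[is_exon])
  i <- match(exon_parent, rna_id)
  keep <- !is.na(i)
  placements <- exon_placements(data.frame(
    transcript_id = rna_id[i[keep]],
    genome_id = genome_id,
    seq_id = as.character(GenomicRanges::seqnames(gr[is_exon]))[keep],
    start = BiocGenerics::start(gr[is_exon])[keep],
    end = BiocGenerics::end(gr[is_exon])[keep],
    strand = as.character(BiocGenerics::strand(gr[is_exon]))[keep],
    identity = 1.0, coverage = 1.0, path_rank = 1L,
    stringsAsFactors = FALSE
  ))
  list(truth = truth, placements = placements)
}

#' Read one-to-one ortholog pairs as true cluster groups
#'
#' Parses an NCBI `gene_orthologs`-layout TSV (columns `tax_id`, `GeneID`,
#' `relationship`, `Other_tax_id`, `Other_GeneID`) as a graph whose connected
#' components become true cluster groups. Genes whose own species passes the
#' filter but whose partner does not remain as singleton groups.
#'
#' @param tsv_path path to the pair table.
#' @param species_filter optional character vector of tax ids to keep; rows
#'   where neither side matches are skipped (count reported).
#' @return A [TrueClustering()] with provenance `"ortholog_pairs"`.
#' @export
read_ortholog_pairs <- function(tsv_path, species_filter = NULL) {
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE,
                          comment.char = "", check.names = FALSE)
  names(df) <- sub("^#", "", names(df))
  need <- c("tax_id", "GeneID", "Other_tax_id", "Other_GeneID")
  if (!all(need %in% names(df)))
    stop("ortholog table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if ("relationship" %in% names(df))
    df <- df[df$relationship == "Ortholog", , drop = FALSE]
  df$tax_id <- as.character(df$tax_id)
  df$Other_tax_id <- as.character(df$Other_tax_id)
  df$GeneID <- as.character(df$GeneID)
  df$Other_GeneID <- as.character(df$Other_GeneID)

  if (!is.null(species_filter)) {
    species_filter <- as.character(species_filter)
    a_ok <- df$tax_id %in% species_filter
    b_ok <- df$Other_tax_id %in% species_filter
    skipped <- sum(!a_ok & !b_ok)
    if (skipped) message(skipped, " ortholog pair row(s) skipped (unknown species)")
    nodes <- c(df$GeneID[a_ok], df$Other_GeneID[b_ok])
    df <- df[a_ok & b_ok, , drop = FALSE]
  } else {
    nodes <- c(df$GeneID, df$Other_GeneID)
  }
  nodes <- sort(unique(nodes))
  if (!length(nodes))
    return(TrueClustering(list(), "ortholog_pairs"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = df$GeneID, to = df$Other_GeneID, stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  comp <- igraph::components(g)
  groups <- split(nodes, comp$membership)
  # deterministic group ids ordered by smallest member
  groups <- groups[order(vapply(groups, min, character(1)))]
  names(groups) <- sprintf("OG%04d", seq_along(groups))
  TrueClustering(groups, "ortholog_pairs")
}

filtered_report_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".filtered.tsv")
}

#' Write / read a clustering as TSV
#'
#' The main file has columns `cluster_id`, `transcript_id`, `binned_flag`
#' (rows sorted by cluster then transcript); filtered transcripts go to a
#' sibling `<stem>.filtered.tsv` with columns `transcript_id`, `reason`.
#' `read_clusters()` inverts `write_clusters()` exactly.
#'
#' @param clustering a [Clustering()] object.
#' @param path output TSV path.
#' @return `write_clusters()` returns `path` invisibly; `read_clusters()`
#'   returns a [Clustering()].
#' @export
write_clusters <- function(clustering, path) {
  stopifnot(is(clustering, "Clustering"))
  cl <- clustering$clusters
  out <- data.frame(cluster_id = cl$cluster_id, transcript_id = cl$transcript_id,
                    binned_flag = cl$flag, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(clustering$filtered, filtered_report_path(path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cluster_id", "transcript_id", "binned_flag") %in% names(df)))
    stop("cluster TSV missing required columns")
  if (nrow(df) && !all(df$binned_flag %in% CLUSTER_FLAGS))
    stop("unknown binned_flag value: ",
         paste(setdiff(unique(df$binned_flag), CLUSTER_FLAGS), collapse = ", "))
  fpath <- filtered_report_path(path)
  filtered <- if (file.exists(fpath)) utils::read.delim(fpath, stringsAsFactors = FALSE)
              else empty_filtered_df()
  Clustering(data.frame(cluster_id = df$cluster_id,
                        transcript_id = df$transcript_id,
                        flag = df$binned_flag, stringsAsFactors = FALSE),
             filtered)
}
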