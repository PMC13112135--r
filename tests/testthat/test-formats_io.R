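test_that("read_transcripts reads records, species tags and rejects duplicates", {
  fa <- write_fasta(c(t1 = strrep("A", 300), t2 = strrep("C", 150)),
                    tempfile(fileext = ".fa"))
  rec <- read_transcripts(fa)
  expect_equal(rec$transcript_id, c("t1", "t2"))
  expect_equal(rec$length, c(300L, 150L))
  expect_equal(rec$species_tag, c("", ""))

  # identifier-prefix convention and sidecar map
  fa2 <- write_fasta(c("sp1|x" = "ACGT", "sp2|y" = "ACGT"),
                     tempfile(fileext = ".fa"))
  expect_equal(read_transcripts(fa2)$species_tag, c("sp1", "sp2"))
  map <- data.frame(transcript_id = "sp1|x", species_tag = "other")
  expect_equal(read_transcripts(fa2, species_map = map)$species_tag,
               c("other", ""))

  dup <- tempfile(fileext = ".fa")
  writeLines(c(">d1", "ACGT", ">d1", "GGGG"), dup)
  expect_error(read_transcripts(dup), "d1")
  empty <- tempfile(fileext = ".fa")
  writeLines(character(), empty)
  expect_error(read_transcripts(empty))
})

test_that("read_gmap_gff3 parses paths, applies filters, and handles dialects", {
  f <- write_gmap_fixture(list(
    list(tid = "tA", path_id = "tA.mrna1", identity = "99.0", coverage = "95.0",
         blocks = cbind(c(100, 300, 700), c(200, 450, 820))),
    list(tid = "tB", path_id = "tB.mrna1", identity = "85.0", coverage = "95.0",
         blocks = cbind(1000, 1100)),
    list(tid = "tA", path_id = "tA.mrna2", identity = "99.0", coverage = "60.0",
         blocks = cbind(5000, 5100))
  ), tempfile(fileext = ".gff3"))

  expect_message(pl <- read_gmap_gff3(f, 0.90, 0.70, genome_id = "G1"),
                 "2 alignment path")
  expect_equal(unique(pl$transcript_id), "tA")        # tB fails identity,
  expect_equal(unique(pl$path_rank), 1L)              # tA path 2 fails coverage
  expect_equal(pl$start, c(100, 300, 700))            # 3 blocks in order
  expect_equal(pl$identity, rep(0.99, 3))

  # everything retained when filters are slack; path_rank preserved
  pl2 <- read_gmap_gff3(f, 0, 0, genome_id = "G1")
  expect_setequal(unique(pl2$transcript_id), c("tA", "tB"))
  expect_equal(sort(unique(pl2$path_rank[pl2$transcript_id == "tA"])), c(1L, 2L))

  # missing identity/coverage attributes default to 1.0 with a warning
  f2 <- write_gmap_fixture(list(
    list(tid = "tC", path_id = "tC.mrna1", blocks = cbind(10, 90))),
    tempfile(fileext = ".gff3"))
  expect_warning(pl3 <- read_gmap_gff3(f2), "defaulting to 1.0")
  expect_equal(pl3$identity, 1.0)

  # cDNA_match dialect
  f3 <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tgmap\tcDNA_match\t100\t200\t.\t+\t.\tID=m1;Target=tD 1 101;identity=98.5;coverage=90.0",
    "chr1\tgmap\tcDNA_match\t400\t500\t.\t+\t.\tID=m1;Target=tD 102 202;identity=98.5;coverage=90.0"),
    f3)
  pl4 <- read_gmap_gff3(f3)
  expect_equal(pl4$transcript_id, c("tD", "tD"))
  expect_equal(pl4$start, c(100, 400))

  # malformed coordinate (end < start) is skipped with a warning
  f4 <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tgmap\tmRNA\t100\t200\t.\t+\t.\tID=tE.mrna1;Name=tE;identity=99;coverage=99",
    "chr1\tgmap\texon\t200\t100\t.\t+\t.\tParent=tE.mrna1",
    "chr1\tgmap\texon\t150\t200\t.\t+\t.\tParent=tE.mrna1"), f4)
  expect_warning(pl5 <- read_gmap_gff3(f4), "malformed")
  expect_equal(nrow(pl5), 1L)

  # zero retained paths is an empty table, not an error
  expect_equal(nrow(suppressMessages(read_gmap_gff3(f, 1, 1))), 0L)
})

test_that("read_annotation_loci groups isoforms under genes and synthesises placements", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tann\tgene\t100\t900\t.\t+\t.\tID=g1",
    "chr1\tann\tmRNA\t100\t900\t.\t+\t.\tID=m1a;Parent=g1",
    "chr1\tann\texon\t100\t200\t.\t+\t.\tParent=m1a",
    "chr1\tann\texon\t500\t900\t.\t+\t.\tParent=m1a",
    "chr1\tann\tmRNA\t100\t900\t.\t+\t.\tID=m1b;Parent=g1",
    "chr1\tann\texon\t100\t200\t.\t+\t.\tParent=m1b",
    "chr1\tann\tgene\t2000\t3000\t.\t-\t.\tID=g2",
    "chr1\tann\tmRNA\t2000\t3000\t.\t-\t.\tID=m2a;Parent=g2",
    "chr1\tann\texon\t2000\t3000\t.\t-\t.\tParent=m2a",
    "chr1\tann\tmRNA\t2000\t3000\t.\t-\t.\tID=m2b;Parent=g2",
    "chr1\tann\texon\t2000\t2500\t.\t-\t.\tParent=m2b"), f)
  res <- read_annotation_loci(f, genome_id = "G1")
  expect_equal(length(res$truth$groups), 2L)
  expect_equal(res$truth$groups$g1, c("m1a", "m1b"))
  expect_equal(res$truth$groups$g2, c("m2a", "m2b"))
  expect_true(all(res$placements$identity == 1))
  expect_true(all(res$placements$path_rank == 1L))
  expect_equal(nrow(res$placements), 5L)

  # orphan mRNA becomes its own locus, with a warning
  f2 <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tann\tmRNA\t10\t90\t.\t+\t.\tID=solo",
    "chr1\tann\texon\t10\t90\t.\t+\t.\tParent=solo"), f2)
  expect_warning(res2 <- read_annotation_loci(f2), "own locus")
  expect_equal(names(res2$truth$groups), "solo")
})

test_that("read_ortholog_pairs builds connected components and matches union-find", {
  # transitive closure: (a,b), (b,c) one group
  p1 <- data.frame(a = c("1", "2"), b = c("2", "3"),
                   tax_a = "9606", tax_b = "10090")
  f <- write_ortholog_fixture(p1, tempfile(fileext = ".tsv"))
  tc <- read_ortholog_pairs(f)
  expect_equal(length(tc$groups), 1L)
  expect_equal(tc$groups[[1]], c("1", "2", "3"))
  expect_equal(tc$provenance, "ortholog_pairs")

  # random pair fixtures equal brute-force union-find components
  for (case in 1:5) {
    set.seed(3000 + case)
    n <- sample(10:40, 1)
    pairs <- data.frame(a = as.character(sample(n, 25, replace = TRUE)),
                        b = as.character(sample(n, 25, replace = TRUE)),
                        tax_a = "1", tax_b = "2")
    pairs <- pairs[pairs$a != pairs$b, ]
    ff <- write_ortholog_fixture(pairs, tempfile(fileext = ".tsv"))
    got <- canonical_partition(read_ortholog_pairs(ff))
    want <- oracle_components(pairs)
    want <- want[order(vapply(want, `[`, character(1), 1L))]
    expect_equal(got, want)
  }

  # species filter: foreign rows skipped with count, half-known rows keep the
  # known gene as a singleton
  p2 <- data.frame(a = c("10", "20", "30"), b = c("11", "21", "31"),
                   tax_a = c("9606", "9606", "7227"),
                   tax_b = c("10090", "7227", "7227"))
  f2 <- write_ortholog_fixture(p2, tempfile(fileext = ".tsv"))
  expect_message(tc2 <- read_ortholog_pairs(f2, species_filter = c("9606", "10090")),
                 "1 ortholog pair row")
  expect_equal(canonical_partition(tc2), list(c("10", "11"), "20"))
})

test_that("cluster TSV round-trips and rejects unknown flags", {
  cl <- Clustering(
    data.frame(cluster_id = rep(sprintf("c%d", 1:7), each = 2),
               transcript_id = sprintf("t%02d", 1:14), flag = "binned"),
    data.frame(transcript_id = c("bad1", "bad2"),
               reason = c("fragment", "chimera")))
  path <- tempfile(fileext = ".tsv")
  write_clusters(cl, path)
  back <- read_clusters(path)
  expect_equal(back$clusters, cl$clusters)
  expect_equal(back$filtered, cl$filtered)
  expect_equal(n_clusters(back), 7L)

  # empty clustering: header-only files
  p2 <- tempfile(fileext = ".tsv")
  write_clusters(Clustering(), p2)
  expect_equal(length(readLines(p2)), 1L)
  expect_equal(n_clusters(read_clusters(p2)), 0L)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("cluster_id\ttranscript_id\tbinned_flag", "c1\tt1\tmaybe"), bad)
  expect_error(read_clusters(bad), "unknown binned_flag")
})

test_that("Clustering invariants are enforced", {
  expect_error(Clustering(data.frame(cluster_id = c("c1", "c2"),
                                     transcript_id = "t1", flag = "binned")),
               "more than one cluster")
  expect_error(Clustering(data.frame(cluster_id = "c1", transcript_id = "t1",
                                     flag = "binned"),
                          data.frame(transcript_id = "t1", reason = "fragment")),
               "both clustered and filtered")
  expect_error(TrueClustering(list(g1 = c("a", "b"), g2 = "a")), "more than one")
})
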