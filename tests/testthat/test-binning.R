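test_that("de novo seeding merges overlapping blocks into shared bins", {
  pl <- rbind_placements(
    make_placements("t1", cbind(100, 200)),
    make_placements("t2", cbind(150, 250)))
  idx <- seed_bins_denovo(pl)
  expect_equal(nrow(idx$bins), 1L)
  expect_equal(idx$bins$start, 100L)
  expect_equal(idx$bins$end, 250L)
  expect_setequal(idx$membership$transcript_id, c("t1", "t2"))

  # disjoint blocks found separate bins
  idx2 <- seed_bins_denovo(rbind_placements(
    make_placements("t1", cbind(100, 200)),
    make_placements("t2", cbind(300, 400))))
  expect_equal(nrow(idx2$bins), 2L)

  # chained extension: three blocks pairwise-linked via the middle one merge
  idx3 <- seed_bins_denovo(rbind_placements(
    make_placements("a", cbind(100, 200)),
    make_placements("b", cbind(190, 310)),
    make_placements("c", cbind(300, 400))))
  expect_equal(nrow(idx3$bins), 1L)
  expect_equal(c(idx3$bins$start, idx3$bins$end), c(100L, 400L))
})

test_that("seeding is order-independent and matches a brute-force scan", {
  for (case in 1:10) {
    set.seed(4000 + case)
    n <- sample(5:25, 1)
    pl <- do.call(rbind, lapply(seq_len(n), function(i) {
      s <- sample(10000, 1)
      make_placements(sprintf("t%02d", i), cbind(s, s + sample(50:400, 1)))
    }))
    idx <- seed_bins_denovo(pl)
    perm <- pl[sample(nrow(pl)), , drop = FALSE]
    idx_perm <- seed_bins_denovo(perm)
    expect_equal(idx$bins, idx_perm$bins)
    expect_equal(idx$membership, idx_perm$membership)

    # brute-force membership oracle: transcript in bin iff some block overlaps
    for (tid in unique(pl$transcript_id)) {
      blocks <- pl[pl$transcript_id == tid, ]
      want <- idx$bins$bin_id[vapply(seq_len(nrow(idx$bins)), function(b)
        any(blocks$start <= idx$bins$end[b] & blocks$end >= idx$bins$start[b]),
        logical(1))]
      expect_equal(bins_of(idx, tid), sort(want))
    }
    # no two de novo bins on one sequence overlap
    b <- idx$bins[order(idx$bins$start), ]
    if (nrow(b) > 1)
      expect_true(all(b$start[-1] > b$end[-nrow(b)]))
    # incidence accounting
    expect_equal(nrow(idx$membership),
                 sum(lengths(lapply(unique(pl$transcript_id),
                                    function(tid) bins_of(idx, tid)))))
  }
})

test_that("pre-seeded bins are frozen and novel loci fall back to de novo", {
  ann <- make_placements("m1", cbind(100, 200))
  tx <- rbind_placements(
    make_placements("t1", cbind(190, 260)),   # joins frozen bin, no extension
    make_placements("t2", cbind(5000, 5100))) # novel locus -> de novo bin
  idx <- seed_bins_preseeded(ann, tx)
  pre <- idx$bins[idx$bins$origin == "preseeded", ]
  expect_equal(c(pre$start, pre$end), c(100L, 200L))   # coordinates unchanged
  expect_equal(bins_of(idx, "t1"), pre$bin_id)
  de <- idx$bins[idx$bins$origin == "denovo", ]
  expect_equal(nrow(de), 1L)
  expect_equal(bins_of(idx, "t2"), de$bin_id)

  # overlapping annotated isoform exons merge into one frozen bin
  ann2 <- rbind_placements(
    make_placements("m1", cbind(100, 200)),
    make_placements("m2", cbind(150, 220)))
  idx2 <- seed_bins_preseeded(ann2, make_placements("t1", cbind(160, 180)))
  expect_equal(nrow(idx2$bins), 1L)
  expect_equal(c(idx2$bins$start, idx2$bins$end), c(100L, 220L))

  # frozen bins that collect no transcript are dropped
  ann3 <- rbind_placements(
    make_placements("m1", cbind(100, 200)),
    make_placements("m2", cbind(1000, 1100)))
  idx3 <- seed_bins_preseeded(ann3, make_placements("t1", cbind(120, 160)))
  expect_equal(nrow(idx3$bins), 1L)
})

test_that("bins_of is the exact inverse and unbinned transcripts are found", {
  members <- list(Seq1 = 1:3, Seq2 = 1:3, other = 5L)
  idx <- bin_index_from_members(members)
  expect_equal(length(bins_of(idx, "Seq1")), 3L)
  expect_equal(bins_of(idx, "missing"), integer())
  expect_equal(unbinned_transcripts(idx, c("Seq1", "Seq2", "other")), character())
  expect_equal(unbinned_transcripts(idx, c("Seq1", "cont1", "cont2")),
               c("cont1", "cont2"))
})

test_that("multi-path, strand and min_overlap options behave as documented", {
  # default keeps only path_rank 1; --multipath keeps all
  pl <- rbind_placements(
    make_placements("t1", cbind(100, 200), path_rank = 1L),
    make_placements("t1", cbind(9000, 9100), path_rank = 2L))
  expect_equal(nrow(seed_bins_denovo(pl)$bins), 1L)
  expect_equal(nrow(seed_bins_denovo(pl, multipath = TRUE)$bins), 2L)

  # strandless by default: opposite strands share a bin space
  pl2 <- rbind_placements(
    make_placements("t1", cbind(100, 200), strand = "+"),
    make_placements("t2", cbind(150, 250), strand = "-"))
  expect_equal(nrow(seed_bins_denovo(pl2)$bins), 1L)
  expect_equal(nrow(seed_bins_denovo(pl2, stranded = TRUE)$bins), 2L)

  # overlap below min_overlap does not join blocks
  pl3 <- rbind_placements(
    make_placements("t1", cbind(100, 200)),
    make_placements("t2", cbind(196, 300)))  # 5 bp overlap
  expect_equal(nrow(seed_bins_denovo(pl3, min_overlap = 10L)$bins), 2L)
  expect_equal(nrow(seed_bins_denovo(pl3, min_overlap = 5L)$bins), 1L)
})
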