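test_that("pair confusion counts match exhaustive pair enumeration", {
  u <- c(a = "1", b = "1", c = "2", d = "2")
  v <- c(a = "x", b = "x", c = "x", d = "x")
  pc <- pair_confusion(u, v)
  expect_equal(pc[c("a", "b", "c", "d")], list(a = 2, b = 0, c = 4, d = 0))
  expect_equal(pc$a + pc$b + pc$c + pc$d, choose(4, 2))

  # identical partitions: no disagreeing pairs
  pc2 <- pair_confusion(u, u)
  expect_equal(pc2$b + pc2$c, 0)

  # random partitions vs brute force, n <= 12
  for (case in 1:10) {
    set.seed(5000 + case)
    n <- sample(4:12, 1)
    items <- sprintf("i%02d", 1:n)
    uu <- setNames(as.character(sample(3, n, replace = TRUE)), items)
    vv <- setNames(as.character(sample(4, n, replace = TRUE)), items)
    expect_equal(pair_confusion(uu, vv)[c("a", "b", "c", "d")],
                 lapply(oracle_pair_counts(uu, vv), as.numeric))
  }

  expect_error(pair_confusion(c(a = "1"), c(a = "x")), "at least 2")
  # evaluation restricted to common items
  pc3 <- pair_confusion(c(a = "1", b = "1", zz = "9"), v)
  expect_equal(pc3$n, 2)
  expect_equal(pc3$dropped_test, 1)
  expect_equal(pc3$dropped_truth, 2)
})

test_that("metrics match the hand-computed two-vs-one-cluster case", {
  u <- c(a = "1", b = "1", c = "2", d = "2")
  v <- c(a = "x", b = "x", c = "x", d = "x")
  m <- compute_metrics(u, v)
  expect_equal(m$ri, 1 / 3)
  expect_equal(m$ari, 0)
  expect_equal(m$nmi, 0)
  expect_equal(m$ami, 0)

  ident <- compute_metrics(u, u)
  expect_equal(c(ident$ri, ident$ari, ident$nmi, ident$ami), rep(1, 4))

  # degenerate one-cluster-vs-one-cluster
  one <- compute_metrics(c(a = "1", b = "1"), c(a = "x", b = "x"))
  expect_equal(c(one$ri, one$ari, one$nmi, one$ami), rep(1, 4))
})

test_that("metrics agree with the frozen reference implementation to 1e-9", {
  ref <- read.delim(test_path("metrics_reference.tsv"))
  expect_equal(nrow(ref), 50L)
  for (i in seq_len(nrow(ref))) {
    p <- random_partition_pair(ref$case[i])
    expect_equal(length(p$u), ref$n[i])
    m <- compute_metrics(p$u, p$v)
    expect_equal(m$ri, ref$ri[i], tolerance = 1e-9)
    expect_equal(m$ari, ref$ari[i], tolerance = 1e-9)
    expect_equal(m$nmi, ref$nmi[i], tolerance = 1e-9)
    expect_equal(m$ami, ref$ami[i], tolerance = 1e-9)
  }
  # negative adjusted values are reported as computed, not clamped
  expect_true(any(ref$ari < 0))
})

test_that("ARI is chance-adjusted: random shuffles average ~0", {
  set.seed(99)
  n <- 60
  items <- sprintf("i%02d", 1:n)
  truth <- setNames(rep(sprintf("g%d", 1:12), each = 5), items)
  aris <- vapply(1:200, function(r) {
    test <- setNames(sample(truth), items)
    compute_metrics(test, truth)$ari
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("subset_by_species intersects clusters and drops empty ones", {
  cl <- clustering_from_list(list(c1 = c("a_sp1", "b_sp2"),
                                  c2 = c("c_sp2", "d_sp2"),
                                  c3 = c("e_sp1")),
                             flag = "binned")
  map <- data.frame(
    transcript_id = c("a_sp1", "b_sp2", "c_sp2", "d_sp2", "e_sp1"),
    species_tag = c("sp1", "sp2", "sp2", "sp2", "sp1"))
  s1 <- subset_by_species(cl, map, "sp1")
  expect_equal(canonical_partition(s1), list("a_sp1", "e_sp1"))
  s2 <- subset_by_species(cl, map, "sp2")
  expect_equal(canonical_partition(s2), list("b_sp2", c("c_sp2", "d_sp2")))
  expect_error(subset_by_species(cl, map, "sp9"), "sp1, sp2")

  # per-species subsets partition each species' transcript set
  for (tag in unique(map$species_tag)) {
    sub <- subset_by_species(cl, map, tag)
    expect_setequal(sub$clusters$transcript_id,
                    map$transcript_id[map$species_tag == tag])
  }
})

test_that("evaluation reports round-trip as TSV", {
  u <- c(a = "1", b = "1", c = "2", d = "2")
  m <- list(self = compute_metrics(u, u),
            collapsed = compute_metrics(u, c(a = "x", b = "x", c = "x", d = "x")))
  p <- tempfile(fileext = ".tsv")
  evaluation_report(m, p)
  back <- read.delim(p)
  expect_equal(back$label, c("self", "collapsed"))
  expect_equal(back$ri, c(1, 1 / 3))
  expect_equal(names(back),
               c("label", "ri", "ari", "nmi", "ami", "n_test_clusters",
                 "n_true_groups", "n_items_compared"))
  p2 <- tempfile(fileext = ".tsv")
  evaluation_report(list(), p2)
  expect_equal(length(readLines(p2)), 1L)
})

test_that("merging true-cluster-concordant test clusters never decreases `a`", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 20
    items <- sprintf("i%02d", 1:n)
    truth <- setNames(rep(sprintf("g%d", 1:4), each = 5), items)
    # refinement of the truth: split each true group into two test clusters
    test <- paste0(truth, ifelse(seq_len(n) %% 2 == 0, "x", "y"))
    names(test) <- items
    a_split <- pair_confusion(test, truth)$a
    merged <- test
    g <- sample(sprintf("g%d", 1:4), 1)
    merged[truth == g] <- g     # merge the two concordant halves
    expect_gte(pair_confusion(merged, truth)$a, a_split)
  }
})
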