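#!/usr/bin/env Rscript
# Emits scratch/partitions.tsv: the seeded random partition pairs consumed by
# scripts/make_metrics_reference.py to freeze the metric reference values.
# Must mirror random_partition_pair() in tests/testthat/helper-oracles.R.

random_partition_pair <- function(case) {
  set.seed(1000L + case)
  n <- sample(5:30, 1)
  k1 <- sample(1:n, 1)
  k2 <- sample(1:n, 1)
  items <- sprintf("it%02d", seq_len(n))
  list(u = setNames(sprintf("u%d", sample(k1, n, replace = TRUE)), items),
       v = setNames(sprintf("v%d", sample(k2, n, replace = TRUE)), items))
}

rows <- lapply(1:50, function(case) {
  p <- random_partition_pair(case)
  data.frame(case = case, item = names(p$u), u = unname(p$u), v = unname(p$v))
})
dir.create("scratch", showWarnings = FALSE)
write.table(do.call(rbind, rows), "scratch/partitions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
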