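#!/usr/bin/env python
"""Freeze reference partition metrics for the R test suite.

Reads scratch/partitions.tsv (seeded random partition pairs emitted by the
same generator the testthat helper uses) and writes
tests/testthat/metrics_reference.tsv with RI/ARI/NMI/AMI computed by
scikit-learn (arithmetic-mean normalisation, natural logs). Run once at build
time; the test suite only consumes the frozen TSV.
"""
import pandas as pd
from sklearn.metrics import (
    adjusted_mutual_info_score,
    adjusted_rand_score,
    normalized_mutual_info_score,
    pair_confusion_matrix,
)

df = pd.read_csv("scratch/partitions.tsv", sep="\t")
rows = []
for case, grp in df.groupby("case"):
    u, v = grp["u"].tolist(), grp["v"].tolist()
    (tn, fp), (fn, tp) = pair_confusion_matrix(u, v)
    ri = (tp + tn) / (tp + tn + fp + fn)
    rows.append({
        "case": case,
        "n": len(u),
        "ri": ri,
        "ari": adjusted_rand_score(u, v),
        "nmi": normalized_mutual_info_score(u, v, average_method="arithmetic"),
        "ami": adjusted_mutual_info_score(u, v, average_method="arithmetic"),
    })
out = pd.DataFrame(rows)
out.to_csv("tests/testthat/metrics_reference.tsv", sep="\t", index=False,
           float_format="%.12f")
print(out.head())
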