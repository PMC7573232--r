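#!/usr/bin/env Rscript
# Step 1 — generate the study fixture: a Help vs No-Help reference count set
# (2,000 genes, 3 vs 3, 10% DE at |log2FC| = 2, NB dispersion 0.1, seed 17),
# a 5-level centroid-mixture query panel, its renamed "species B" copy with
# a gene-id mapping table, and a GMT of the true up/down DE sets.

suppressPackageStartupMessages(library(nohelpscore))
options(nohelpscore.verbose = TRUE)

paths <- make_default_fixture("results/fixtures")
counts <- read_counts(paths$counts)
truth <- read.delim(paths$truth)

cat(sprintf("Reference: %d genes x %d samples; %d genes truly DE (%d up, %d down in NoHelp).\n",
            nrow(counts), ncol(counts), nrow(truth),
            sum(truth$direction == "up_in_NoHelp"),
            sum(truth$direction == "down_in_NoHelp")))
cat(sprintf("Query panel: %d samples across mixture weights 0, 0.25, 0.5, 0.75, 1.\n",
            ncol(read_expression(paths$query))))
cat("Fixture written under results/fixtures/.\n")
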