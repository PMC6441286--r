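#!/usr/bin/env Rscript
# Fetches the published cancer-mutation example data (NOT vendored here) and
# converts it to this package's TSV dialect, enabling the published-analysis
# reproduction:
#
#   overall: cancer types vs genes 0.34; vs annotation groups 0.18
#   singular: KIRC-VHL 0.47, COAD.READ-APC 0.37; COAD.READ-Wnt 0.30
#
# The matrix (mutated genes x 12 cancer types, 3281 tumors, derived from the
# Kandoth et al. pan-cancer set) ships with the original implementation at
#   https://github.com/mpiwowar/MEUSassociation.git
# as the data objects `cancer_mutations` (matrix) and
# `cancer_mutations_gene_groups` (factor vector aligned with the gene axis).
#
# Orientation caveat: the original usage examples pass the gene-group vector
# as row_groups in one call and col_groups in another for the same matrix, so
# the matrix orientation is ambiguous. This script therefore writes both the
# documented orientation and its transpose; compare
#   zassoc z cancer_mutations.tsv            (rows predicted from columns)
#   zassoc z cancer_mutations.tsv --direction cols
# against the printed 0.34 to fix the orientation empirically, and record
# which one reproduces it.
#
# Requires network access; run from the repository root.

repo <- "https://github.com/mpiwowar/MEUSassociation.git"
dest <- file.path("scratch", "MEUSassociation")
if (!dir.exists(dest)) {
  status <- system2("git", c("clone", "--depth", "1", repo, dest))
  if (status != 0) stop("clone failed; network access is required")
}

load(file.path(dest, "data", "cancer_mutations.rda"))
load(file.path(dest, "data", "cancer_mutations_gene_groups.rda"))

library(zassoc)
tab <- as_contingency_table(cancer_mutations)
dir.create("scratch/cancer", recursive = TRUE, showWarnings = FALSE)
write_table_file(tab, "scratch/cancer/cancer_mutations.tsv")
write_table_file(transpose(tab), "scratch/cancer/cancer_mutations_t.tsv")
writeLines(paste(rownames(tab), as.character(cancer_mutations_gene_groups),
                 sep = "\t"),
           "scratch/cancer/gene_groups.tsv")
message("wrote scratch/cancer/{cancer_mutations,cancer_mutations_t,gene_groups}.tsv")
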