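#!/usr/bin/env Rscript
# Stage 5 — differential expression: reads-per-million normalization, zero
# substitution (0.01), low-expression exclusion (NE < 1), log2 fold change
# and the exact two-library statistic on every between-group sample pair,
# with consensus calls per contrast (young vs adult, male vs female).

suppressPackageStartupMessages(library(mirprofiler))

simdir <- "results/sim"
discdir <- "results/discover"
outdir <- "results/diffexpr"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- read_config(file.path(simdir, "pipeline.cfg"))
samples <- read_report(file.path(simdir, "samples.tsv"))
emt <- read_report(file.path(discdir, "expression_matrix.tsv"))
counts <- as.matrix(emt[, samples$sample])
rownames(counts) <- emt$mirna
tot <- read_report(file.path(discdir, "library_totals.tsv"))
em <- build_expression_matrix(counts,
                              totals = stats::setNames(tot$total, tot$sample))

run_contrast <- function(groups, contrast, label) {
    de <- call_differential(em, groups, contrast, cfg)
    write_report(de$pairwise, file.path(outdir, paste0(label, "_pairwise.tsv")))
    write_report(de$consensus, file.path(outdir, paste0(label, "_consensus.tsv")))
    cons <- de$consensus
    message(sprintf("%s: %d consensus-up, %d consensus-down (of %d miRNAs)",
                    label,
                    sum(cons$consensus & cons$direction == "up"),
                    sum(cons$consensus & cons$direction == "down"),
                    nrow(cons)))
    for (m in cons$mirna[cons$consensus]) {
        sub <- de$pairwise[de$pairwise$mirna == m, ]
        message(sprintf("  %s: mean log2FC %.2f, max p %.2e", m,
                        mean(sub$log2fc), max(sub$p_two_sided)))
    }
    de
}

de_age <- run_contrast(samples[, c("sample", "group")], c("young", "adult"),
                       "young_vs_adult")
groups_sex <- data.frame(sample = samples$sample, group = samples$sex)
de_sex <- run_contrast(groups_sex, c("male", "female"), "male_vs_female")
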