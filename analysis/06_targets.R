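#!/usr/bin/env Rscript
# Stage 6 — targets: transfer donor-species 3'UTRs onto the genome near
# annotated gene 3' ends (<= 2 mismatches, >= 80% coverage), scan them with
# the seed-anchored complementarity scorer for every miRNA, tally predicted
# target genes by pathway, and compare target-gene expression between
# groups on a simulated FPKM table.

suppressPackageStartupMessages(library(mirprofiler))

simdir <- "results/sim"
discdir <- "results/discover"
dedir <- "results/diffexpr"
outdir <- "results/targets"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

seed <- 42L
cfg <- read_config(file.path(simdir, "pipeline.cfg"))
genome <- read_fasta(file.path(simdir, "genome.fa"))[[1]]
genes <- read_report(file.path(simdir, "genes.tsv"))

# donor UTRs diverge 0-2 substitutions from the genome; a planted target
# site (exact complement of one mature) makes the scan informative
t0 <- build_truth(seed = seed)
planted <- names(sort(t0$base_prop))[2]
truth <- build_truth(seed = seed, catalog_fraction = 0.5,
                     fold_change = stats::setNames(8, planted))
donors <- simulate_utr_donors(truth,
                              mismatches = rep_len(0:2, nrow(genes)),
                              seed = seed + 1L)
tr <- transfer_utrs(donors, genome, gene_ends(truth),
                    max_mismatch = cfg$utr_max_mismatch,
                    min_coverage = cfg$utr_min_coverage,
                    proximity = cfg$utr_proximity)
write_report(tr, file.path(outdir, "transferred_utrs.tsv"))
write_fasta(stats::setNames(tr$seq, paste0(tr$gene, "_utr")),
            file.path(outdir, "utrs.fa"))
message(nrow(tr), " of ", nrow(donors), " donor UTRs transferred")

# synthetic unigene UTRs: one per gene, each carrying the exact complement
# of one mature miRNA (a planted positive-control binding site)
mature <- read_fasta(file.path(simdir, "mature.fa"))
set.seed(seed + 2L)
flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
uni <- data.frame(
    gene = genes$gene,
    seq = vapply(seq_len(nrow(genes)), function(i) {
        m <- mature[[(i - 1L) %% length(mature) + 1L]]
        paste0(flank(25), dna_revcomp(m), flank(25))
    }, character(1)), stringsAsFactors = FALSE)
utrs <- merge_utrs(tr, uni)

mirna_ids <- sub("^aml-", "", names(mature))
sites <- do.call(rbind, lapply(seq_along(mature), function(i) {
    predict_targets(mature[[i]], utrs, score_min = cfg$target_score_min,
                    mirna_id = mirna_ids[i])
}))
write_report(sites, file.path(outdir, "target_sites.tsv"))
message(nrow(sites), " target sites over ", length(unique(sites$gene)),
        " genes (deduplicated per miRNA: ",
        nrow(unique(sites[, c("mirna", "gene")])), " miRNA-gene links)")

# pathway tallies: all miRNAs, and the consensus-up subset
pmap <- data.frame(gene = genes$gene,
                   pathway = rep_len(c("Ras signaling", "PI3K-Akt signaling",
                                       "MAPK signaling"), nrow(genes)))
write_report(pmap, file.path(outdir, "pathway_map.tsv"))
tal_all <- tally_pathways(sites, pmap)
write_report(tal_all, file.path(outdir, "pathways_all.tsv"))
cons <- read_report(file.path(dedir, "young_vs_adult_consensus.tsv"))
up <- cons$mirna[cons$consensus & cons$direction == "up"]
tal_up <- tally_pathways(sites, pmap, mirnas = up)
write_report(tal_up, file.path(outdir, "pathways_young_up.tsv"))
message("pathway tallies written (all miRNAs and the ", length(up),
        " young-up miRNAs)")

# expression trends of the young-up targets on a simulated FPKM table
samples <- read_report(file.path(simdir, "samples.tsv"))
set.seed(seed + 3L)
fpkm <- matrix(stats::rlnorm(nrow(genes) * nrow(samples), 3, 0.3),
               nrow(genes), nrow(samples),
               dimnames = list(genes$gene, samples$sample))
up_targets <- unique(sites$gene[sites$mirna %in% up])
# repression by a young-up miRNA: its targets run lower in the young group
fpkm[up_targets, samples$sample[samples$group == "young"]] <-
    fpkm[up_targets, samples$sample[samples$group == "young"]] * 0.5
write_report(cbind(gene = rownames(fpkm), as.data.frame(fpkm)),
             file.path(outdir, "fpkm.tsv"))
tre <- compare_target_expression(fpkm, up_targets,
                                 samples[, c("sample", "group")],
                                 threshold = cfg$trend_threshold)
write_report(tre, file.path(outdir, "young_up_target_trends.tsv"))
message(sum(tre$trend == "higher_in_B", na.rm = TRUE), " of ", nrow(tre),
        " young-up target genes trend lower in the young group")
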