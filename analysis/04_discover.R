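#!/usr/bin/env Rscript
# Stage 4 — quantify conserved miRNAs against the hairpin catalog, map the
# remaining candidate tags to the genome, and discover novel hairpins
# (fold, signature score, dinucleotide-shuffle structure test,
# signal-to-noise against shuffled genomes). Writes the candidate report,
# the novel precursor FASTA with dot-bracket lines, and the expression
# matrix for the differential stage.

suppressPackageStartupMessages(library(mirprofiler))

simdir <- "results/sim"
anndir <- "results/annotate"
cleandir <- "results/clean"
outdir <- "results/discover"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

seed <- 42L
cfg <- read_config(file.path(simdir, "pipeline.cfg"))
samples <- read_report(file.path(simdir, "samples.tsv"))
genome <- read_fasta(file.path(simdir, "genome.fa"))[[1]]

# per-sample candidate tag counts, merged over samples
per_sample <- lapply(samples$sample, function(nm) {
    ann <- read_report(file.path(anndir, paste0(nm, "_annotated.tsv")))
    cand <- ann[ann$category == "candidate", c("insert", "count")]
    names(cand)[2] <- nm
    cand
})
cand <- Reduce(function(a, b) merge(a, b, by = "insert", all = TRUE),
               per_sample)
cand[is.na(cand)] <- 0L
cand$count <- rowSums(cand[, samples$sample, drop = FALSE])

# conserved quantification: catalog = precursor + mature reference files
pre <- read_fasta(file.path(simdir, "precursors.fa"))
mat <- read_fasta(file.path(simdir, "mature.fa"))
truth_pre <- read_report(file.path(simdir, "truth_precursors.tsv"))
catalog <- data.frame(id = truth_pre$id,
                      precursor_seq = unname(pre),
                      mature_rel_start = truth_pre$mature_start -
                          truth_pre$start,
                      mature_len = truth_pre$mature_end -
                          truth_pre$mature_start,
                      stringsAsFactors = FALSE)
catalog <- catalog[truth_pre$in_catalog, ]
qc <- quantify_conserved(cand[, c("insert", samples$sample)], catalog,
                         tolerance = cfg$conserved_tolerance)
write_report(cbind(id = rownames(qc$counts), as.data.frame(qc$counts)),
             file.path(outdir, "conserved_counts.tsv"))
message("conserved miRNAs with reads: ", sum(rowSums(qc$counts) > 0),
        " of ", nrow(catalog), " in the catalog")

# novel discovery on the rest
novel_cand <- cand[!cand$insert %in% qc$assignments$insert, , drop = FALSE]
excl <- truth_pre[truth_pre$in_catalog, c("start", "end")]
nov <- discover_novel(novel_cand[, c("insert", "count")], genome, cfg,
                      exclude = excl, seed = seed)
write_report(nov[, setdiff(names(nov), "window_seq")],
             file.path(outdir, "novel_candidates.tsv"))
rep <- nov[nov$reported, , drop = FALSE]
message("novel hairpins reported: ", nrow(rep))

# novel precursor FASTA with dot-bracket lines
fa <- file.path(outdir, "novel_precursors.fa")
con <- file(fa, "w")
for (i in seq_len(nrow(rep))) {
    writeLines(c(sprintf(">novel-%02d chr1:%d-%d(%s) score=%.2f p=%.4f",
                         i, rep$start[i], rep$end[i], rep$strand[i],
                         rep$signature_score[i], rep$structure_p[i]),
                 rep$window_seq[i], rep$structure[i]), con)
}
close(con)

# signal to noise against dinucleotide-shuffled genomes
sn <- estimate_signal_to_noise(novel_cand[, c("insert", "count")], genome,
                               cfg, n_permutations = 3L, seed = seed + 1L)
write_report(data.frame(ratio = sn$ratio, n_real = sn$n_real,
                        n_shuffled = paste(sn$n_shuffled, collapse = ",")),
             file.path(outdir, "signal_to_noise.tsv"))
message(sprintf("signal-to-noise ratio: %.1f", sn$ratio))

# expression matrix: conserved + novel mature counts per sample
novel_counts <- matrix(0, nrow(rep), nrow(samples),
                       dimnames = list(sprintf("novel-%02d",
                                               seq_len(nrow(rep))),
                                       samples$sample))
if (nrow(rep)) {
    map <- map_tags(novel_cand$insert, genome, cfg$map_max_mismatch)
    for (i in seq_len(nrow(rep))) {
        hit <- map$start < rep$mature_end[i] & map$end > rep$mature_start[i] &
            abs(ifelse(map$strand == "+", map$start, map$end - 1L) -
                ifelse(rep$strand[i] == "+", rep$mature_start[i],
                       rep$mature_end[i] - 1L)) <= 2L
        tags_i <- unique(map$tag[hit])
        rows <- novel_cand$insert %in% tags_i
        novel_counts[i, ] <- colSums(novel_cand[rows, samples$sample,
                                                drop = FALSE])
    }
}
clean_stats <- read_report(file.path(cleandir, "cleaning_stats.tsv"))
totals <- stats::setNames(clean_stats$clean_total, clean_stats$sample)
em <- build_expression_matrix(qc$counts, novel_counts, totals)
write_report(cbind(mirna = rownames(em$counts), as.data.frame(em$counts)),
             file.path(outdir, "expression_matrix.tsv"))
write_report(data.frame(sample = names(em$totals), total = em$totals),
             file.path(outdir, "library_totals.tsv"))
message("expression matrix: ", nrow(em$counts), " miRNAs x ",
        ncol(em$counts), " samples")
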