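# Cross-species 3'UTR transfer, seed-anchored miRNA target prediction,
# pathway tallies, and target-gene expression trend comparison.

# mismatch profile of donor vs genome at one offset (logical vector)
seq_mismatches <- function(a, b) {
    utf8ToInt(a) != utf8ToInt(b)
}

#' Transfer donor-species 3'UTRs onto a genome
#'
#' A donor UTR transfers when an ungapped alignment covers at least
#' `min_coverage` of its length with at most `max_mismatch` substitutions
#' and the alignment starts within `proximity` nt of an annotated gene 3'
#' end. The transferred sequence is taken from the genome at the aligned
#' interval. Output is invariant to donor input order (sorted by locus).
#'
#' @param donors data.frame with `donor_id` (or `id`), `seq`, and
#'   optionally `gene`.
#' @param genome genome sequence string.
#' @param gene_end_table data.frame with `gene`, `end` (0-based 3'-end
#'   coordinate), as from [gene_ends()].
#' @param max_mismatch substitution budget (default 2).
#' @param min_coverage minimum fraction of the donor length aligned
#'   (default 0.8).
#' @param proximity window around a gene 3' end, nt (default 1000).
#' @return data.frame of UTR records: `gene`, `seq`, `source`
#'   (`"transferred"`), `start`, `end`, `mismatches`, `coverage`,
#'   `dist_to_gene_end`, sorted by `start`.
#' @export
transfer_utrs <- function(donors, genome, gene_end_table,
                          max_mismatch = 2L, min_coverage = 0.8,
                          proximity = 1000L) {
    if (!"donor_id" %in% names(donors) && "id" %in% names(donors))
        donors$donor_id <- donors$id
    L <- nchar(genome)
    gch <- strsplit(genome, "")[[1]]
    recs <- list(); k <- 0L
    for (i in seq_len(nrow(donors))) {
        dseq <- donors$seq[i]
        dl <- nchar(dseq)
        minc <- as.integer(ceiling(min_coverage * dl))
        dch <- utf8ToInt(dseq)
        best <- NULL
        for (g in seq_len(nrow(gene_end_table))) {
            gend <- gene_end_table$end[g]
            lo <- max(0L, gend - proximity)
            hi <- min(L - dl, gend + proximity)
            if (hi < lo) next
            for (o in lo:hi) {
                mm <- utf8ToInt(substr(genome, o + 1L, o + dl)) != dch
                full <- sum(mm)
                cand <- NULL
                if (full <= max_mismatch) {
                    cand <- list(start = o, sub_start = 0L, sub_len = dl,
                                 mismatches = full, coverage = 1,
                                 gene = gene_end_table$gene[g],
                                 dist = abs(o - gend))
                } else if (minc < dl) {
                    # best window of the minimum acceptable coverage length
                    cs <- cumsum(mm)
                    wins <- cs[minc:dl] - c(0, cs)[1:(dl - minc + 1L)]
                    if (min(wins) <= max_mismatch) {
                        a <- which.min(wins) - 1L  # 0-based offset in donor
                        cand <- list(start = o + a, sub_start = a,
                                     sub_len = minc,
                                     mismatches = min(wins),
                                     coverage = minc / dl,
                                     gene = gene_end_table$gene[g],
                                     dist = abs(o - gend))
                    }
                }
                if (!is.null(cand) &&
                    (is.null(best) || cand$mismatches < best$mismatches ||
                     (cand$mismatches == best$mismatches &&
                      cand$coverage > best$coverage)))
                    best <- cand
            }
        }
        if (!is.null(best)) {
            k <- k + 1L
            recs[[k]] <- data.frame(
                gene = best$gene,
                donor_id = donors$donor_id[i],
                seq = substr(genome, best$start + 1L,
                             best$start + best$sub_len),
                source = "transferred",
                start = best$start, end = best$start + best$sub_len,
                mismatches = best$mismatches, coverage = best$coverage,
                dist_to_gene_end = best$dist,
                stringsAsFactors = FALSE)
        }
    }
    if (!k)
        return(data.frame(gene = character(), donor_id = character(),
                          seq = character(), source = character(),
                          start = integer(), end = integer(),
                          mismatches = integer(), coverage = numeric(),
                          dist_to_gene_end = integer(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, recs)
    out[order(out$start), , drop = FALSE]
}

#' Merge transferred and unigene-derived UTR records
#'
#' Unigene UTRs are accepted verbatim as a second source.
#'
#' @param transferred output of [transfer_utrs()].
#' @param unigene data.frame with `gene` and `seq`.
#' @return combined UTR record data.frame.
#' @export
merge_utrs <- function(transferred, unigene = NULL) {
    if (is.null(unigene) || !nrow(unigene)) return(transferred)
    uni <- data.frame(gene = unigene$gene, donor_id = NA_character_,
                      seq = unigene$seq, source = "unigene",
                      start = NA_integer_, end = NA_integer_,
                      mismatches = NA_integer_, coverage = NA_real_,
                      dist_to_gene_end = NA_integer_,
                      stringsAsFactors = FALSE)
    rbind(transferred[, names(uni)], uni)
}

#' Predict miRNA target sites in 3'UTRs
#'
#' Scans every UTR offset where the mature fits for Watson-Crick
#' complementarity to miRNA positions 2-8 (the seed; one G:U wobble
#' allowed, class `7mer-wobble`), then scores an ungapped alignment over
#' the full mature: +5 per Watson-Crick pair, +1 per G:U, -4 per mismatch.
#' Sites with a seed hit and total score at or above `score_min` are
#' reported. Class `8mer` adds an adenosine in the UTR opposite miRNA
#' position 1.
#'
#' @param mature mature miRNA sequence (DNA alphabet, 18-26 nt), 5'->3'.
#' @param utrs UTR record data.frame (`gene`, `seq`), or a named character
#'   vector of UTR sequences.
#' @param score_min reporting threshold (default 60).
#' @param mirna_id label for the output rows.
#' @return data.frame of target sites: `mirna`, `gene`, `pos` (1-based UTR
#'   offset of the site's 5' end), `seed_class`, `score`,
#'   `paired_fraction`.
#' @export
predict_targets <- function(mature, utrs, score_min = 60,
                            mirna_id = "mirna") {
    m <- nchar(mature)
    if (m < 18L || m > 26L)
        stop("mature length must be within 18-26 nt")
    if (!is.data.frame(utrs))
        utrs <- data.frame(gene = names(utrs), seq = as.character(utrs),
                           stringsAsFactors = FALSE)
    rcm <- utf8ToInt(dna_revcomp(mature))      # rc[j] pairs miRNA pos m-j+1
    C <- utf8ToInt("C"); A <- utf8ToInt("A")
    G <- utf8ToInt("G"); Tb <- utf8ToInt("T")
    seed_idx <- m + 1L - (2:8)                 # window indices of seed
    rows <- list(); k <- 0L
    for (i in seq_len(nrow(utrs))) {
        useq <- utrs$seq[i]
        ul <- nchar(useq)
        if (ul < m) next
        uch <- utf8ToInt(useq)
        for (s in 1:(ul - m + 1L)) {
            w <- uch[s:(s + m - 1L)]
            wc <- w == rcm
            wob <- (rcm == C & w == Tb) | (rcm == A & w == G)
            mis <- !wc & !wob
            seed_wc <- sum(wc[seed_idx])
            seed_wob <- sum(wob[seed_idx])
            cls <- NA_character_
            if (seed_wc == 7L) {
                cls <- if (w[m] == A) "8mer" else "7mer"
            } else if (seed_wc == 6L && seed_wob == 1L) {
                cls <- "7mer-wobble"
            }
            if (is.na(cls)) next
            score <- 5 * sum(wc) + 1 * sum(wob) - 4 * sum(mis)
            if (score < score_min) next
            k <- k + 1L
            rows[[k]] <- data.frame(
                mirna = mirna_id, gene = utrs$gene[i], pos = s,
                seed_class = cls, score = score,
                paired_fraction = (sum(wc) + sum(wob)) / m,
                stringsAsFactors = FALSE)
        }
    }
    if (!k)
        return(data.frame(mirna = character(), gene = character(),
                          pos = integer(), seed_class = character(),
                          score = numeric(), paired_fraction = numeric(),
                          stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

#' Tally predicted target genes by pathway
#'
#' Per-pathway unique target-gene counts and the number of distinct
#' contributing miRNAs; genes absent from the mapping are tallied under
#' `"unmapped"`.
#'
#' @param sites target-site data.frame from [predict_targets()] (possibly
#'   row-bound over miRNAs).
#' @param pathway_map data.frame with `gene` and `pathway`.
#' @param mirnas optional subset of miRNA ids to restrict the tally to.
#' @return data.frame with `pathway`, `n_genes`, `n_mirnas`.
#' @export
tally_pathways <- function(sites, pathway_map, mirnas = NULL) {
    if (!is.null(mirnas)) sites <- sites[sites$mirna %in% mirnas, ,
                                         drop = FALSE]
    if (!nrow(sites))
        return(data.frame(pathway = character(), n_genes = integer(),
                          n_mirnas = integer(), stringsAsFactors = FALSE))
    pw <- pathway_map$pathway[match(sites$gene, pathway_map$gene)]
    pw[is.na(pw)] <- "unmapped"
    agg <- lapply(split(seq_len(nrow(sites)), pw), function(idx) {
        data.frame(n_genes = length(unique(sites$gene[idx])),
                   n_mirnas = length(unique(sites$mirna[idx])))
    })
    out <- do.call(rbind, agg)
    out <- data.frame(pathway = rownames(out), out, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out[order(-out$n_genes, out$pathway), , drop = FALSE]
}

#' Expression trend of predicted target genes between two groups
#'
#' Per gene: mean expression (e.g. FPKM) per group and a trend label.
#' A gene is `higher_in_A`/`higher_in_B` when the relative difference
#' `|mA - mB| / mean(mA, mB)` is at least `threshold`, else `tied`. Genes
#' missing from the table are flagged.
#'
#' @param fpkm matrix or data.frame of expression values, genes in rows
#'   (rownames), samples in columns.
#' @param target_genes character vector of genes to compare.
#' @param groups data.frame with `sample` and `group` (two levels; the
#'   first-appearing level is group A).
#' @param threshold relative-difference threshold (default 0.2).
#' @return data.frame with `gene`, `present`, `mean_A`, `mean_B`, `trend`.
#' @export
compare_target_expression <- function(fpkm, target_genes, groups,
                                      threshold = 0.2) {
    lev <- unique(groups$group)
    if (length(lev) != 2L) stop("exactly two groups required")
    sa <- groups$sample[groups$group == lev[1]]
    sb <- groups$sample[groups$group == lev[2]]
    fpkm <- as.matrix(fpkm)
    out <- lapply(target_genes, function(g) {
        if (!g %in% rownames(fpkm))
            return(data.frame(gene = g, present = FALSE, mean_A = NA_real_,
                              mean_B = NA_real_, trend = NA_character_,
                              stringsAsFactors = FALSE))
        ma <- mean(fpkm[g, sa]); mb <- mean(fpkm[g, sb])
        trend <- "tied"
        if (ma + mb > 0) {
            rel <- abs(ma - mb) / ((ma + mb) / 2)
            if (rel >= threshold) trend <- if (ma > mb) "higher_in_A"
                                           else "higher_in_B"
        }
        data.frame(gene = g, present = TRUE, mean_A = ma, mean_B = mb,
                   trend = trend, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
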