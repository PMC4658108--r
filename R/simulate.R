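# Synthetic small RNA-seq experiment generator: a toy genome with planted
# hairpin precursors, non-miRNA loci and genes, plus Dicer-like read stacks
# with adapters, quality strings and contaminant classes, each read carrying
# a ground-truth label for downstream validation.

with_seed <- function(seed, code) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(seed)
    code
}

random_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

NONMIRNA_CATEGORIES <- c("rRNA", "tRNA", "scRNA", "snRNA", "snoRNA",
                         "repeat", "exon", "intron")

#' Build the ground truth for a synthetic small RNA experiment
#'
#' Generates a random genome and plants, without overlap: hairpin miRNA
#' precursors (a mature arm, a loop, and the arm's reverse complement, so
#' every precursor folds into a stem-loop), category-labelled non-miRNA loci
#' with fixed read start sites, and protein-coding gene intervals whose 3'
#' ends anchor the UTR-transfer stage. Mature lengths are drawn from
#' 20–23 nt with mode 22, matching the typical blood small-RNA length
#' profile. The star strand is placed with the canonical 2-nt 3' overhang.
#'
#' @param n_precursors number of planted hairpins (>= 1).
#' @param genome_length toy genome length, nt.
#' @param n_loci_per_category non-miRNA loci planted per category.
#' @param locus_length_range length range for non-miRNA loci, nt.
#' @param n_sites_per_locus fixed read start sites per non-miRNA locus.
#' @param mature_lengths,mature_length_weights mature length model.
#' @param loop_length_range hairpin loop length range, nt.
#' @param arm_mismatches substitutions planted in the pairing arm (0 gives
#'   perfect reverse-complement arms).
#' @param n_genes,gene_length planted gene intervals for the targets stage.
#' @param catalog_fraction fraction of precursors entered into the conserved
#'   catalog (the rest are "novel" and must be discovered de novo).
#' @param fold_change named numeric vector of young/adult expression ratios
#'   per precursor id; unnamed precursors default to 1.
#' @param signal_fraction expected fraction of reads that are miRNA signal.
#' @param background_fraction expected fraction from non-miRNA loci.
#' @param star_fraction fraction of each precursor's signal that is star
#'   strand rather than mature.
#' @param contaminant_fractions named fractions for the contaminant classes
#'   `low_quality`, `no_adapter3`, `polyN`, `short`, `adapter5`.
#' @param config pipeline configuration (adapters are taken from it).
#' @param seed RNG seed; the truth is deterministic given the seed.
#' @return a list of class `sim_truth`.
#' @export
build_truth <- function(n_precursors = 10L,
                        genome_length = 10000L,
                        n_loci_per_category = 2L,
                        locus_length_range = c(80L, 200L),
                        n_sites_per_locus = 4L,
                        mature_lengths = 20:23,
                        mature_length_weights = c(0.15, 0.2, 0.5, 0.15),
                        loop_length_range = c(8L, 15L),
                        arm_mismatches = 0L,
                        n_genes = 6L,
                        gene_length = 300L,
                        catalog_fraction = 0,
                        fold_change = NULL,
                        signal_fraction = 0.55,
                        background_fraction = 0.25,
                        star_fraction = 0.08,
                        contaminant_fractions = c(low_quality = 0.05,
                                                  no_adapter3 = 0.05,
                                                  polyN = 0.03,
                                                  short = 0.04,
                                                  adapter5 = 0.03),
                        config = default_config(),
                        seed = 1L) {
    stopifnot(n_precursors >= 1L)
    if (signal_fraction + background_fraction + sum(contaminant_fractions) >
        1 + 1e-9)
        stop("class fractions exceed 1")
    with_seed(seed, {
        genome <- random_dna(genome_length)
        occupied <- matrix(numeric(0), ncol = 2)  # [start, end) 0-based
        margin <- 100L
        gap <- 40L  # wider than the read-stack clustering gap, so two
                    # planted features can never pile into one stack
        place <- function(len) {
            for (try in seq_len(2000L)) {
                s <- sample.int(genome_length - len - 2L * margin, 1L) + margin
                e <- s + len
                if (!nrow(occupied) ||
                    all(e + gap <= occupied[, 1] | s >= occupied[, 2] + gap)) {
                    occupied <<- rbind(occupied, c(s, e))
                    return(s)
                }
            }
            stop("generation error: could not place a ", len,
                 " nt feature without overlap; enlarge the genome")
        }
        plant <- function(s, seq) {
            substr(genome, s + 1L, s + nchar(seq)) <<- seq
        }

        # --- genes first: the largest features pack best ---
        genes <- NULL
        if (n_genes > 0L) {
            gs <- vapply(seq_len(n_genes), function(i) place(gene_length + 120L),
                         numeric(1))
            genes <- data.frame(gene = sprintf("gene-%02d", seq_len(n_genes)),
                                chrom = "chr1",
                                start = gs, end = gs + gene_length,
                                strand = "+", stringsAsFactors = FALSE)
        }

        # --- hairpin precursors ---
        pre <- vector("list", n_precursors)
        for (i in seq_len(n_precursors)) {
            m <- sample(mature_lengths, 1L, prob = mature_length_weights)
            l <- sample(loop_length_range[1]:loop_length_range[2], 1L)
            arm <- random_dna(m)
            arm2 <- dna_revcomp(arm)
            if (arm_mismatches > 0L) {
                pos <- sample.int(m, min(arm_mismatches, m))
                for (p in pos) {
                    cur <- substr(arm2, p, p)
                    substr(arm2, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                         cur), 1L)
                }
            }
            prec_seq <- paste0(arm, random_dna(l), arm2)
            plen <- 2L * m + l
            s <- place(plen + 4L)  # room for the 2 nt star overhang
            plant(s, prec_seq)
            on5p <- i %% 2L == 1L
            if (on5p) {
                ms <- s; me <- s + m
                ss <- s + m + l + 2L; se <- ss + m
            } else {
                ms <- s + m + l; me <- ms + m
                ss <- s + 2L; se <- ss + m
            }
            pre[[i]] <- data.frame(
                id = sprintf("mir-%02d", i), start = s, end = s + plen,
                mature_start = ms, mature_end = me,
                star_start = ss, star_end = se,
                mature_on_5p = on5p,
                precursor_seq = prec_seq,
                stringsAsFactors = FALSE)
        }
        precursors <- do.call(rbind, pre)
        precursors$mature_seq <- substring(genome, precursors$mature_start + 1L,
                                           precursors$mature_end)
        precursors$star_seq <- substring(genome, precursors$star_start + 1L,
                                         precursors$star_end)
        ncat <- ceiling(catalog_fraction * n_precursors)
        precursors$in_catalog <- seq_len(n_precursors) <= ncat

        # --- non-miRNA loci with fixed read start sites ---
        loci <- list(); sites <- list()
        k <- 0L
        for (cat in NONMIRNA_CATEGORIES) {
            for (j in seq_len(n_loci_per_category)) {
                k <- k + 1L
                len <- sample(locus_length_range[1]:locus_length_range[2], 1L)
                s <- place(len)
                id <- sprintf("%s-%02d", cat, j)
                loci[[k]] <- data.frame(locus = id, category = cat,
                                        start = s, end = s + len,
                                        stringsAsFactors = FALSE)
                st <- sort(sample.int(len - 25L, n_sites_per_locus)) - 1L
                sites[[k]] <- data.frame(locus = id, site = s + st,
                                         stringsAsFactors = FALSE)
            }
        }
        nonmirna <- do.call(rbind, loci)
        sites <- do.call(rbind, sites)

        base_prop <- stats::rexp(n_precursors)
        base_prop <- base_prop / sum(base_prop)
        names(base_prop) <- precursors$id
        fc <- stats::setNames(rep(1, n_precursors), precursors$id)
        if (!is.null(fold_change)) fc[names(fold_change)] <- fold_change

        truth <- list(genome = genome, genome_length = genome_length,
                      precursors = precursors, nonmirna = nonmirna,
                      sites = sites, genes = genes,
                      base_prop = base_prop, fold_change = fc,
                      signal_fraction = signal_fraction,
                      background_fraction = background_fraction,
                      star_fraction = star_fraction,
                      contaminant_fractions = contaminant_fractions,
                      config = config, seed = seed)
        class(truth) <- "sim_truth"
        truth
    })
}

# Expected read-class proportions for one library.
class_probs <- function(truth, group) {
    rel <- if (identical(group, "young")) truth$base_prop * truth$fold_change
           else truth$base_prop
    rel <- rel / sum(rel)
    mat <- truth$signal_fraction * rel * (1 - truth$star_fraction)
    star <- truth$signal_fraction * rel * truth$star_fraction
    names(mat) <- paste0("mirna:", names(rel))
    names(star) <- paste0("star:", names(rel))
    nl <- nrow(truth$nonmirna)
    bg <- stats::setNames(rep(truth$background_fraction / nl, nl),
                          paste0("bg:", truth$nonmirna$locus))
    cont <- truth$contaminant_fractions
    names(cont) <- paste0("contam:", names(truth$contaminant_fractions))
    p <- c(mat, star, bg, cont)
    p / sum(p)
}

max_base_frac <- function(x) {
    n <- nchar(x)
    f <- vapply(c("A", "C", "G", "T"),
                function(b) (n - nchar(gsub(b, "", x, fixed = TRUE))) / n,
                numeric(length(x)))
    if (length(x) == 1L) max(f) else apply(matrix(f, nrow = length(x)), 1, max)
}

# Random inserts re-drawn until they cannot trip any filter other than the
# intended one, so truth labels and rejection reasons agree by construction.
screened_random_inserts <- function(n, len, cfg, want_adapter_free = FALSE) {
    out <- character(n)
    need <- seq_len(n)
    lens <- if (length(len) == 1L) rep(len, n) else len
    while (length(need)) {
        cand <- vapply(lens[need], random_dna, character(1))
        ok <- max_base_frac(cand) < cfg$polyN_fraction
        ok <- ok & !cpp_match_prefix(cand, cfg$adapter5,
                                     cfg$adapter_min_overlap,
                                     cfg$adapter_max_mismatch)
        if (want_adapter_free)
            ok <- ok & cpp_find_adapter3(cand, cfg$adapter3,
                                         cfg$adapter_min_overlap,
                                         cfg$adapter_max_mismatch) == 0L
        else {
            full <- paste0(cand, cfg$adapter3)
            ok <- ok & cpp_find_adapter3(full, cfg$adapter3,
                                         cfg$adapter_min_overlap,
                                         cfg$adapter_max_mismatch) ==
                nchar(cand) + 1L
        }
        out[need[ok]] <- cand[ok]
        need <- need[!ok]
    }
    out
}

#' Simulate one sequencing library from a synthetic truth
#'
#' Draws reads multinomially over the truth's read classes. miRNA reads are
#' mature (or star) sequences with a ±1 nt 5'-end jitter and a ±1 nt 3'
#' length variation, the 3' adapter appended and uniformly high quality
#' (Q40). Contaminant classes are emitted at their configured fractions and
#' constructed so that exactly one cleaning filter fires for each:
#' `low_quality` (60\% of bases at Q2), `no_adapter3`, `polyN`, `short`
#' (insert < 18 nt) and `adapter5` (5' adapter at the read start). Every
#' read carries a truth label with its class and source locus.
#'
#' @param truth a `sim_truth` from [build_truth()].
#' @param sample sample label.
#' @param depth library depth (number of reads).
#' @param group `"young"` or `"adult"`; young libraries see the planted fold
#'   changes.
#' @param seed RNG seed.
#' @param jitter5_prob probabilities for a 5'-end shift of -1/0/+1 nt.
#' @param len3_prob probabilities for a 3' length change of -1/0/+1 nt.
#' @return list with `reads` (data.frame id/seq/qual) and `labels`
#'   (data.frame id/class/source).
#' @export
simulate_library <- function(truth, sample, depth, group = "adult", seed = 1L,
                             jitter5_prob = c(0.15, 0.7, 0.15),
                             len3_prob = c(0.2, 0.6, 0.2)) {
    stopifnot(inherits(truth, "sim_truth"), depth >= 1L)
    cfg <- truth$config
    with_seed(seed, {
        probs <- class_probs(truth, group)
        counts <- stats::rmultinom(1L, depth, probs)[, 1L]
        names(counts) <- names(probs)
        cnt <- function(key) if (key %in% names(counts)) counts[[key]] else 0L
        seqs <- character(0); quals <- character(0)
        classes <- character(0); sources <- character(0)
        hi <- function(n) strrep("I", n)  # Q40

        emit_locus_reads <- function(n, start5, len) {
            ins <- substring(truth$genome, start5 + 1L, start5 + len)
            paste0(ins, cfg$adapter3)
        }

        pr <- truth$precursors
        for (i in seq_len(nrow(pr))) {
            for (cls in c("mirna", "star")) {
                n <- cnt(paste0(cls, ":", pr$id[i]))
                if (n == 0L) next
                anchor <- if (cls == "mirna") pr$mature_start[i] else pr$star_start[i]
                blen <- if (cls == "mirna") pr$mature_end[i] - pr$mature_start[i]
                        else pr$star_end[i] - pr$star_start[i]
                jit <- sample(c(-1L, 0L, 1L), n, TRUE, jitter5_prob)
                dl <- sample(c(-1L, 0L, 1L), n, TRUE, len3_prob)
                s <- emit_locus_reads(n, anchor + jit, blen + dl - jit)
                seqs <- c(seqs, s); quals <- c(quals, hi(nchar(s)))
                classes <- c(classes, rep(cls, n))
                sources <- c(sources, rep(pr$id[i], n))
            }
        }

        st <- truth$sites
        for (loc in unique(truth$nonmirna$locus)) {
            n <- cnt(paste0("bg:", loc))
            if (n == 0L) next
            cat <- truth$nonmirna$category[truth$nonmirna$locus == loc]
            locsites <- st$site[st$locus == loc]
            site <- locsites[sample.int(length(locsites), n, TRUE)]
            jit <- sample(0:1, n, TRUE)
            len <- sample(20:23, n, TRUE)
            s <- emit_locus_reads(n, site + jit, len)
            seqs <- c(seqs, s); quals <- c(quals, hi(nchar(s)))
            classes <- c(classes, rep(cat, n))
            sources <- c(sources, rep(loc, n))
        }

        n <- cnt("contam:low_quality")
        if (n > 0L) {
            ins <- screened_random_inserts(n, 22L, cfg)
            s <- paste0(ins, cfg$adapter3)
            q <- vapply(nchar(s), function(L) {
                nlow <- ceiling(0.6 * L)
                qq <- rep("I", L)
                qq[sample.int(L, nlow)] <- "#"  # Q2
                paste(qq, collapse = "")
            }, character(1))
            seqs <- c(seqs, s); quals <- c(quals, q)
            classes <- c(classes, rep("low_quality", n))
            sources <- c(sources, rep(NA_character_, n))
        }
        n <- cnt("contam:no_adapter3")
        if (n > 0L) {
            s <- screened_random_inserts(n, sample(30:40, n, TRUE), cfg,
                                         want_adapter_free = TRUE)
            seqs <- c(seqs, s); quals <- c(quals, hi(nchar(s)))
            classes <- c(classes, rep("no_adapter3", n))
            sources <- c(sources, rep(NA_character_, n))
        }
        n <- cnt("contam:polyN")
        if (n > 0L) {
            base <- sample(c("A", "C", "G", "T"), n, TRUE)
            s <- paste0(strrep(base, 22L), cfg$adapter3)
            seqs <- c(seqs, s); quals <- c(quals, hi(nchar(s)))
            classes <- c(classes, rep("polyN", n))
            sources <- c(sources, rep(NA_character_, n))
        }
        n <- cnt("contam:short")
        if (n > 0L) {
            ins <- screened_random_inserts(n, sample(5:17, n, TRUE), cfg)
            s <- paste0(ins, cfg$adapter3)
            seqs <- c(seqs, s); quals <- c(quals, hi(nchar(s)))
            classes <- c(classes, rep("short", n))
            sources <- c(sources, rep(NA_character_, n))
        }
        n <- cnt("contam:adapter5")
        if (n > 0L) {
            ins <- screened_random_inserts(n, 22L, cfg)
            s <- paste0(cfg$adapter5, ins, cfg$adapter3)
            seqs <- c(seqs, s); quals <- c(quals, hi(nchar(s)))
            classes <- c(classes, rep("adapter5", n))
            sources <- c(sources, rep(NA_character_, n))
        }

        perm <- sample.int(length(seqs))
        ids <- sprintf("%s_read%06d", sample, seq_along(seqs))
        list(reads = data.frame(id = ids, seq = seqs[perm], qual = quals[perm],
                                stringsAsFactors = FALSE),
             labels = data.frame(id = ids, class = classes[perm],
                                 source = sources[perm],
                                 stringsAsFactors = FALSE))
    })
}

#' Simulate a multi-sample experiment
#'
#' The default design mirrors a four-animal blood study: two young samples
#' (M05, F06) and two adult samples (M12, F18).
#'
#' @param truth a `sim_truth`.
#' @param samples data.frame with columns `sample`, `group` (young/adult),
#'   `sex`, and `depth`.
#' @param seed base RNG seed; sample i uses `seed + i`.
#' @return named list of per-sample [simulate_library()] results.
#' @export
simulate_experiment <- function(truth,
                                samples = data.frame(
                                    sample = c("M05", "F06", "M12", "F18"),
                                    group = c("young", "young", "adult", "adult"),
                                    sex = c("male", "female", "male", "female"),
                                    depth = rep(20000L, 4L),
                                    stringsAsFactors = FALSE),
                                seed = 1L) {
    out <- lapply(seq_len(nrow(samples)), function(i) {
        simulate_library(truth, samples$sample[i], samples$depth[i],
                         samples$group[i], seed = seed + i)
    })
    names(out) <- samples$sample
    attr(out, "samples") <- samples
    out
}

#' Simulate an expression count matrix directly from the truth
#'
#' Bypasses the read level: per-sample mature counts are drawn multinomially
#' from the truth's expected proportions at the given depth, which is what
#' the full simulate → clean → quantify path converges to. Used to exercise
#' the differential-expression stage at scale.
#'
#' @param truth a `sim_truth`.
#' @param samples data.frame as in [simulate_experiment()].
#' @param seed RNG seed.
#' @return list with `counts` (precursor x sample integer matrix) and
#'   `totals` (clean-read totals per sample, here the depths).
#' @export
simulate_counts <- function(truth,
                            samples = data.frame(
                                sample = c("M05", "F06", "M12", "F18"),
                                group = c("young", "young", "adult", "adult"),
                                depth = rep(100000L, 4L),
                                stringsAsFactors = FALSE),
                            seed = 1L) {
    with_seed(seed, {
        n <- nrow(truth$precursors)
        counts <- matrix(0L, n, nrow(samples),
                         dimnames = list(truth$precursors$id, samples$sample))
        for (j in seq_len(nrow(samples))) {
            p <- class_probs(truth, samples$group[j])
            p <- p[paste0("mirna:", truth$precursors$id)]
            p <- c(p, other = 1 - sum(p))
            cts <- stats::rmultinom(1L, samples$depth[j], p)[, 1L]
            counts[, j] <- cts[seq_len(n)]
        }
        list(counts = counts,
             totals = stats::setNames(as.numeric(samples$depth),
                                      samples$sample))
    })
}

#' Derive donor 3'UTR sequences from a synthetic truth
#'
#' Extracts the region just downstream of each planted gene 3' end and
#' plants a configurable number of substitutions, emulating a donor species
#' whose UTRs diverge slightly from the target genome. Substitutions are
#' planted in the donor core — the stretch every alignment window at the
#' minimum acceptable coverage must contain — so the planted divergence is
#' exactly what the transfer rule sees.
#'
#' @param truth a `sim_truth`.
#' @param utr_length donor UTR length, nt.
#' @param mismatches integer vector (recycled over genes) of substitutions
#'   planted per donor.
#' @param offset distance from the gene 3' end to the UTR start, nt.
#' @param seed RNG seed.
#' @return data.frame with `donor_id`, `gene`, `seq`, `planted_mismatches`.
#' @export
simulate_utr_donors <- function(truth, utr_length = 80L, mismatches = 0L,
                                offset = 20L, seed = 1L) {
    stopifnot(!is.null(truth$genes))
    with_seed(seed, {
        g <- truth$genes
        mm <- rep_len(mismatches, nrow(g))
        seqs <- character(nrow(g))
        for (i in seq_len(nrow(g))) {
            s <- g$end[i] + offset
            utr <- substr(truth$genome, s + 1L, s + utr_length)
            if (mm[i] > 0L) {
                minc <- as.integer(ceiling(0.8 * utr_length))
                core <- (utr_length - minc + 1L):minc
                pos <- core[sample.int(length(core), mm[i])]
                for (p in pos) {
                    cur <- substr(utr, p, p)
                    substr(utr, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                        cur), 1L)
                }
            }
            seqs[i] <- utr
        }
        data.frame(donor_id = paste0("utr-", g$gene), gene = g$gene,
                   seq = seqs, planted_mismatches = mm,
                   stringsAsFactors = FALSE)
    })
}

#' Gene 3'-end table from a synthetic truth
#'
#' @param truth a `sim_truth`.
#' @return data.frame with `gene`, `chrom`, `end`, `strand`.
#' @export
gene_ends <- function(truth) {
    truth$genes[, c("gene", "chrom", "end", "strand")]
}

#' Conserved miRNA catalog from a synthetic truth
#'
#' Precursor and mature sequences of the planted hairpins flagged
#' `in_catalog`, in the layout [quantify_conserved()] expects.
#'
#' @param truth a `sim_truth`.
#' @return data.frame with `id`, `precursor_seq`, `mature_rel_start`,
#'   `mature_len`, `mature_seq`.
#' @export
truth_catalog <- function(truth) {
    p <- truth$precursors[truth$precursors$in_catalog, , drop = FALSE]
    data.frame(id = p$id,
               precursor_seq = p$precursor_seq,
               mature_rel_start = p$mature_start - p$start,
               mature_len = p$mature_end - p$mature_start,
               mature_seq = p$mature_seq,
               stringsAsFactors = FALSE)
}

#' Write the synthetic reference files to disk
#'
#' Emits the genome FASTA, precursor and mature FASTA (miRBase-style
#' headers), a BED-like non-miRNA annotation table (chrom, start, end, name,
#' category, strand) and TSV truth tables.
#'
#' @param truth a `sim_truth`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_truth_files <- function(truth, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(c(chr1 = truth$genome), file.path(dir, "genome.fa"))
    p <- truth$precursors
    write_fasta(stats::setNames(p$precursor_seq, paste0("aml-", p$id)),
                file.path(dir, "precursors.fa"))
    write_fasta(stats::setNames(p$mature_seq, paste0("aml-", p$id)),
                file.path(dir, "mature.fa"))
    bed <- data.frame(chrom = "chr1", start = truth$nonmirna$start,
                      end = truth$nonmirna$end, name = truth$nonmirna$locus,
                      category = truth$nonmirna$category, strand = "+")
    utils::write.table(bed, file.path(dir, "nonmirna.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    write_report(p[, setdiff(names(p), c("precursor_seq"))],
                 file.path(dir, "truth_precursors.tsv"))
    if (!is.null(truth$genes))
        write_report(truth$genes, file.path(dir, "genes.tsv"))
    invisible(dir)
}
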