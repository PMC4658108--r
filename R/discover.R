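# Novel miRNA discovery: map candidate tags to the genome, pile them into
# read stacks, excise candidate precursor windows, fold them by weighted
# base-pair maximization, score the read signature, and test the structure
# against dinucleotide shuffles. Conserved miRNAs are quantified against a
# hairpin catalog.

#' Map unique tags to a genome
#'
#' Reports every alignment with at most `max_mismatch` substitutions on
#' either strand (no indels). Coordinates are 0-based half-open; a minus
#' strand alignment means the reverse complement of the tag matches the
#' forward genome at the reported interval.
#'
#' @param tags character vector of tag sequences (or a unique-tag
#'   data.frame).
#' @param genome genome sequence string (single chromosome, `chr1`) or a
#'   named character vector of chromosomes.
#' @param max_mismatch substitution budget (default 1, "less than 1 base
#'   mismatch" read as a 1-mismatch budget; set 0 for exact).
#' @return data.frame with `tag`, `chrom`, `start`, `end`, `strand`,
#'   `mismatches`.
#' @export
map_tags <- function(tags, genome, max_mismatch = 1L) {
    if (is.data.frame(tags)) tags <- tags$insert
    if (is.null(names(genome)) && length(genome) == 1L)
        names(genome) <- "chr1"
    out <- list(); k <- 0L
    for (chrom in names(genome)) {
        subj <- Biostrings::DNAString(genome[[chrom]])
        for (tg in tags) {
            for (strand in c("+", "-")) {
                pat <- if (strand == "+") tg else dna_revcomp(tg)
                m <- Biostrings::matchPattern(pat, subj,
                                              max.mismatch = max_mismatch)
                if (!length(m)) next
                mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pat),
                                                  subj,
                                                  starting.at = BiocGenerics::start(m))
                k <- k + 1L
                out[[k]] <- data.frame(
                    tag = tg, chrom = chrom,
                    start = BiocGenerics::start(m) - 1L,
                    end = BiocGenerics::end(m),
                    strand = strand, mismatches = as.integer(mm),
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!k)
        return(data.frame(tag = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), mismatches = integer(),
                          stringsAsFactors = FALSE))
    do.call(rbind, out)
}

#' Quantify conserved miRNAs against a hairpin catalog
#'
#' A tag counts toward a catalog miRNA when it aligns exactly within the
#' precursor sequence with its 5' end within `tolerance` nt of the catalog
#' mature 5' end. Tags assigned to the same precursor aggregate into one
#' miRNA (length and 3'-end variants are the same kind).
#'
#' @param tag_counts unique-tag counts: a data.frame with `insert` plus one
#'   count column per sample (or a single `count` column).
#' @param catalog data.frame as from [truth_catalog()]: `id`,
#'   `precursor_seq`, `mature_rel_start`.
#' @param tolerance 5'-end tolerance, nt (default 2).
#' @return list with `counts` (miRNA x sample matrix) and `assignments`
#'   (data.frame `insert`, `id`, `rel_start`).
#' @export
quantify_conserved <- function(tag_counts, catalog, tolerance = 2L) {
    count_cols <- setdiff(names(tag_counts), c("insert", "category"))
    asg <- list(); k <- 0L
    for (i in seq_len(nrow(catalog))) {
        pre <- catalog$precursor_seq[i]
        m5 <- catalog$mature_rel_start[i]
        for (j in seq_len(nrow(tag_counts))) {
            tg <- tag_counts$insert[j]
            hit <- gregexpr(tg, pre, fixed = TRUE)[[1]]
            if (hit[1] == -1L) next
            rel <- hit - 1L
            rel <- rel[abs(rel - m5) <= tolerance]
            if (!length(rel)) next
            k <- k + 1L
            asg[[k]] <- data.frame(insert = tg, id = catalog$id[i],
                                   rel_start = rel[1], j = j,
                                   stringsAsFactors = FALSE)
        }
    }
    counts <- matrix(0, nrow(catalog), length(count_cols),
                     dimnames = list(catalog$id, count_cols))
    if (k) {
        asg <- do.call(rbind, asg)
        for (r in seq_len(nrow(asg)))
            counts[asg$id[r], ] <- counts[asg$id[r], ] +
                as.numeric(tag_counts[asg$j[r], count_cols])
        asg$j <- NULL
    } else {
        asg <- data.frame(insert = character(), id = character(),
                          rel_start = integer(), stringsAsFactors = FALSE)
    }
    list(counts = counts, assignments = asg)
}

#' Pile mapped tags into read stacks
#'
#' Alignments on the same chromosome and strand are clustered whenever the
#' next alignment starts within `max_gap` nt of the running cluster end.
#' Each stack records its members and the dominant 5' position (the
#' strand-aware 5' end carrying the largest read count; ties break to the
#' 5'-most position).
#'
#' @param map alignment table from [map_tags()].
#' @param tag_counts unique-tag table with `insert` and `count` (pooled
#'   counts used to weight 5' positions).
#' @param max_gap clustering gap, nt.
#' @return list of stacks; each a list with `chrom`, `strand`, `start`,
#'   `end`, `members` (data.frame `tag`, `start`, `end`, `five`, `count`),
#'   `dominant5`, `mature_len`.
#' @export
build_stacks <- function(map, tag_counts, max_gap = 10L) {
    if (!nrow(map)) return(list())
    cnt <- stats::setNames(tag_counts$count, tag_counts$insert)
    map$count <- as.numeric(cnt[map$tag])
    map$count[is.na(map$count)] <- 1
    map$five <- ifelse(map$strand == "+", map$start, map$end - 1L)
    stacks <- list(); k <- 0L
    for (key in unique(paste(map$chrom, map$strand))) {
        sub <- map[paste(map$chrom, map$strand) == key, , drop = FALSE]
        sub <- sub[order(sub$start), , drop = FALSE]
        cur_end <- -Inf; groups <- integer(nrow(sub)); g <- 0L
        for (i in seq_len(nrow(sub))) {
            if (sub$start[i] > cur_end + max_gap) { g <- g + 1L; cur_end <- sub$end[i] }
            else cur_end <- max(cur_end, sub$end[i])
            groups[i] <- g
        }
        for (gi in seq_len(g)) {
            mem <- sub[groups == gi, , drop = FALSE]
            by5 <- tapply(mem$count, mem$five, sum)
            top <- max(by5)
            dom5 <- min(as.integer(names(by5)[by5 == top]))
            at <- mem[mem$five == dom5, , drop = FALSE]
            mlen <- nchar(at$tag[which.max(at$count)])
            k <- k + 1L
            stacks[[k]] <- list(chrom = mem$chrom[1], strand = mem$strand[1],
                                start = min(mem$start), end = max(mem$end),
                                members = mem[, c("tag", "start", "end",
                                                  "five", "count")],
                                dominant5 = dom5, mature_len = mlen)
        }
    }
    stacks
}

#' Excise candidate precursor windows around a stack
#'
#' For the stack's dominant mature interval, emits the two genomic windows
#' that could hold the hairpin: mature plus `flank` nt of upstream context,
#' and mature plus `flank` nt of downstream context, clipped at the genome
#' ends. Minus-strand stacks are handled on the reverse-complemented
#' coordinate system, so the returned `seq` always reads 5'->3' with the
#' mature at the stated relative interval.
#'
#' @param stack one stack from [build_stacks()].
#' @param genome the chromosome sequence string.
#' @param flank context length, nt (default 70).
#' @return list of windows; each has `seq`, `mature_rel` (0-based
#'   half-open), `genome_start`, `genome_end`, `strand`, and `members`
#'   (stack members that fall inside the window, with window-relative
#'   `five`).
#' @export
excise_candidates <- function(stack, genome, flank = 70L) {
    L <- nchar(genome)
    minus <- stack$strand == "-"
    if (minus) {
        gseq <- dna_revcomp(genome)
        mem <- stack$members
        mem$five <- L - 1L - mem$five
        ms <- L - 1L - stack$dominant5
    } else {
        gseq <- genome
        mem <- stack$members
        ms <- stack$dominant5
    }
    me <- ms + stack$mature_len
    win <- list(c(max(0L, ms - flank), me), c(ms, min(L, me + flank)))
    out <- lapply(win, function(w) {
        ws <- w[1]; we <- w[2]
        # all stack members, rebased to window coordinates (a member's 5'
        # end may fall outside the window; the signature shares are over
        # the whole stack)
        members <- mem
        members$five <- members$five - ws
        gs <- if (minus) L - we else ws
        ge <- if (minus) L - ws else we
        list(seq = substr(gseq, ws + 1L, we),
             mature_rel = c(ms - ws, me - ws),
             genome_start = gs, genome_end = ge,
             strand = stack$strand, members = members)
    })
    out
}

#' Fold a candidate window by weighted base-pair maximization
#'
#' Maximum-weight non-crossing pairing with weights GC=3, AU=2, GU=1 and a
#' minimum hairpin loop of 3 nt; deterministic tie-breaking (the 5'-most
#' free base pairs, preferring the outermost partner).
#'
#' @param window_seq window sequence (>= `min_window` nt, default 40).
#' @param min_loop minimum loop length, nt.
#' @param min_window windows shorter than this are skipped (`NULL` return).
#' @return list with `structure` (dot-bracket) and `score`, or `NULL` when
#'   the window is too short.
#' @export
fold_hairpin <- function(window_seq, min_loop = 3L, min_window = 40L) {
    if (nchar(window_seq) < min_window) return(NULL)
    cpp_nussinov(window_seq, min_loop)
}

#' Read-signature score of a folded candidate
#'
#' An additive surrogate for a probabilistic hairpin-read score:
#' `4 * share of reads whose 5' end is within 1 nt of the dominant mature
#' 5'` `+ 3` if at least 60\% of mature bases are paired, `+ 2` if
#' star-compatible reads exist (5' end within 2 nt of the position implied
#' by a 2-nt 3' overhang, and clearly outside the mature interval), `+ 1`
#' if the hairpin loop length is within
#' 3–25 nt, `- 4 * share of reads whose 5' end falls inside the loop`.
#' Range -4..10. A mature with no paired base is not on a stem arm and
#' scores `-Inf` (candidate discarded).
#'
#' @param members window members (data.frame with window-relative `five`
#'   and `count`).
#' @param structure dot-bracket string of the window.
#' @param mature_rel 0-based half-open mature interval within the window.
#' @param dominant5 window-relative dominant 5' position.
#' @return list with `score` and components (`share5`, `mature_paired_frac`,
#'   `has_star`, `loop_len`, `loop_share`, `star_implied5`).
#' @export
score_signature <- function(members, structure, mature_rel, dominant5) {
    total <- sum(members$count)
    if (total == 0) return(list(score = -Inf))
    partners <- structure_partners(structure)
    ms <- mature_rel[1]; me <- mature_rel[2]
    idx <- (ms + 1L):me                       # 1-based positions of mature
    paired <- !is.na(partners[idx])
    frac_paired <- mean(paired)
    if (!any(paired)) return(list(score = -Inf))

    share5 <- sum(members$count[abs(members$five - dominant5) <= 1L]) / total

    # star 5' implied by a 2-nt 3' overhang from the mature's 3' end
    q <- max(which(paired)) + ms - 1L          # 0-based innermost paired base
    star5 <- partners[q + 1L] - ((me - 1L) - q) + 2L
    # star-compatible reads must sit across the loop, not be jittered
    # mature reads: require a clear separation from the mature interval
    star_reads <- members$count[abs(members$five - star5) <= 2L &
                                (members$five <= ms - 5L |
                                 members$five >= me + 5L)]
    has_star <- sum(star_reads) > 0

    # hairpin loop: the innermost pair's enclosed stretch
    pr <- which(!is.na(partners)) - 1L
    loop_len <- NA_integer_; loop_lo <- NA_integer_; loop_hi <- NA_integer_
    if (length(pr)) {
        spans <- partners[pr + 1L] - pr
        inner <- pr[spans > 0][which.min(spans[spans > 0])]
        loop_lo <- inner; loop_hi <- partners[inner + 1L]
        loop_len <- loop_hi - loop_lo - 1L
    }
    loop_ok <- !is.na(loop_len) && loop_len >= 3L && loop_len <= 25L
    loop_share <- if (is.na(loop_len) || loop_len == 0L) 0 else
        sum(members$count[members$five > loop_lo & members$five < loop_hi]) /
        total

    score <- 4 * share5 + 3 * (frac_paired >= 0.6) + 2 * has_star +
        1 * loop_ok - 4 * loop_share
    list(score = score, share5 = share5, mature_paired_frac = frac_paired,
         has_star = has_star, loop_len = loop_len, loop_share = loop_share,
         star_implied5 = star5)
}

#' Shuffle-based structure test
#'
#' Empirical p-value of a window's pairing score against
#' dinucleotide-preserving shuffles:
#' `p = (1 + #{shuffles with score >= observed}) / (shuffle_count + 1)`.
#'
#' @param window_seq window sequence.
#' @param observed_score the window's pairing score.
#' @param shuffle_count number of shuffles (>= 20).
#' @param seed RNG seed; the test is deterministic given the seed.
#' @param min_loop minimum loop length for scoring.
#' @return p-value in `[1/(shuffle_count+1), 1]`; 1 for windows shorter
#'   than 10 nt.
#' @export
shuffle_structure_test <- function(window_seq, observed_score,
                                   shuffle_count = 100L, seed = 1L,
                                   min_loop = 3L) {
    stopifnot(shuffle_count >= 20L)
    if (nchar(window_seq) < 10L) return(1)
    with_seed(seed, {
        ge <- 0L
        for (i in seq_len(shuffle_count)) {
            sh <- dinucleotide_shuffle(window_seq)
            if (cpp_nussinov_score(sh, min_loop) >= observed_score)
                ge <- ge + 1L
        }
        (1 + ge) / (shuffle_count + 1)
    })
}

#' Discover novel miRNA candidates
#'
#' Runs the full discovery chain on candidate tags: genome mapping, read
#' stacking, window excision, folding, signature scoring, and the shuffle
#' structure test. For each stack the better-scoring of the two excised
#' windows is kept; overlapping candidates (the two strands of one hairpin,
#' or length variants of one precursor) are grouped and only the best per
#' precursor is retained. The shuffle structure test randomizes the
#' candidate precursor subregion — the mature arm plus every base it pairs
#' with — rather than the whole excised window, so flanking context cannot
#' dilute the test. A candidate is `reported` when its signature score
#' exceeds `report_score_min` and its structure p-value is below
#' `shuffle_alpha`.
#'
#' @param tag_counts candidate unique-tag table (`insert`, `count`, plus
#'   optional per-sample count columns used for the expression matrix).
#' @param genome genome string.
#' @param config pipeline configuration.
#' @param exclude optional data.frame of intervals (`start`, `end`) whose
#'   overlapping stacks are skipped (e.g. catalog miRNA loci).
#' @param seed RNG seed for the shuffle tests.
#' @param map optional precomputed [map_tags()] result.
#' @return data.frame, one row per candidate precursor: coordinates, window
#'   sequence, dot-bracket `structure`, `pairing_score`, `signature_score`,
#'   `structure_p`, `reported`, plus per-sample mature counts when sample
#'   columns are present in `tag_counts`.
#' @export
discover_novel <- function(tag_counts, genome, config = default_config(),
                           exclude = NULL, seed = 1L, map = NULL) {
    empty <- data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        window_seq = character(), structure = character(),
                        pairing_score = numeric(), signature_score = numeric(),
                        structure_p = numeric(), reported = logical(),
                        mature_start = integer(), mature_end = integer(),
                        n_reads = numeric(), group = integer(),
                        stringsAsFactors = FALSE)
    if (is.null(map))
        map <- map_tags(tag_counts$insert, genome, config$map_max_mismatch)
    if (!nrow(map)) return(empty)
    stacks <- build_stacks(map, tag_counts, config$stack_max_gap)
    if (!is.null(exclude) && nrow(exclude)) {
        keep <- vapply(stacks, function(st) {
            !any(st$start < exclude$end & st$end > exclude$start)
        }, logical(1))
        stacks <- stacks[keep]
    }
    if (!length(stacks)) return(empty)
    rows <- list(); k <- 0L
    for (st in stacks) {
        wins <- excise_candidates(st, genome, config$excise_flank)
        best <- NULL
        for (w in wins) {
            fold <- fold_hairpin(w$seq, min_window = config$min_window)
            if (is.null(fold)) next
            dom5 <- w$mature_rel[1]
            sig <- score_signature(w$members, fold$structure, w$mature_rel,
                                   dom5)
            if (!is.finite(sig$score)) next
            cand <- list(w = w, fold = fold, sig = sig)
            if (is.null(best) || sig$score > best$sig$score ||
                (sig$score == best$sig$score &&
                 fold$score > best$fold$score))
                best <- cand
        }
        if (is.null(best)) next
        p <- NA_real_
        if (best$sig$score > config$report_score_min) {
            # randomize the candidate precursor, not the excised context:
            # the tested subregion spans the mature and every base it
            # pairs with
            partners <- structure_partners(best$fold$structure)
            mi <- (best$w$mature_rel[1] + 1L):best$w$mature_rel[2]
            pp <- partners[mi]
            pp <- pp[!is.na(pp)]
            lo <- min(c(best$w$mature_rel[1], pp))
            hi <- max(c(best$w$mature_rel[2] - 1L, pp))
            hp_seq <- substr(best$w$seq, lo + 1L, hi + 1L)
            obs <- cpp_nussinov_score(hp_seq)
            p <- shuffle_structure_test(hp_seq, obs, config$shuffle_count,
                                        seed = seed)
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
            chrom = st$chrom, start = best$w$genome_start,
            end = best$w$genome_end, strand = st$strand,
            window_seq = best$w$seq, structure = best$fold$structure,
            pairing_score = best$fold$score,
            signature_score = best$sig$score,
            structure_p = p,
            reported = !is.na(p) && best$sig$score > config$report_score_min &&
                p < config$shuffle_alpha,
            mature_start = best$w$genome_start + best$w$mature_rel[1],
            mature_end = best$w$genome_start + best$w$mature_rel[2],
            n_reads = sum(best$w$members$count),
            stringsAsFactors = FALSE)
    }
    if (!k) return(empty)
    out <- do.call(rbind, rows)
    # group overlapping candidates (same precursor); keep the best per group
    out <- out[order(-out$signature_score, -out$pairing_score, out$start), ,
               drop = FALSE]
    grp <- rep(NA_integer_, nrow(out)); g <- 0L
    kept <- list()
    for (i in seq_len(nrow(out))) {
        hit <- NA_integer_
        for (j in seq_along(kept)) {
            if (out$start[i] < kept[[j]]$end && out$end[i] > kept[[j]]$start) {
                hit <- j; break
            }
        }
        if (is.na(hit)) {
            g <- g + 1L
            kept[[g]] <- list(start = out$start[i], end = out$end[i])
            grp[i] <- g
        } else grp[i] <- hit
    }
    out$group <- grp
    out <- out[!duplicated(out$group), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Signal-to-noise ratio of novel discovery
#'
#' Reported candidates on the real genome divided by (one plus) the mean
#' number reported on dinucleotide-shuffled genomes.
#'
#' @param tag_counts candidate unique-tag table.
#' @param genome genome string.
#' @param config pipeline configuration.
#' @param n_permutations number of shuffled genomes (>= 3).
#' @param seed RNG seed.
#' @return list with `ratio`, `n_real`, `n_shuffled` (per permutation).
#' @export
estimate_signal_to_noise <- function(tag_counts, genome,
                                     config = default_config(),
                                     n_permutations = 3L, seed = 1L) {
    stopifnot(n_permutations >= 3L)
    real <- sum(discover_novel(tag_counts, genome, config, seed = seed)$reported)
    nshuf <- vapply(seq_len(n_permutations), function(i) {
        g <- dinucleotide_shuffle(genome, seed = seed + i)
        sum(discover_novel(tag_counts, g, config, seed = seed + i)$reported)
    }, numeric(1))
    list(ratio = real / (mean(nshuf) + 1), n_real = real, n_shuffled = nshuf)
}

#' Assemble an expression matrix of conserved and novel miRNAs
#'
#' @param conserved_counts miRNA x sample matrix from [quantify_conserved()].
#' @param novel_counts optional matrix of novel candidate counts (rows named
#'   `novel-*`).
#' @param totals named per-sample clean-read totals.
#' @return list of class `expression_matrix` with `counts` and `totals`;
#'   totals must be at least the column sums.
#' @export
build_expression_matrix <- function(conserved_counts, novel_counts = NULL,
                                    totals) {
    counts <- conserved_counts
    if (!is.null(novel_counts) && nrow(novel_counts))
        counts <- rbind(counts, novel_counts[, colnames(counts), drop = FALSE])
    if (any(counts < 0)) stop("negative counts")
    if (any(colSums(counts) > totals[colnames(counts)] + 1e-9))
        stop("totals smaller than column sums")
    structure(list(counts = counts, totals = totals[colnames(counts)]),
              class = "expression_matrix")
}
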