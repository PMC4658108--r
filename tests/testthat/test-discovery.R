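test_that("tag mapping reports exact, mismatched and minus-strand hits", {
    set.seed(31)
    genome <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
    tag <- substr(genome, 101, 122)
    m <- map_tags(tag, genome, max_mismatch = 0L)
    expect_true(any(m$start == 100L & m$strand == "+" & m$mismatches == 0L))

    rc <- dna_revcomp(tag)
    mrc <- map_tags(rc, genome, max_mismatch = 0L)
    expect_true(any(mrc$start == 100L & mrc$strand == "-"))

    # plant two substitutions; budget 1 must drop it everywhere
    mut <- tag
    substr(mut, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(tag, 3, 3))[1]
    substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                   substr(tag, 10, 10))[1]
    # exhaustive offset-scan oracle: no placement within 1 mismatch
    ok <- TRUE
    for (s in 1:(nchar(genome) - nchar(mut) + 1L)) {
        for (probe in c(mut, dna_revcomp(mut))) {
            mm <- sum(utf8ToInt(substr(genome, s, s + nchar(mut) - 1L)) !=
                      utf8ToInt(probe))
            if (mm <= 1L) ok <- FALSE
        }
    }
    expect_true(ok)
    expect_identical(nrow(map_tags(mut, genome, max_mismatch = 1L)), 0L)
    expect_gt(nrow(map_tags(mut, genome, max_mismatch = 2L)), 0L)
})

test_that("conserved quantification groups 5' variants and enforces the offset rule", {
    pre <- paste0("GGAATTCCGGAATTCC", "TCAGGCATCGATTCAGGACTGA",
                  "CCTTAAGGCCTTAAGG")
    catalog <- data.frame(id = "mir-x", precursor_seq = pre,
                          mature_rel_start = 16L, mature_len = 22L,
                          stringsAsFactors = FALSE)
    mature <- substr(pre, 17, 38)
    variant <- substr(pre, 17, 39)        # 3' length variant, same 5' end
    shifted <- substr(pre, 22, 43)        # 5 nt downstream
    tags <- data.frame(insert = c(mature, variant, shifted),
                       count = c(10L, 4L, 7L), stringsAsFactors = FALSE)
    q <- quantify_conserved(tags, catalog, tolerance = 2L)
    expect_identical(unname(q$counts["mir-x", "count"]), 14)
    expect_true(!shifted %in% q$assignments$insert)
})

test_that("candidate windows contain the planted hairpin and clip at genome ends", {
    truth <- build_truth(seed = 23)
    p <- truth$precursors[1, ]
    members <- data.frame(tag = p$mature_seq, start = p$mature_start,
                          end = p$mature_end, five = p$mature_start,
                          count = 50)
    stack <- list(chrom = "chr1", strand = "+", start = p$mature_start,
                  end = p$mature_end, members = members,
                  dominant5 = p$mature_start,
                  mature_len = p$mature_end - p$mature_start)
    wins <- excise_candidates(stack, truth$genome, flank = 70L)
    expect_length(wins, 2L)
    contains <- vapply(wins, function(w)
        w$genome_start <= p$start && w$genome_end >= p$end, logical(1))
    expect_true(any(contains))
    w <- wins[[which(contains)[1]]]
    expect_identical(substr(w$seq, w$mature_rel[1] + 1L, w$mature_rel[2]),
                     p$mature_seq)

    # stack 10 nt from the chromosome start: upstream window clipped, no error
    near <- list(chrom = "chr1", strand = "+", start = 10L, end = 32L,
                 members = data.frame(tag = substr(truth$genome, 11, 32),
                                      start = 10L, end = 32L, five = 10L,
                                      count = 5),
                 dominant5 = 10L, mature_len = 22L)
    wn <- excise_candidates(near, truth$genome, flank = 70L)
    expect_identical(wn[[1]]$genome_start, 0L)
    expect_identical(nchar(wn[[1]]$seq), 32L)
})

test_that("weighted base-pair maximization matches hand-derived examples", {
    expect_identical(mirprofiler:::cpp_nussinov_score("GGGAAACCC"), 9L)
    expect_identical(mirprofiler:::cpp_nussinov_score(strrep("A", 30)), 0L)

    set.seed(5)
    S <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    hp <- paste0(S, "AAAA", dna_revcomp(S))
    fold <- fold_hairpin(hp, min_window = 10L)
    expect_gte(lengths(regmatches(fold$structure,
                                  gregexpr("(", fold$structure,
                                           fixed = TRUE))), 20L)
})

test_that("folding equals the exhaustive enumeration oracle for short windows", {
    set.seed(77)
    cases <- c("GGGAAACCC", "GCGCAAAGCGC", "ACGUACGT",
               vapply(1:25, function(i) {
                   n <- sample(8:18, 1)
                   paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
               }, character(1)))
    cases <- cases[!grepl("U", cases)]
    for (s in cases) {
        oracle <- enum_best_fold_score(s)
        fold <- mirprofiler:::cpp_nussinov(s)
        expect_identical(fold$score, as.integer(oracle))
        # returned structure is valid and scores exactly the reported score
        expect_identical(score_structure(s, fold$structure), fold$score)
    }
})

test_that("dinucleotide shuffling preserves dinucleotide counts", {
    set.seed(12)
    for (i in 1:15) {
        n <- sample(20:120, 1)
        s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
        sh <- dinucleotide_shuffle(s, seed = i)
        expect_identical(dinuc_counts(sh), dinuc_counts(s))
        expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
        expect_identical(substr(sh, n, n), substr(s, n, n))
    }
    expect_identical(dinucleotide_shuffle("ACGTACGTAC", seed = 4),
                     dinucleotide_shuffle("ACGTACGTAC", seed = 4))
})

test_that("the shuffle structure test is bounded, degenerate-safe and powerful", {
    expect_identical(shuffle_structure_test(strrep("A", 60), 0,
                                            shuffle_count = 50L, seed = 1), 1)
    expect_identical(shuffle_structure_test("ACGTACGT", 5,
                                            shuffle_count = 50L, seed = 1), 1)

    set.seed(6)
    S <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    hp <- paste0("ACGT", S, "GAAAACTT", dna_revcomp(S), "TTAA")
    obs <- mirprofiler:::cpp_nussinov_score(hp)
    ps <- vapply(1:10, function(sd)
        shuffle_structure_test(hp, obs, shuffle_count = 100L, seed = sd),
        numeric(1))
    expect_true(all(ps >= 1 / 101 & ps <= 1))
    expect_gte(sum(ps <= 0.05), 9L)

    # p is deterministic given the seed
    expect_identical(shuffle_structure_test(hp, obs, 100L, seed = 3),
                     shuffle_structure_test(hp, obs, 100L, seed = 3))
})

test_that("the signature score follows its additive definition", {
    # perfect hairpin: mature = S (5' arm), loop 8, star across the loop
    set.seed(41)
    S <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
    loop <- "ACGTTGCA"
    win <- paste0(S, loop, dna_revcomp(S), "GG")
    fold <- fold_hairpin(win, min_window = 10L)
    star5 <- 22L + 8L + 2L
    members <- data.frame(tag = c(S, "star"), start = 0L, end = 22L,
                          five = c(0L, star5), count = c(90, 10))
    sig <- score_signature(members, fold$structure, c(0L, 22L), 0L)
    expect_true(sig$has_star)
    expect_equal(sig$share5, 0.9)
    expect_gte(sig$mature_paired_frac, 0.6)
    expect_equal(sig$score, 4 * 0.9 + 3 + 2 + 1)

    # uniform 5' ends on an unpaired mature: score stays below threshold
    members2 <- data.frame(tag = "t", start = 0L, end = 22L,
                           five = 0:21, count = rep(1, 22))
    sig2 <- score_signature(members2, fold$structure, c(0L, 22L), 0L)
    expect_lt(sig2$score, 5)

    # mature with no paired base is discarded
    flat <- paste0(strrep(".", 22), "((((....))))",
                   strrep(".", nchar(win) - 34L))
    sig3 <- score_signature(members, flat, c(0L, 22L), 0L)
    expect_identical(sig3$score, -Inf)
})

test_that("planted hairpins are discovered and shuffled genomes stay quiet", {
    truth <- build_truth(seed = 29)
    lib <- simulate_library(truth, "S", 20000L, seed = 30)
    cl <- clean_library(lib$reads, truth$config)
    tags <- collapse_unique(cl$clean)
    ann <- annotate_tags(tags, truth_annotation_db(truth))
    cand <- ann[ann$category == "candidate", c("insert", "count")]
    nov <- discover_novel(cand, truth$genome, truth$config, seed = 31)
    rep <- nov[nov$reported, ]
    pr <- truth$precursors
    recovered <- vapply(seq_len(nrow(pr)), function(i)
        any(rep$start < pr$end[i] & rep$end > pr$start[i]), logical(1))
    expect_gte(sum(recovered), 9L)
    # every reported window sits on a planted hairpin
    on_hairpin <- vapply(seq_len(nrow(rep)), function(i)
        any(rep$start[i] < pr$end & rep$end[i] > pr$start), logical(1))
    expect_true(all(on_hairpin))

    g2 <- dinucleotide_shuffle(truth$genome, seed = 99)
    nov2 <- discover_novel(cand, g2, truth$config, seed = 31)
    expect_lte(sum(nov2$reported), 1L)
})

test_that("signal-to-noise estimation is deterministic and sign-correct", {
    truth <- build_truth(n_precursors = 4L, genome_length = 8000L,
                         n_loci_per_category = 1L, seed = 33)
    lib <- simulate_library(truth, "S", 8000L, seed = 34)
    cl <- clean_library(lib$reads, truth$config)
    tags <- collapse_unique(cl$clean)
    ann <- annotate_tags(tags, truth_annotation_db(truth))
    cand <- ann[ann$category == "candidate", c("insert", "count")]
    cfg <- truth$config
    cfg$shuffle_count <- 50L
    s1 <- estimate_signal_to_noise(cand, truth$genome, cfg,
                                   n_permutations = 3L, seed = 7)
    s2 <- estimate_signal_to_noise(cand, truth$genome, cfg,
                                   n_permutations = 3L, seed = 7)
    expect_identical(s1, s2)
    expect_gt(s1$ratio, 1)

    # no mappable tags -> no reported candidates -> ratio 0
    none <- data.frame(insert = strrep("ACGT", 6), count = 1L)
    g <- paste(rep("A", 2000), collapse = "")
    s0 <- estimate_signal_to_noise(none, g, cfg, n_permutations = 3L,
                                   seed = 8)
    expect_identical(s0$ratio, 0)
})

test_that("expression matrices validate their totals", {
    counts <- matrix(c(5, 10, 3, 7), 2, 2,
                     dimnames = list(c("m1", "m2"), c("s1", "s2")))
    totals <- c(s1 = 100, s2 = 100)
    em <- build_expression_matrix(counts, totals = totals)
    expect_identical(em$counts, counts)
    expect_error(build_expression_matrix(counts, totals = c(s1 = 10, s2 = 5)),
                 "totals")
    expect_error(build_expression_matrix(-counts, totals = totals),
                 "negative")
})
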