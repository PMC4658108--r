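test_that("UTR transfer enforces mismatch, coverage and proximity rules", {
    set.seed(61)
    genome <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
    gend <- data.frame(gene = "g1", chrom = "chr1", end = 1000L,
                       strand = "+", stringsAsFactors = FALSE)
    utr_start <- 1050L
    donor_exact <- substr(genome, utr_start + 1L, utr_start + 100L)

    plant_mm <- function(seq, k) {
        pos <- sample.int(nchar(seq), k)
        for (p in pos) {
            cur <- substr(seq, p, p)
            substr(seq, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
        }
        seq
    }
    donors <- data.frame(
        donor_id = c("d0", "d2", "d3", "dfar"),
        seq = c(donor_exact, plant_mm(donor_exact, 2L),
                plant_mm(donor_exact, 3L),
                substr(genome, 3001, 3100)),  # matches, but 2 kb from the end
        stringsAsFactors = FALSE)
    tr <- transfer_utrs(donors, genome, gend, proximity = 1000L)
    expect_true("d0" %in% tr$donor_id)
    expect_true("d2" %in% tr$donor_id)
    expect_false("d3" %in% tr$donor_id)   # 3 substitutions over any 80% window
    expect_false("dfar" %in% tr$donor_id) # outside the proximity window
    expect_identical(tr$seq[tr$donor_id == "d0"], donor_exact)
    expect_identical(tr$seq[tr$donor_id == "d2"], donor_exact)  # genome copy

    # 70% matchable donor: tail diverges, no 80%-coverage window fits
    donor70 <- paste0(substr(donor_exact, 1, 70),
                      plant_mm(substr(donor_exact, 71, 100), 12L))
    tr70 <- transfer_utrs(data.frame(donor_id = "d70", seq = donor70),
                          genome, gend)
    expect_identical(nrow(tr70), 0L)

    # partial-coverage acceptance: clean 85 nt core, noisy 15 nt tail
    donor85 <- paste0(substr(donor_exact, 1, 85),
                      plant_mm(substr(donor_exact, 86, 100), 9L))
    tr85 <- transfer_utrs(data.frame(donor_id = "d85", seq = donor85),
                          genome, gend)
    expect_identical(nrow(tr85), 1L)
    expect_lt(tr85$coverage, 1)
    expect_gte(tr85$coverage, 0.8)
})

test_that("UTR transfer is invariant to donor order and merges unigene records", {
    set.seed(62)
    genome <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
    gend <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                       end = c(500L, 1800L), strand = "+")
    donors <- data.frame(
        donor_id = c("a", "b"),
        seq = c(substr(genome, 551, 630), substr(genome, 1851, 1930)),
        stringsAsFactors = FALSE)
    t1 <- transfer_utrs(donors, genome, gend)
    t2 <- transfer_utrs(donors[2:1, ], genome, gend)
    rownames(t1) <- rownames(t2) <- NULL
    expect_identical(t1, t2)
    expect_true(all(diff(t1$start) > 0))

    uni <- data.frame(gene = "g9", seq = "ACGTACGTACGTACGTACGTACGTACGT")
    merged <- merge_utrs(t1, uni)
    expect_identical(nrow(merged), nrow(t1) + 1L)
    expect_identical(merged$source[nrow(merged)], "unigene")
})

test_that("target prediction matches hand-built seed classes", {
    mature <- "TAGCTTATCAGACTGATGTTGA"   # starts with T: rc site can be 8mer
    site <- dna_revcomp(mature)          # full complement, ends in A
    utr <- paste0("CCGGAACCGG", site, "GGCCAAGGCC")
    hits <- predict_targets(mature, c(g1 = utr))
    expect_identical(nrow(hits), 1L)
    expect_identical(hits$seed_class, "8mer")
    expect_identical(hits$pos, 11L)
    expect_equal(hits$score, 5 * nchar(mature))
    expect_equal(hits$paired_fraction, 1)

    # one seed mismatch kills the site regardless of 3' pairing
    bad <- site
    substr(bad, nchar(bad) - 3L, nchar(bad) - 3L) <-
        setdiff(c("A", "C", "G", "T"),
                c(substr(bad, nchar(bad) - 3L, nchar(bad) - 3L), "G"))[1]
    utr_bad <- paste0("CCGGAACCGG", bad, "GGCCAAGGCC")
    expect_identical(nrow(predict_targets(mature, c(g1 = utr_bad))), 0L)

    # a single G:U wobble in the seed downgrades the class, site survives
    wob <- site
    p <- nchar(wob) - 4L                  # opposite miRNA position 5
    stopifnot(substr(mature, 5, 5) %in% c("G", "T"))
    substr(wob, p, p) <- if (substr(mature, 5, 5) == "G") "T" else "G"
    utr_wob <- paste0("CCGGAACCGG", wob, "GGCCAAGGCC")
    hw <- predict_targets(mature, c(g1 = utr_wob))
    expect_identical(hw$seed_class, "7mer-wobble")

    expect_error(predict_targets("ACGTACGT", c(g = utr)), "18-26")
})

test_that("target prediction equals the brute-force oracle on random pairs", {
    set.seed(63)
    for (i in 1:50) {
        m <- sample(18:24, 1)
        mature <- paste(sample(c("A", "C", "G", "T"), m, TRUE), collapse = "")
        utr <- paste(sample(c("A", "C", "G", "T"), sample(60:200, 1), TRUE),
                     collapse = "")
        # plant the complement at a random position half the time
        if (i %% 2 == 0) {
            at <- sample(1:(nchar(utr) - m), 1)
            utr <- paste0(substr(utr, 1, at - 1), dna_revcomp(mature),
                          substr(utr, at + m, nchar(utr)))
        }
        got <- predict_targets(mature, c(u = utr), score_min = 60)
        want <- brute_force_targets(mature, utr, score_min = 60)
        expect_identical(nrow(got), nrow(want))
        if (nrow(got)) {
            expect_identical(got$pos, want$pos)
            expect_identical(got$seed_class, want$seed_class)
            expect_equal(got$score, want$score)
        }
    }
})

test_that("reported seed patterns re-validate by direct string comparison", {
    set.seed(64)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (i in 1:20) {
        mature <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
        utr <- paste0(paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                            collapse = ""),
                      dna_revcomp(mature),
                      paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                            collapse = ""))
        hits <- predict_targets(mature, c(u = utr), score_min = 40)
        for (r in seq_len(nrow(hits))) {
            s <- hits$pos[r]; m <- nchar(mature)
            wc <- 0L; gu <- 0L
            for (pos in 2:8) {
                u <- substr(utr, s + m - pos, s + m - pos)
                b <- substr(mature, pos, pos)
                if (u == comp[[b]]) wc <- wc + 1L
                else if ((b == "G" && u == "T") || (b == "T" && u == "G"))
                    gu <- gu + 1L
            }
            if (hits$seed_class[r] %in% c("8mer", "7mer"))
                expect_identical(wc, 7L)
            else expect_identical(c(wc, gu), c(6L, 1L))
        }
    }
})

test_that("pathway tallies count genes once per pathway", {
    sites <- data.frame(mirna = c("m1", "m1", "m2", "m2"),
                        gene = c("g1", "g2", "g1", "g3"),
                        pos = 1L, seed_class = "7mer", score = 80,
                        paired_fraction = 0.9, stringsAsFactors = FALSE)
    map <- data.frame(gene = c("g1", "g2", "g3"),
                      pathway = c("P1", "P1", "P2"))
    tal <- tally_pathways(sites, map)
    expect_identical(tal$n_genes[tal$pathway == "P1"], 2L)
    expect_identical(tal$n_genes[tal$pathway == "P2"], 1L)
    expect_identical(tal$n_mirnas[tal$pathway == "P1"], 2L)

    expect_identical(nrow(tally_pathways(sites[0, ], map)), 0L)

    # unmapped genes are tallied, and the miRNA subset restricts the tally
    tal2 <- tally_pathways(sites, map[1:2, ])
    expect_identical(tal2$n_genes[tal2$pathway == "unmapped"], 1L)
    tal3 <- tally_pathways(sites, map, mirnas = "m2")
    expect_identical(sum(tal3$n_genes), 2L)
})

test_that("expression trends follow the relative-difference threshold", {
    fpkm <- rbind(flat = c(10, 10, 10, 10),
                  up = c(100, 120, 10, 12),
                  down = c(5, 6, 50, 60),
                  zero = c(0, 0, 0, 0))
    colnames(fpkm) <- c("y1", "y2", "a1", "a2")
    groups <- data.frame(sample = colnames(fpkm),
                         group = c("young", "young", "adult", "adult"))
    tr <- compare_target_expression(fpkm, rownames(fpkm), groups)
    expect_identical(tr$trend[tr$gene == "flat"], "tied")
    expect_identical(tr$trend[tr$gene == "up"], "higher_in_A")
    expect_identical(tr$trend[tr$gene == "down"], "higher_in_B")
    expect_identical(tr$trend[tr$gene == "zero"], "tied")

    miss <- compare_target_expression(fpkm, c("up", "ghost"), groups)
    expect_false(miss$present[miss$gene == "ghost"])
    expect_true(is.na(miss$trend[miss$gene == "ghost"]))

    # planted directions on a random fixture are recovered exactly
    set.seed(65)
    n <- 30L
    dir <- sample(c("higher_in_A", "higher_in_B", "tied"), n, TRUE)
    base <- runif(n, 5, 50)
    mk <- function(mu) rep(mu, 2)
    mat <- t(vapply(seq_len(n), function(i) {
        if (dir[i] == "higher_in_A") c(mk(base[i] * 2), mk(base[i]))
        else if (dir[i] == "higher_in_B") c(mk(base[i]), mk(base[i] * 2))
        else c(mk(base[i]), mk(base[i]))
    }, numeric(4)))
    rownames(mat) <- sprintf("g%02d", seq_len(n))
    colnames(mat) <- colnames(fpkm)
    got <- compare_target_expression(mat, rownames(mat), groups)
    expect_identical(got$trend, dir)
})
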