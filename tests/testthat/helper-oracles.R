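# Independent oracles and small fixture builders shared across the suite.

# Exhaustive enumeration of every non-crossing pairing (minimum loop
# respected) of a short sequence; returns the set of achievable total
# weights. Independent of the maximization DP: it collects all complete
# structures' scores rather than propagating maxima.
enum_pair_weights <- function(seq, min_loop = 3L,
                              w = c(GC = 3, AU = 2, GU = 1)) {
    ch <- strsplit(seq, "")[[1]]
    pw <- function(a, b) {
        ab <- paste0(a, b)
        if (ab %in% c("GC", "CG")) w[["GC"]]
        else if (ab %in% c("AT", "TA")) w[["AU"]]
        else if (ab %in% c("GT", "TG")) w[["GU"]]
        else 0
    }
    memo <- new.env(parent = emptyenv())
    rec <- function(i, j) {
        if (i >= j) return(0)
        key <- paste(i, j)
        if (!is.null(memo[[key]])) return(memo[[key]])
        out <- rec(i + 1L, j)            # i unpaired in every structure
        ks <- if (i + min_loop + 1L <= j) (i + min_loop + 1L):j else integer(0)
        for (k in ks) {
            wk <- pw(ch[i], ch[k])
            if (wk == 0) next
            left <- rec(i + 1L, k - 1L)
            right <- rec(k + 1L, j)
            out <- c(out, as.vector(outer(left, right, "+")) + wk)
        }
        out <- unique(out)
        memo[[key]] <- out
        out
    }
    rec(1L, length(ch))
}

enum_best_fold_score <- function(seq, min_loop = 3L) {
    max(enum_pair_weights(seq, min_loop))
}

# Score the returned dot-bracket independently: sum pair weights, and check
# structural validity (balanced, pairable bases, minimum loop).
score_structure <- function(seq, db, min_loop = 3L) {
    ch <- strsplit(seq, "")[[1]]
    p <- mirprofiler::structure_partners(db)
    stopifnot(length(p) == length(ch))
    total <- 0L
    for (i in seq_along(p)) {
        j <- p[i] + 1L
        if (is.na(p[i]) || j < i) next
        stopifnot(p[j] + 1L == i)             # mutual
        stopifnot(j - i > min_loop)           # minimum loop
        ab <- paste0(ch[i], ch[j])
        wk <- switch(ab, GC = 3L, CG = 3L, AT = 2L, TA = 2L,
                     GT = 1L, TG = 1L, 0L)
        stopifnot(wk > 0)                     # only canonical pairs
        total <- total + wk
    }
    total
}

dinuc_counts <- function(seq) {
    ch <- strsplit(seq, "")[[1]]
    if (length(ch) < 2) return(table(character(0)))
    table(paste0(ch[-length(ch)], ch[-1]))
}

# Brute-force seed-anchored target scan, written position-by-position with
# an explicit complement table (independent of the vectorized scanner).
brute_force_targets <- function(mature, utr, score_min = 60) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    mch <- strsplit(mature, "")[[1]]
    uch <- strsplit(utr, "")[[1]]
    m <- length(mch)
    hits <- list()
    if (length(uch) < m) return(data.frame())
    for (s in 1:(length(uch) - m + 1L)) {
        n_wc <- 0L; n_gu <- 0L; n_mm <- 0L
        seed_wc <- 0L; seed_gu <- 0L
        for (i in 1:m) {
            u <- uch[s + m - i]               # UTR base opposite miRNA pos i
            if (u == comp[[mch[i]]]) {
                n_wc <- n_wc + 1L
                if (i >= 2 && i <= 8) seed_wc <- seed_wc + 1L
            } else if ((mch[i] == "G" && u == "T") ||
                       (mch[i] == "T" && u == "G")) {
                n_gu <- n_gu + 1L
                if (i >= 2 && i <= 8) seed_gu <- seed_gu + 1L
            } else n_mm <- n_mm + 1L
        }
        cls <- NA_character_
        if (seed_wc == 7L) cls <- if (uch[s + m - 1] == "A") "8mer" else "7mer"
        else if (seed_wc == 6L && seed_gu == 1L) cls <- "7mer-wobble"
        sc <- 5 * n_wc + n_gu - 4 * n_mm
        if (!is.na(cls) && sc >= score_min)
            hits[[length(hits) + 1L]] <- data.frame(pos = s, seed_class = cls,
                                                    score = sc)
    }
    if (!length(hits)) return(data.frame())
    do.call(rbind, hits)
}

# A ten-read library containing one read per rejection class and five clean
# reads, with its expected cleaning ledger.
hand_fixture <- function(cfg = default_config()) {
    a3 <- cfg$adapter3
    q <- function(s) strrep("I", nchar(s))
    ins <- c("ACGTAGCTAGCTAGGCTACGAT",   # 22 nt, mixed composition
             "TGCATGCATCGGATCGTAGCAT",
             "CCGATATCGGAATTGCCGATAC",
             "GATTACCAGATTACCAGATTAC",
             "TCAGGCATCGATTCAGGACTGA")
    clean <- paste0(ins, a3)
    lowq_seq <- paste0("ACGTACGTACGTACGTACGTAC", a3)
    lowq_qual <- paste0(strrep("#", 22), strrep("I", nchar(lowq_seq) - 22))
    reads <- data.frame(
        id = sprintf("r%02d", 1:10),
        seq = c(clean,
                lowq_seq,                               # low quality
                paste0(cfg$adapter5, ins[1], a3),       # 5' contaminant
                "ACGGTTCAAGCCTTGGAACCGTTAGCCAATTGGCC",  # no 3' adapter
                paste0(strrep("A", 22), a3),            # polyN
                paste0("ACGTACGTACGT", a3)),            # 12 nt insert
        qual = c(q(clean[1]), q(clean[2]), q(clean[3]), q(clean[4]),
                 q(clean[5]), lowq_qual,
                 q(paste0(cfg$adapter5, ins[1], a3)),
                 q("ACGGTTCAAGCCTTGGAACCGTTAGCCAATTGGCC"),
                 q(paste0(strrep("A", 22), a3)),
                 q(paste0("ACGTACGTACGT", a3))),
        stringsAsFactors = FALSE)
    truth <- c(rep("clean", 5), "low_quality", "adapter5", "no_adapter3",
               "polyN", "short")
    list(reads = reads, truth = truth)
}

# Random read fixture (not guaranteed clean) for ledger-partition checks.
random_fixture <- function(n, cfg = default_config()) {
    base <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(n), function(i) {
        len <- sample(8:40, 1)
        ins <- paste(sample(base, len, replace = TRUE), collapse = "")
        if (stats::runif(1) < 0.7) paste0(ins, cfg$adapter3) else ins
    }, character(1))
    quals <- vapply(nchar(seqs), function(L) {
        paste(sample(c("#", "5", "I"), L, replace = TRUE,
                     prob = c(0.2, 0.2, 0.6)), collapse = "")
    }, character(1))
    data.frame(id = sprintf("x%04d", seq_len(n)), seq = seqs, qual = quals,
               stringsAsFactors = FALSE)
}
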