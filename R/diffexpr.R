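# Differential expression between two sequencing libraries: reads-per-
# million normalization, zero substitution, low-expression exclusion, log2
# fold change, and the exact two-library count statistic (Audic-Claverie)
# with both cumulative tails.

#' Normalized expression (reads per million)
#'
#' `NE = count / total * 1e6`.
#'
#' @param count miRNA read count (0 <= count <= total).
#' @param total total clean reads in the library (>= 1).
#' @return normalized expression, reads per million.
#' @export
normalize_expression <- function(count, total) {
    if (any(total < 1)) stop("library total must be >= 1")
    if (any(count < 0) || any(count > total))
        stop("count must satisfy 0 <= count <= total")
    count / total * 1e6
}

#' Zero substitution and low-expression exclusion
#'
#' Exact zeros are replaced by `ne_floor` (so the fold change stays
#' finite); the pair is excluded from testing when its normalized
#' expressions fall below `ne_exclusion` — in both libraries
#' (`mode = "both"`, the default) or in at least one (`mode = "either"`).
#' The boundary is strict: NE exactly 1 is not "less than 1" and is kept.
#'
#' @param ne1,ne2 normalized expressions of the two libraries.
#' @param ne_floor substitute for exact zeros (default 0.01).
#' @param ne_exclusion exclusion boundary (default 1).
#' @param mode `"both"` or `"either"`.
#' @return list with `ne1`, `ne2` (adjusted) and `status` (one of
#'   `tested`, `zero_substituted`, `excluded_low_NE`).
#' @export
preprocess_pair <- function(ne1, ne2, ne_floor = 0.01, ne_exclusion = 1,
                            mode = c("both", "either")) {
    mode <- match.arg(mode)
    stopifnot(ne1 >= 0, ne2 >= 0)
    subbed <- ne1 == 0 || ne2 == 0
    if (ne1 == 0) ne1 <- ne_floor
    if (ne2 == 0) ne2 <- ne_floor
    low1 <- ne1 < ne_exclusion; low2 <- ne2 < ne_exclusion
    excluded <- if (mode == "both") low1 && low2 else low1 || low2
    status <- if (excluded) "excluded_low_NE"
              else if (subbed) "zero_substituted"
              else "tested"
    list(ne1 = ne1, ne2 = ne2, status = status)
}

#' Log2 fold change
#'
#' `log2(NE_young / NE_adult)` (first argument over second).
#'
#' @param ne_young,ne_adult positive normalized expressions
#'   (post-substitution).
#' @return log2 fold change.
#' @export
log2_fold_change <- function(ne_young, ne_adult) {
    if (any(ne_young <= 0) || any(ne_adult <= 0))
        stop("fold change requires positive normalized expressions")
    log2(ne_young / ne_adult)
}

#' Exact two-library count probability mass
#'
#' The probability of observing `y` counts in a library of depth `N2` given
#' `x` counts in a library of depth `N1`, under a shared Poisson rate:
#' `p(y|x) = (N2/N1)^y * (x+y)! / (x! y!) / (1 + N2/N1)^(x+y+1)`,
#' computed in log-gamma space. Vectorized over `y`.
#'
#' @param y counts in library 2 (non-negative integers; vectorized).
#' @param x count in library 1 (non-negative integer).
#' @param N1,N2 library totals (>= 1).
#' @return probability mass at each `y`.
#' @export
ac_pmf <- function(y, x, N1, N2) {
    if (any(y < 0) || x < 0 || any(y != floor(y)) || x != floor(x))
        stop("x and y must be non-negative integers")
    if (N1 < 1 || N2 < 1) stop("library totals must be >= 1")
    r <- N2 / N1
    exp(y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(r))
}

#' Cumulative tails of the exact two-library statistic
#'
#' `C = sum_{y=0..y_obs} p(y|x)` (lower tail),
#' `D = 1 - sum_{y=0..y_obs-1} p(y|x)` (upper tail, computed by
#' complement), and the two-sided p-value `min(1, 2 min(C, D))`.
#' `C + D = 1 + p(y_obs|x)` by construction.
#'
#' @param x count in library 1.
#' @param y_obs observed count in library 2.
#' @param N1,N2 library totals.
#' @return list with `C`, `D`, `p_two_sided`.
#' @export
ac_tails <- function(x, y_obs, N1, N2) {
    pm <- ac_pmf(0:y_obs, x, N1, N2)
    C <- sum(pm)
    D <- 1 - (C - pm[y_obs + 1L])
    C <- min(1, C); D <- min(1, max(0, D))
    list(C = C, D = D, p_two_sided = min(1, 2 * min(C, D)))
}

#' Pairwise and consensus differential expression calls
#'
#' Tests every between-group sample pair with the exact two-library
#' statistic on raw counts, applying the normalization, zero-substitution
#' and exclusion rules first. A miRNA is significant in a pair when its
#' two-sided p-value is below `de_p_threshold`, its absolute log2 fold
#' change is at least `de_lfc_threshold`, and the pair was not excluded.
#' A miRNA is a consensus call for the contrast when it is significant with
#' the same fold-change sign in all pairs.
#'
#' @param em an `expression_matrix` from [build_expression_matrix()], or a
#'   list with `counts` (miRNA x sample) and `totals`.
#' @param groups data.frame with `sample` and `group` columns; `contrast`
#'   names the two group levels, fold changes are
#'   `log2(NE[contrast[1]] / NE[contrast[2]])`.
#' @param contrast character vector of two group levels (default the two
#'   levels in `groups$group`, first-appearing first).
#' @param config pipeline configuration (thresholds and exclusion rules).
#' @return list with `pairwise` (one row per miRNA per sample pair) and
#'   `consensus` (per miRNA: `n_pairs`, `n_significant`, `direction` in
#'   `up`/`down`/`none`, `consensus` logical).
#' @export
call_differential <- function(em, groups, contrast = NULL,
                              config = default_config()) {
    counts <- em$counts; totals <- em$totals
    if (!all(groups$sample %in% colnames(counts)))
        stop("unknown sample in grouping: ",
             paste(setdiff(groups$sample, colnames(counts)), collapse = ", "))
    if (is.null(contrast)) contrast <- unique(groups$group)
    if (length(contrast) != 2L) stop("contrast must name two groups")
    s1 <- groups$sample[groups$group == contrast[1]]
    s2 <- groups$sample[groups$group == contrast[2]]
    if (!length(s1) || !length(s2)) stop("each contrast group needs >= 1 sample")
    mirnas <- rownames(counts)
    rows <- list(); k <- 0L
    for (a in s1) for (b in s2) {
        N1 <- totals[[a]]; N2 <- totals[[b]]
        for (m in mirnas) {
            x <- counts[m, a]; y <- counts[m, b]
            ne1 <- normalize_expression(x, N1)
            ne2 <- normalize_expression(y, N2)
            pp <- preprocess_pair(ne1, ne2, config$ne_floor_substitute,
                                  config$ne_exclusion,
                                  config$ne_exclusion_mode)
            lfc <- log2_fold_change(pp$ne1, pp$ne2)
            if (pp$status == "excluded_low_NE") {
                tails <- list(C = NA_real_, D = NA_real_,
                              p_two_sided = NA_real_)
                sig <- FALSE
            } else {
                tails <- ac_tails(x, y, N1, N2)
                sig <- tails$p_two_sided < config$de_p_threshold &&
                    abs(lfc) >= config$de_lfc_threshold
            }
            k <- k + 1L
            rows[[k]] <- data.frame(
                mirna = m, sample1 = a, sample2 = b,
                count1 = x, count2 = y, NE1 = pp$ne1, NE2 = pp$ne2,
                log2fc = lfc, p_down = tails$C, p_up = tails$D,
                p_two_sided = tails$p_two_sided,
                status = pp$status, significant = sig,
                stringsAsFactors = FALSE)
        }
    }
    pairwise <- do.call(rbind, rows)
    cons <- lapply(mirnas, function(m) {
        sub <- pairwise[pairwise$mirna == m, , drop = FALSE]
        nsig <- sum(sub$significant)
        all_up <- all(sub$significant & sub$log2fc > 0)
        all_dn <- all(sub$significant & sub$log2fc < 0)
        direction <- if (all_up) "up" else if (all_dn) "down" else "none"
        data.frame(mirna = m, n_pairs = nrow(sub), n_significant = nsig,
                   direction = direction, consensus = all_up || all_dn,
                   stringsAsFactors = FALSE)
    })
    list(pairwise = pairwise, consensus = do.call(rbind, cons),
         contrast = contrast)
}
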