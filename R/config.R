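#' Default pipeline configuration
#'
#' Returns the full set of tunable pipeline parameters with their default
#' values. The cleaning thresholds (Phred floor 5, 50\% low-quality fraction,
#' 18 nt length floor, 80\% single-nucleotide content), the genome mapping
#' mismatch budget (1), the novel-miRNA reporting score (5), the
#' differential-expression rules (zero substitution 0.01, exclusion boundary
#' 1 NE, reads-per-million scale) and the 3'UTR transfer rules (2 mismatches,
#' 80\% coverage) follow the standard blood small-RNA protocol this package
#' implements; everything is overridable.
#'
#' @param ... named overrides for any configuration key.
#' @return A named list of class `mirprof_config`.
#' @examples
#' cfg <- default_config(min_length = 20L)
#' cfg$min_length
#' @export
default_config <- function(...) {
    cfg <- list(
        phred_offset         = 33L,
        quality_floor        = 5L,
        low_quality_fraction = 0.5,
        min_length           = 18L,
        polyN_fraction       = 0.8,
        adapter3             = "TGGAATTCTCGGGTGCCAAGG",
        adapter5             = "GTTCAGAGTTCTACAGTCCGACGATC",
        adapter_min_overlap  = 6L,
        adapter_max_mismatch = 1L,
        map_max_mismatch     = 1L,
        conserved_tolerance  = 2L,
        report_score_min     = 5,
        shuffle_count        = 100L,
        shuffle_alpha        = 0.05,
        stack_max_gap        = 25L,
        excise_flank         = 70L,
        min_window           = 40L,
        utr_max_mismatch     = 2L,
        utr_min_coverage     = 0.8,
        utr_proximity        = 1000L,
        target_score_min     = 60,
        ne_floor_substitute  = 0.01,
        ne_exclusion         = 1.0,
        ne_exclusion_mode    = "both",
        de_p_threshold       = 0.01,
        de_lfc_threshold     = 1.0,
        trend_threshold      = 0.2,
        rng_seed             = 1L
    )
    ov <- list(...)
    if (length(ov)) {
        bad <- setdiff(names(ov), names(cfg))
        if (length(bad))
            stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
        cfg[names(ov)] <- ov
    }
    class(cfg) <- "mirprof_config"
    validate_config(cfg)
    cfg
}

#' Validate a pipeline configuration
#'
#' Checks the structural invariants: proportions in \[0, 1\], count
#' thresholds non-negative, adapters non-empty over the A/C/G/T/N alphabet.
#'
#' @param cfg a configuration list as returned by [default_config()].
#' @return `cfg`, invisibly; errors when an invariant is violated.
#' @export
validate_config <- function(cfg) {
    props <- c("low_quality_fraction", "polyN_fraction", "utr_min_coverage",
               "shuffle_alpha")
    for (p in props) {
        v <- cfg[[p]]
        if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
            stop(p, " must be a proportion in [0, 1]")
    }
    counts <- c("quality_floor", "min_length", "map_max_mismatch",
                "shuffle_count", "utr_max_mismatch", "adapter_min_overlap",
                "adapter_max_mismatch", "conserved_tolerance", "stack_max_gap",
                "excise_flank", "min_window", "utr_proximity")
    for (p in counts) {
        v <- cfg[[p]]
        if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
            stop(p, " must be a non-negative count")
    }
    for (a in c("adapter3", "adapter5")) {
        v <- cfg[[a]]
        if (!is.character(v) || length(v) != 1L || nchar(v) == 0L ||
            grepl("[^ACGTN]", v))
            stop(a, " must be a non-empty string over {A,C,G,T,N}")
    }
    if (!cfg$ne_exclusion_mode %in% c("both", "either"))
        stop("ne_exclusion_mode must be 'both' or 'either'")
    invisible(cfg)
}

#' Write a configuration to a flat key=value file
#'
#' @param cfg a configuration list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
    lines <- vapply(names(cfg), function(k) {
        v <- cfg[[k]]
        paste0(k, "=", format(v, scientific = FALSE, trim = TRUE))
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a configuration from a flat key=value file
#'
#' Values are coerced to the type of the corresponding default; a written
#' configuration round-trips identically.
#'
#' @param path input file path.
#' @return a configuration list of class `mirprof_config`.
#' @export
read_config <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
    keys <- vapply(kv, `[`, character(1), 1L)
    vals <- vapply(kv, `[`, character(1), 2L)
    ref <- default_config()
    ov <- list()
    for (i in seq_along(keys)) {
        k <- trimws(keys[i]); v <- trimws(vals[i])
        if (!k %in% names(ref)) stop("unknown configuration key: ", k)
        ov[[k]] <- if (is.integer(ref[[k]])) as.integer(v)
                   else if (is.numeric(ref[[k]])) as.numeric(v)
                   else v
    }
    do.call(default_config, ov)
}
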