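# Four-step read cleaning: quality -> adapters -> poly-nucleotide -> length,
# applied in that order, with a stats ledger that partitions the input.

#' Low-quality read filter
#'
#' A read is rejected when the fraction of bases with Phred score strictly
#' below `quality_floor` is at least `low_quality_fraction` of the read.
#'
#' @param read a one-row data.frame (or list) with `seq` and `qual`.
#' @param quality_floor Phred threshold (bases below it count as low quality).
#' @param low_quality_fraction rejection fraction (default 0.5).
#' @param phred_offset quality encoding offset.
#' @return `TRUE` to keep, `FALSE` to reject.
#' @export
filter_low_quality <- function(read, quality_floor = 5L,
                               low_quality_fraction = 0.5,
                               phred_offset = 33L) {
    frac <- cpp_low_quality_frac(read$qual, phred_offset, quality_floor)
    frac < low_quality_fraction
}

#' Adapter trimming with 5'-contaminant rejection
#'
#' Rejects reads whose start matches the 5' adapter (within
#' `max_mismatch` over the overlap) and reads in which no 3' adapter
#' occurrence is found (full internal match, or a terminal overlap of at
#' least `min_overlap` nt of the adapter prefix, within `max_mismatch`).
#' Otherwise returns the insert upstream of the leftmost 3'-adapter match.
#'
#' @param read a one-row data.frame (or list) with `seq`.
#' @param adapter3,adapter5 adapter sequences.
#' @param min_overlap minimum terminal overlap for the 3' adapter.
#' @param max_mismatch mismatch tolerance for both adapters.
#' @return list with `insert` (character or `NA`) and `reason`
#'   (`NA`, `"adapter5"`, or `"no_adapter3"`).
#' @export
trim_adapters <- function(read, adapter3, adapter5,
                          min_overlap = 6L, max_mismatch = 1L) {
    if (cpp_match_prefix(read$seq, adapter5, min_overlap, max_mismatch))
        return(list(insert = NA_character_, reason = "adapter5"))
    pos <- cpp_find_adapter3(read$seq, adapter3, min_overlap, max_mismatch)
    if (pos == 0L)
        return(list(insert = NA_character_, reason = "no_adapter3"))
    list(insert = substr(read$seq, 1L, pos - 1L), reason = NA_character_)
}

#' Poly-nucleotide filter
#'
#' Rejects an insert when any single nucleotide accounts for at least
#' `polyN_fraction` of its bases.
#'
#' @param insert character vector of trimmed inserts.
#' @param polyN_fraction content threshold (default 0.8).
#' @return logical vector, `TRUE` to keep.
#' @export
filter_polyN <- function(insert, polyN_fraction = 0.8) {
    stopifnot(all(nchar(insert) > 0L))
    max_base_frac(insert) < polyN_fraction
}

#' Minimum-length filter
#'
#' @param insert character vector of trimmed inserts.
#' @param min_length minimum insert length kept (default 18 nt; an 18 nt
#'   insert is kept, 17 nt is rejected).
#' @return logical vector, `TRUE` to keep.
#' @export
filter_length <- function(insert, min_length = 18L) {
    nchar(insert) >= min_length
}

#' Clean a sequencing library
#'
#' Applies the four filters in order — low quality, adapters (5'
#' contaminant or missing 3' adapter), poly-nucleotide content of the
#' trimmed insert, insert length — and returns the clean inserts together
#' with a stats ledger that exactly partitions the input.
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param config pipeline configuration, see [default_config()].
#' @return list with:
#'   \describe{
#'     \item{clean}{data.frame `id`, `insert` of surviving reads}
#'     \item{stats}{one-row data.frame: `input_reads`,
#'       `removed_low_quality`, `removed_adapter`, `removed_polyN`,
#'       `removed_short`, `clean_total`, `unique_count`}
#'     \item{per_read}{data.frame `id`, `fate` (clean / low_quality /
#'       adapter5 / no_adapter3 / polyN / short), `insert`}
#'   }
#' @export
clean_library <- function(reads, config = default_config()) {
    n <- nrow(reads)
    fate <- rep("clean", n)
    insert <- rep(NA_character_, n)
    if (n > 0L) {
        lowq <- cpp_low_quality_frac(reads$qual, config$phred_offset,
                                     config$quality_floor) >=
            config$low_quality_fraction
        fate[lowq] <- "low_quality"

        live <- which(!lowq)
        if (length(live)) {
            a5 <- cpp_match_prefix(reads$seq[live], config$adapter5,
                                   config$adapter_min_overlap,
                                   config$adapter_max_mismatch)
            fate[live[a5]] <- "adapter5"
            live <- live[!a5]
        }
        if (length(live)) {
            pos <- cpp_find_adapter3(reads$seq[live], config$adapter3,
                                     config$adapter_min_overlap,
                                     config$adapter_max_mismatch)
            fate[live[pos == 0L]] <- "no_adapter3"
            hit <- pos > 0L
            insert[live[hit]] <- substr(reads$seq[live[hit]], 1L,
                                        pos[hit] - 1L)
            live <- live[hit]
        }
        if (length(live)) {
            # empty inserts (adapter at the very start) go to the length filter
            nonempty <- nchar(insert[live]) > 0L
            pn <- rep(FALSE, length(live))
            pn[nonempty] <- !filter_polyN(insert[live[nonempty]],
                                          config$polyN_fraction)
            fate[live[pn]] <- "polyN"
            live <- live[!pn]
        }
        if (length(live)) {
            short <- !filter_length(insert[live], config$min_length)
            fate[live[short]] <- "short"
            live <- live[!short]
        }
    }
    clean <- data.frame(id = reads$id[fate == "clean"],
                        insert = insert[fate == "clean"],
                        stringsAsFactors = FALSE)
    stats <- data.frame(
        input_reads = n,
        removed_low_quality = sum(fate == "low_quality"),
        removed_adapter = sum(fate %in% c("adapter5", "no_adapter3")),
        removed_polyN = sum(fate == "polyN"),
        removed_short = sum(fate == "short"),
        clean_total = nrow(clean),
        unique_count = length(unique(clean$insert)))
    list(clean = clean, stats = stats,
         per_read = data.frame(id = reads$id, fate = fate, insert = insert,
                               stringsAsFactors = FALSE))
}

#' Collapse clean reads to unique tags with counts
#'
#' One row per distinct insert sequence; counts sum to the number of clean
#' reads ("total number" vs "unique number" semantics of a library summary).
#'
#' @param inserts character vector of clean insert sequences, or the `clean`
#'   data.frame from [clean_library()].
#' @return data.frame with `insert`, `count`, ordered by decreasing count
#'   then sequence.
#' @export
collapse_unique <- function(inserts) {
    if (is.data.frame(inserts)) inserts <- inserts$insert
    if (!length(inserts))
        return(data.frame(insert = character(), count = integer(),
                          stringsAsFactors = FALSE))
    tab <- table(inserts)
    out <- data.frame(insert = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out[order(-out$count, out$insert), , drop = FALSE]
}

#' Insert length histogram
#'
#' Frequency distribution of clean-read lengths, over reads and over unique
#' tags.
#'
#' @param tags a unique-tag data.frame from [collapse_unique()].
#' @return data.frame with `length`, `reads`, `tags`.
#' @export
length_histogram <- function(tags) {
    len <- nchar(tags$insert)
    agg <- stats::aggregate(cbind(reads = tags$count,
                                  tags = rep(1L, nrow(tags))),
                            by = list(length = len), FUN = sum)
    agg[order(agg$length), , drop = FALSE]
}

#' Cross-sample tag sharing summary
#'
#' For a set of per-sample unique-tag tables, the fraction of total reads
#' carried by tags present in every sample, and the fraction of unique tags
#' present in every sample.
#'
#' @param tag_tables named list of [collapse_unique()] outputs.
#' @return one-row data.frame with `shared_read_fraction`,
#'   `shared_tag_fraction`, `n_tags_union`, `n_tags_shared`.
#' @export
sharing_summary <- function(tag_tables) {
    sets <- lapply(tag_tables, function(t) t$insert)
    shared <- Reduce(intersect, sets)
    union_tags <- unique(unlist(sets))
    total <- sum(vapply(tag_tables, function(t) sum(t$count), numeric(1)))
    shared_reads <- sum(vapply(tag_tables, function(t)
        sum(t$count[t$insert %in% shared]), numeric(1)))
    data.frame(shared_read_fraction = if (total > 0) shared_reads / total else 0,
               shared_tag_fraction = if (length(union_tags))
                   length(shared) / length(union_tags) else 0,
               n_tags_union = length(union_tags),
               n_tags_shared = length(shared))
}
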