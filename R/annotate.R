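# Hierarchical non-miRNA annotation. A small-RNA tag is assigned to the
# highest-priority category whose reference contains it as a (reverse-
# complement aware) substring; unassigned tags go forward as miRNA
# candidates.

#' The fixed annotation priority order
#'
#' rRNA > tRNA > scRNA > snRNA > snoRNA > repeat > exon > intron; every tag
#' receives exactly one annotation.
#'
#' @return character vector of categories, highest priority first.
#' @export
annotation_priority <- function() NONMIRNA_CATEGORIES

#' Build an annotation reference database
#'
#' @param seqs character vector of reference sequences.
#' @param category category label per sequence (one of the eight priority
#'   categories).
#' @param name optional entry names.
#' @return data.frame of class `annotation_db`.
#' @export
annotation_db <- function(seqs, category, name = NULL) {
    bad <- setdiff(unique(category), NONMIRNA_CATEGORIES)
    if (length(bad))
        stop("unknown annotation category: ", paste(bad, collapse = ", "))
    if (is.null(name)) name <- paste0(category, "_", seq_along(seqs))
    db <- data.frame(name = name, category = category, seq = toupper(seqs),
                     stringsAsFactors = FALSE)
    class(db) <- c("annotation_db", "data.frame")
    db
}

#' Annotation database from a synthetic truth
#'
#' @param truth a `sim_truth` from [build_truth()].
#' @return an `annotation_db` of the planted non-miRNA locus sequences.
#' @export
truth_annotation_db <- function(truth) {
    seqs <- substring(truth$genome, truth$nonmirna$start + 1L,
                      truth$nonmirna$end)
    annotation_db(seqs, truth$nonmirna$category, truth$nonmirna$locus)
}

# Substring containment of the tag (or its reverse complement) in any entry
# of one category. Concatenating entries with '|' (outside the alphabet) is
# safe for fixed-string search.
category_hit <- function(tags, entries, max_mismatch = 0L,
                         revcomp = TRUE) {
    if (!length(entries)) return(rep(FALSE, length(tags)))
    if (max_mismatch == 0L) {
        subject <- paste(entries, collapse = "|")
        hit <- vapply(tags, grepl, logical(1), x = subject, fixed = TRUE,
                      USE.NAMES = FALSE)
        if (revcomp) {
            rc <- dna_revcomp(tags)
            hit <- hit | vapply(rc, grepl, logical(1), x = subject,
                                fixed = TRUE, USE.NAMES = FALSE)
        }
        return(hit)
    }
    subs <- lapply(entries, Biostrings::DNAString)
    probes <- if (revcomp) Map(c, tags, dna_revcomp(tags)) else
        lapply(tags, identity)
    vapply(probes, function(pr) {
        for (p in pr) for (s in subs) {
            if (length(Biostrings::matchPattern(p, s,
                                                max.mismatch = max_mismatch)) > 0L)
                return(TRUE)
        }
        FALSE
    }, logical(1), USE.NAMES = FALSE)
}

#' Assign a unique tag to an annotation category
#'
#' Categories are tried in priority order; the first whose reference
#' contains the tag (default: exact substring, reverse complement included)
#' wins. Tags matching nothing are `"candidate"` miRNAs.
#'
#' @param tag a single tag sequence.
#' @param db an `annotation_db`.
#' @param max_mismatch substitution budget for containment (default 0).
#' @param revcomp also match the reverse complement (default `TRUE`).
#' @return the category, or `"candidate"`.
#' @export
assign_category <- function(tag, db, max_mismatch = 0L, revcomp = TRUE) {
    annotate_tags(data.frame(insert = tag, count = 1L), db,
                  max_mismatch = max_mismatch, revcomp = revcomp)$category
}

#' Annotate a unique-tag table
#'
#' @param tags a unique-tag data.frame (`insert`, `count`).
#' @param db an `annotation_db`.
#' @param max_mismatch substitution budget for containment (default 0).
#' @param revcomp also match reverse complements (default `TRUE`).
#' @return `tags` with an added `category` column (a priority category or
#'   `"candidate"`).
#' @export
annotate_tags <- function(tags, db, max_mismatch = 0L, revcomp = TRUE) {
    bad <- setdiff(unique(db$category), NONMIRNA_CATEGORIES)
    if (length(bad))
        stop("unknown annotation category: ", paste(bad, collapse = ", "))
    cat_out <- rep("candidate", nrow(tags))
    open <- rep(TRUE, nrow(tags))
    for (cat in NONMIRNA_CATEGORIES) {
        if (!any(open)) break
        entries <- db$seq[db$category == cat]
        if (!length(entries)) next
        hit <- category_hit(tags$insert[open], entries, max_mismatch, revcomp)
        cat_out[which(open)[hit]] <- cat
        open[which(open)[hit]] <- FALSE
    }
    tags$category <- cat_out
    tags
}

#' Per-category tag and read proportions
#'
#' Proportions are reported over unique tags and over total reads; each sums
#' to 1 including the `"candidate"` class.
#'
#' @param assignments an annotated tag table from [annotate_tags()].
#' @return data.frame with `category`, `n_tags`, `n_reads`, `tag_prop`,
#'   `read_prop`.
#' @export
summarize_categories <- function(assignments) {
    lev <- c(NONMIRNA_CATEGORIES, "candidate")
    f <- factor(assignments$category, levels = lev)
    n_tags <- as.integer(table(f))
    n_reads <- as.numeric(tapply(assignments$count, f, sum, default = 0))
    tot_tags <- sum(n_tags); tot_reads <- sum(n_reads)
    data.frame(category = lev, n_tags = n_tags, n_reads = n_reads,
               tag_prop = if (tot_tags > 0) n_tags / tot_tags else 0,
               read_prop = if (tot_reads > 0) n_reads / tot_reads else 0,
               stringsAsFactors = FALSE)
}
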