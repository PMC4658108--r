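# Dinucleotide-preserving sequence shuffling (Altschul–Erickson Euler-walk
# construction) and dot-bracket utilities.

#' Dinucleotide-preserving shuffle
#'
#' Generates a random permutation of the sequence that preserves all
#' dinucleotide counts (and hence mononucleotide counts, the first and the
#' last base), by drawing a random Eulerian walk over the dinucleotide
#' multigraph: for every vertex except the terminal one a random "last
#' edge" is drawn and accepted only if the last edges form a tree into the
#' terminal vertex, then the remaining edges are permuted.
#'
#' @param seq a single sequence string.
#' @param seed optional RNG seed for a deterministic shuffle.
#' @return a shuffled sequence string.
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
    run <- function() {
        s <- strsplit(seq, "")[[1]]
        n <- length(s)
        if (n < 3L) return(seq)
        verts <- unique(s)
        last <- s[n]
        edges <- split(s[-1L], factor(s[-n], levels = verts))
        if (length(verts) > 1L) {
            for (rep in seq_len(1000L)) {
                pick <- vapply(verts, function(v) {
                    if (v == last || !length(edges[[v]])) return(NA_character_)
                    ev <- edges[[v]]
                    ev[sample.int(length(ev), 1L)]
                }, character(1))
                # each vertex must reach the terminal vertex via picks
                ok <- TRUE
                for (v in verts) {
                    if (v == last || !length(edges[[v]])) next
                    seen <- character(0); cur <- v
                    while (cur != last) {
                        if (cur %in% seen || is.na(pick[[cur]])) { ok <- FALSE; break }
                        seen <- c(seen, cur)
                        cur <- pick[[cur]]
                    }
                    if (!ok) break
                }
                if (ok) break
            }
            if (!ok) stop("dinucleotide shuffle: no spanning arborescence found")
            for (v in verts) {
                ev <- edges[[v]]
                if (!length(ev)) next
                if (v != last && !is.na(pick[[v]])) {
                    drop1 <- match(pick[[v]], ev)
                    rest <- ev[-drop1]
                    edges[[v]] <- c(rest[sample.int(length(rest))], pick[[v]])
                } else {
                    edges[[v]] <- ev[sample.int(length(ev))]
                }
            }
        }
        ptr <- stats::setNames(rep(1L, length(verts)), verts)
        out <- character(n)
        out[1L] <- s[1L]
        cur <- s[1L]
        for (i in 2:n) {
            nxt <- edges[[cur]][ptr[[cur]]]
            ptr[[cur]] <- ptr[[cur]] + 1L
            out[i] <- nxt
            cur <- nxt
        }
        paste(out, collapse = "")
    }
    if (is.null(seed)) run() else with_seed(seed, run())
}

#' Pairing partners of a dot-bracket structure
#'
#' @param db a dot-bracket string.
#' @return integer vector, 0-based partner index per position (`NA` when
#'   unpaired).
#' @export
structure_partners <- function(db) {
    v <- strsplit(db, "")[[1]]
    p <- rep(NA_integer_, length(v))
    stack <- integer(0)
    for (i in seq_along(v)) {
        if (v[i] == "(") stack <- c(stack, i)
        else if (v[i] == ")") {
            j <- stack[length(stack)]
            stack <- stack[-length(stack)]
            p[i] <- j - 1L
            p[j] <- i - 1L
        }
    }
    p
}
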