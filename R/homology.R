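# Reciprocal-best-hit homolog selection from BLAST tabular output.

#' Read BLAST tabular (outfmt 6) output
#'
#' Parses the 12-column tab-separated format produced by `blastp -outfmt 6`
#' and friends: qseqid, sseqid, pident, length, mismatch, gapopen, qstart,
#' qend, sstart, send, evalue, bitscore. Lines starting with `#` are
#' ignored.
#'
#' @param path Path to a tabular hit file.
#' @return A data.frame with one row per hit and typed columns
#'   (`query_id`, `subject_id`, `percent_identity`, `alignment_length`,
#'   `mismatches`, `gap_opens`, `q_start`, `q_end`, `s_start`, `s_end`,
#'   `evalue`, `bitscore`).
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cols <- c("query_id", "subject_id", "percent_identity",
            "alignment_length", "mismatches", "gap_opens",
            "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore")
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  empty <- function() {
    df <- as.data.frame(setNames(rep(list(character(0)), 12), cols))
    for (j in 3:12) df[[j]] <- numeric(0)
    df
  }
  if (!any(keep)) return(empty())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(keep)[which(nf != 12L)[1]]
    stop("line ", bad, ": expected 12 tab-separated fields, found ",
         nf[which(nf != 12L)[1]])
  }
  m <- do.call(rbind, fields)
  df <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                   stringsAsFactors = FALSE)
  num <- apply(m[, 3:12, drop = FALSE], 2, as.numeric)
  if (is.null(dim(num))) num <- matrix(num, nrow = 1)
  colnames(num) <- cols[3:12]
  df <- cbind(df, as.data.frame(num))
  if (any(!is.finite(df$evalue)) || any(df$evalue < 0))
    stop("non-finite or negative e-value in ", path)
  if (any(df$q_start > df$q_end))
    stop("q_start > q_end in ", path)
  df
}

#' Filter hits by e-value threshold
#'
#' Retains hits with `evalue <= e_max`. The comparison is inclusive,
#' matching the semantics of search-tool `-evalue` cutoffs.
#'
#' @param hits Data.frame from [read_blast_tab()].
#' @param e_max Maximum e-value to retain (default `1e-5`).
#' @return The retained rows of `hits`.
#' @export
filter_by_evalue <- function(hits, e_max = 1e-5) {
  stopifnot(is.data.frame(hits), is.numeric(e_max), length(e_max) == 1L)
  if (!is.finite(e_max) || e_max <= 0) stop("e_max must be > 0")
  hits[hits$evalue <= e_max, , drop = FALSE]
}

#' Best subject per query
#'
#' Collapses multiple HSPs per query-subject pair to the single
#' best-bitscore record, then selects, per query, the subject with
#' maximal bitscore. Ties are broken by smaller e-value, then by
#' lexicographically smaller subject id.
#'
#' @param hits Data.frame of (filtered) hits.
#' @return A named character vector mapping `query_id` to the best
#'   `subject_id`.
#' @export
best_hit_per_query <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) return(setNames(character(0), character(0)))
  # order so the preferred record per query comes first:
  # bitscore desc, evalue asc, subject_id asc (C collation for stability)
  o <- order(hits$query_id,
             -hits$bitscore,
             hits$evalue,
             hits$subject_id,
             method = "radix")
  h <- hits[o, , drop = FALSE]
  first <- !duplicated(h$query_id)
  setNames(h$subject_id[first], h$query_id[first])
}

#' Reciprocal best hits
#'
#' A pair (q, s) is kept iff q's best hit in the forward search is s and
#' s's best hit in the reverse search is q. Pairs are unordered: swapping
#' the two input maps returns the same set.
#'
#' @param forward_map,reverse_map Named character vectors from
#'   [best_hit_per_query()].
#' @return A data.frame with columns `gene_a`, `gene_b`, one row per
#'   reciprocal pair, with `gene_a < gene_b` lexicographically and rows
#'   sorted for determinism.
#' @export
reciprocal_best_hits <- function(forward_map, reverse_map) {
  stopifnot(is.character(forward_map), is.character(reverse_map))
  q <- names(forward_map)
  s <- unname(forward_map)
  keep <- !is.na(reverse_map[s]) & reverse_map[s] == q
  keep[is.na(keep)] <- FALSE
  a <- pmin(q[keep], s[keep])
  b <- pmax(q[keep], s[keep])
  pairs <- unique(data.frame(gene_a = a, gene_b = b,
                             stringsAsFactors = FALSE))
  pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
}

#' Write reciprocal-best-hit pairs as TSV
#'
#' @param pairs Data.frame from [reciprocal_best_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rbh_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
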