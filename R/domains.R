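# Domain-architecture handling: HMMER3 domtblout / simple TSV readers,
# significance filtering, overlap resolution, bHLH-PAS family calls and
# C-terminal region delimitation for degron scanning.
#
# Coordinates are 1-based inclusive in all on-disk formats (HMMER
# convention) and 0-based half-open internally.

# PFAM models that tile canonical bHLH-PAS proteins
.DEFAULT_DOMAIN_VOCAB <- list(
  bHLH = c("HLH"),
  PAS  = c("PAS", "PAS_3", "PAS_11", "PAC"))

#' Default domain vocabulary for bHLH-PAS calling
#'
#' Named list with elements `bHLH` and `PAS` giving the PFAM model names
#' counted as basic helix-loop-helix and PAS-sensor class respectively.
#' @return The default vocabulary list.
#' @export
default_domain_vocab <- function() .DEFAULT_DOMAIN_VOCAB

.new_domain_hits <- function(protein_id, domain_name, start, end, evalue,
                             bitscore) {
  df <- data.frame(protein_id = protein_id, domain_name = domain_name,
                   start = as.integer(start), end = as.integer(end),
                   evalue = as.numeric(evalue),
                   bitscore = as.numeric(bitscore),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("domain with start >= end")
  if (any(df$evalue < 0)) stop("negative domain e-value")
  df
}

#' Read HMMER3 per-domain tabular output (domtblout)
#'
#' Whitespace-delimited parse tolerant of free-text description fields
#' (only the first 22 columns are positional). Envelope coordinates
#' (columns 20-21, 1-based inclusive) are converted to 0-based half-open;
#' the independent e-value (column 13) and per-domain bitscore (column
#' 14) are kept.
#'
#' @param path Path to a domtblout file.
#' @return Data.frame with columns `protein_id`, `domain_name`, `start`,
#'   `end` (0-based half-open), `evalue`, `bitscore`.
#' @export
read_domtblout <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L)
    return(.new_domain_hits(character(0), character(0), integer(0),
                            integer(0), numeric(0), numeric(0)))
  fields <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 22L))
    stop("line ", keep[which(nf < 22L)[1]],
         ": domtblout line has fewer than 22 fields")
  m <- t(vapply(fields, function(f) f[1:22], character(22)))
  .new_domain_hits(protein_id = m[, 1], domain_name = m[, 4],
                   start = as.integer(m[, 20]) - 1L,
                   end = as.integer(m[, 21]),
                   evalue = as.numeric(m[, 13]),
                   bitscore = as.numeric(m[, 14]))
}

#' Read/write the simplified domain TSV
#'
#' Columns: protein_id, domain_name, start, end (1-based inclusive on
#' disk), evalue, bitscore. A write/read round trip preserves all
#' fields.
#'
#' @param path TSV path.
#' @return `read_domain_tsv`: data.frame with internal (0-based
#'   half-open) coordinates; `write_domain_tsv`: `path`, invisibly.
#' @export
read_domain_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  .new_domain_hits(df$protein_id, df$domain_name, df$start - 1L, df$end,
                   df$evalue, df$bitscore)
}

#' @rdname read_domain_tsv
#' @param hits Data.frame of domain hits (internal coordinates).
#' @export
write_domain_tsv <- function(hits, path) {
  out <- hits
  out$start <- out$start + 1L  # back to 1-based inclusive
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter domain hits by significance
#'
#' Retains hits with `evalue <= e_max` and `bitscore >= score_min`.
#' Idempotent.
#'
#' @param hits Data.frame of domain hits.
#' @param e_max Maximum independent e-value (default 0.1).
#' @param score_min Minimum bitscore in bits (default 10).
#' @return The retained rows.
#' @export
filter_domains <- function(hits, e_max = 0.1, score_min = 10) {
  if (!is.finite(e_max) || e_max <= 0) stop("e_max must be positive")
  if (!is.finite(score_min) || score_min <= 0)
    stop("score_min must be positive")
  hits[hits$evalue <= e_max & hits$bitscore >= score_min, , drop = FALSE]
}

# overlap length of two half-open intervals
.ovl <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))

#' Resolve overlapping domain hits for one protein
#'
#' Greedy by descending bitscore: a hit is dropped when it overlaps an
#' already-accepted hit by more than 50% of the shorter of the two.
#' Bitscore ties are broken in favour of the earlier-starting hit.
#'
#' @param hits Data.frame of domain hits for a single protein.
#' @return Accepted hits, sorted by start.
#' @export
resolve_overlaps <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  if (length(unique(hits$protein_id)) > 1L)
    stop("resolve_overlaps() expects hits for a single protein")
  o <- order(-hits$bitscore, hits$start)
  h <- hits[o, , drop = FALSE]
  acc <- integer(0)
  for (i in seq_len(nrow(h))) {
    clash <- FALSE
    for (j in acc) {
      ov <- .ovl(h$start[i], h$end[i], h$start[j], h$end[j])
      shorter <- min(h$end[i] - h$start[i], h$end[j] - h$start[j])
      if (ov > 0.5 * shorter) { clash <- TRUE; break }
    }
    if (!clash) acc <- c(acc, i)
  }
  out <- h[acc, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Protein architecture
#'
#' An ordered, non-overlapping set of domain hits plus the protein
#' length.
#'
#' @param protein_id Protein id.
#' @param hits Data.frame of domain hits for this protein (overlaps are
#'   resolved if present).
#' @param length Protein length in residues.
#' @return List of class `architecture`.
#' @export
architecture <- function(protein_id, hits, length) {
  stopifnot(length >= 1)
  hits <- hits[hits$protein_id == protein_id, , drop = FALSE]
  hits <- resolve_overlaps(hits)
  if (nrow(hits) > 0 && max(hits$end) > length)
    stop("domain extends beyond protein length")
  structure(list(protein_id = protein_id, hits = hits,
                 length = as.integer(length)),
            class = "architecture")
}

#' Is a protein a bHLH-PAS family member?
#'
#' TRUE iff the architecture carries at least one bHLH-class and one
#' PAS-class domain, with the bHLH-class domain N-terminal to the first
#' PAS-class domain (the canonical arrangement; the ordering requirement
#' can be relaxed).
#'
#' @param arch An [architecture()] object.
#' @param domain_vocab Named list with elements `bHLH` and `PAS` mapping
#'   to domain-name vectors; see [default_domain_vocab()].
#' @param require_order Require bHLH before the first PAS-class domain
#'   (default TRUE).
#' @return Logical scalar.
#' @export
is_bhlh_pas <- function(arch, domain_vocab = default_domain_vocab(),
                        require_order = TRUE) {
  if (is.null(domain_vocab$bHLH) || is.null(domain_vocab$PAS) ||
      length(domain_vocab$bHLH) + length(domain_vocab$PAS) == 0)
    stop("empty domain vocabulary")
  h <- arch$hits
  bh <- h[h$domain_name %in% domain_vocab$bHLH, , drop = FALSE]
  pas <- h[h$domain_name %in% domain_vocab$PAS, , drop = FALSE]
  if (nrow(bh) == 0L || nrow(pas) == 0L) return(FALSE)
  if (!require_order) return(TRUE)
  min(bh$start) < min(pas$start)
}

#' C-terminal region downstream of the last PAS-class domain
#'
#' The interval (0-based half-open) from the end of the last PAS-class
#' (or PAC) domain to the protein end: the region scanned for
#' oxygen-dependent degradation motifs. May be empty.
#'
#' @inheritParams is_bhlh_pas
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
cterm_region <- function(arch, domain_vocab = default_domain_vocab()) {
  h <- arch$hits
  if (nrow(h) == 0L) stop("architecture has no domains")
  pas <- h[h$domain_name %in% domain_vocab$PAS, , drop = FALSE]
  if (nrow(pas) == 0L)
    stop("no PAS-class domain in ", arch$protein_id,
         "; scan the full sequence explicitly if intended")
  c(max(pas$end), arch$length)
}
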