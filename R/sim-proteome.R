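# Synthetic proteomes with bHLH+PAS domain architectures,
# proline/serine/glutamine-rich C-terminal tails, and planted ODD
# degrons, emitted as FASTA plus a companion domain TSV and truth
# record.

#' Plan one synthetic protein
#'
#' @param protein_id Sequence id.
#' @param domains Data.frame with columns `name` and `length` (residues),
#'   in N-to-C order; default a canonical bHLH-PAS architecture.
#' @param linker Residues between consecutive domains (default 10).
#' @param tail_length C-terminal tail length in residues (>= 0).
#' @param tail_freqs Named numeric of target tail residue frequencies
#'   (subset of the 20 letters, sum <= 1); the remaining probability
#'   mass is spread uniformly over the unnamed letters. Default is a
#'   P/S/Q-rich tail (P = 0.2, S = 0.15, Q = 0.1).
#' @param planted Data.frame with columns `octamer` (8-residue strict
#'   degron, e.g. `"LEMLAPYI"`) and `offset` (0-based position within
#'   the tail); may be empty.
#' @return Plan list consumed by [simulate_proteome()].
#' @export
protein_plan <- function(protein_id,
                         domains = data.frame(
                           name = c("HLH", "PAS", "PAS_3"),
                           length = c(50L, 70L, 65L)),
                         linker = 10L, tail_length = 200L,
                         tail_freqs = c(P = 0.2, S = 0.15, Q = 0.1),
                         planted = NULL) {
  stopifnot(all(c("name", "length") %in% names(domains)),
            all(domains$length > 0), linker >= 0, tail_length >= 0)
  if (is.null(planted))
    planted <- data.frame(octamer = character(0), offset = integer(0))
  if (any(!names(tail_freqs) %in% .AA20) || sum(tail_freqs) > 1 + 1e-12)
    stop("tail_freqs must be named by amino acids and sum to <= 1")
  if (nrow(planted) > 0) {
    if (any(nchar(planted$octamer) != 8L))
      stop("planted motifs must be octamers")
    if (any(planted$offset < 0 | planted$offset + 8 > tail_length))
      stop("planted motif outside the tail (would overlap a domain or ",
           "run past the protein end)")
  }
  list(protein_id = protein_id, domains = domains,
       linker = as.integer(linker), tail_length = as.integer(tail_length),
       tail_freqs = tail_freqs, planted = planted)
}

# full 20-letter probability vector from a partial specification
.tail_probs <- function(tail_freqs) {
  p <- setNames(rep(0, 20), .AA20)
  p[names(tail_freqs)] <- tail_freqs
  rest <- setdiff(.AA20, names(tail_freqs))
  if (length(rest) > 0) p[rest] <- (1 - sum(tail_freqs)) / length(rest)
  p
}

#' Simulate a proteome with planted degrons
#'
#' Residues are drawn i.i.d.: uniformly over the 20 letters inside
#' domains and linkers, and from the plan's tail composition in the
#' C-terminal tail. Planted octamers overwrite the tail at the requested
#' offsets. Any chance strict-consensus match outside a planted window
#' is scrubbed (its terminal isoleucine is replaced by asparagine, which
#' occurs at no constrained pattern position), so the truth record lists
#' exactly the planted strict hits.
#'
#' @param plans List of [protein_plan()]s.
#' @param seed Integer seed.
#' @return List of class `proteome_truth`: `fasta` (character, one
#'   FASTA record per protein, wrapped at 60 columns), `sequences`
#'   (named character), `domains` (data.frame in internal 0-based
#'   half-open coordinates with `evalue`/`bitscore` filler), `truth`
#'   (per protein: tail interval and planted-hit table), `seed`.
#' @export
simulate_proteome <- function(plans, seed) {
  if (inherits(plans, "list") && !is.null(plans$protein_id))
    plans <- list(plans)
  seqs <- character(0)
  dom_rows <- list()
  truth <- list()
  .with_seed(seed, {
    for (plan in plans) {
      pos <- 0L
      parts <- character(0)
      for (d in seq_len(nrow(plan$domains))) {
        if (d > 1 && plan$linker > 0) {
          parts <- c(parts, sample(.AA20, plan$linker, replace = TRUE))
          pos <- pos + plan$linker
        }
        len <- plan$domains$length[d]
        dom_rows[[length(dom_rows) + 1L]] <- data.frame(
          protein_id = plan$protein_id,
          domain_name = plan$domains$name[d],
          start = pos, end = pos + len,
          evalue = 1e-8, bitscore = 100, stringsAsFactors = FALSE)
        parts <- c(parts, sample(.AA20, len, replace = TRUE))
        pos <- pos + len
      }
      tail_start <- pos
      probs <- .tail_probs(plan$tail_freqs)
      tail <- if (plan$tail_length > 0)
        sample(.AA20, plan$tail_length, replace = TRUE, prob = probs)
      else character(0)
      if (nrow(plan$planted) > 0) {
        for (k in seq_len(nrow(plan$planted))) {
          off <- plan$planted$offset[k]
          tail[(off + 1):(off + 8)] <-
            strsplit(plan$planted$octamer[k], "")[[1]]
        }
      }
      seq_chars <- c(parts, tail)
      seq_str <- paste(seq_chars, collapse = "")
      # scrub chance strict matches outside planted windows: break the
      # match at a constrained pattern position that does not fall
      # inside any planted octamer
      hits <- scan_motif(seq_str, mode = "strict")
      planted_starts <- tail_start + plan$planted$offset
      in_planted <- function(idx0) any(idx0 >= planted_starts &
                                       idx0 < planted_starts + 8L)
      for (h in seq_len(nrow(hits))) {
        if (hits$start[h] %in% planted_starts) next
        for (p in c(8L, 6L, 5L, 1L, 2L, 4L, 7L)) {  # constrained slots
          idx0 <- hits$start[h] + p - 1L
          if (!in_planted(idx0)) { seq_chars[idx0 + 1L] <- "N"; break }
        }
      }
      seq_str <- paste(seq_chars, collapse = "")
      seqs[plan$protein_id] <- seq_str
      truth[[plan$protein_id]] <- list(
        tail = c(tail_start, tail_start + plan$tail_length),
        planted = data.frame(
          start = if (nrow(plan$planted)) planted_starts else integer(0),
          octamer = plan$planted$octamer,
          offset_in_tail = plan$planted$offset,
          stringsAsFactors = FALSE),
        length = nchar(seq_str))
    }
  })
  domains <- if (length(dom_rows) > 0) do.call(rbind, dom_rows)
             else .new_domain_hits(character(0), character(0), integer(0),
                                   integer(0), numeric(0), numeric(0))
  fasta <- vapply(names(seqs), function(id) {
    body <- gsub("(.{60})", "\\1\n", seqs[[id]])
    paste0(">", id, "\n", sub("\n$", "", body))
  }, character(1))
  structure(list(fasta = unname(fasta), sequences = seqs,
                 domains = domains, truth = truth, seed = seed),
            class = "proteome_truth")
}

#' Write a simulated proteome to FASTA and domain TSV
#'
#' @param proteome A [simulate_proteome()] result.
#' @param fasta_path,domains_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_proteome <- function(proteome, fasta_path, domains_path) {
  writeLines(proteome$fasta, fasta_path)
  write_domain_tsv(proteome$domains, domains_path)
  invisible(c(fasta_path, domains_path))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta_proteins <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}
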