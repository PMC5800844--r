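# Synthetic homology-search tables (BLAST outfmt 6) for simulated gene
# families.
#
# Bitscores are a strictly decreasing function of patristic distance on
# the true gene tree, plus seeded jitter bounded to never reorder ranks;
# e-values decrease monotonically with bitscore. Each file pair emulates
# a search of one species' proteins against a combined database holding
# both proteomes: in-paralogs (closer on the tree than any cross-species
# gene) therefore outcompete cross-species hits, which is exactly what
# makes reciprocal best hits coincide with the true 1:1 ortholog pairs.

.blast_line <- function(q, s, d, bitscore) {
  pident <- 100 * exp(-d / 4)
  alen <- 250L
  mm <- as.integer(round(alen * (1 - pident / 100)))
  evalue <- 10^(-bitscore / 10)
  sprintf("%s\t%s\t%.2f\t%d\t%d\t0\t1\t%d\t1\t%d\t%.3e\t%.1f",
          q, s, pident, alen, mm, alen, alen, evalue, bitscore)
}

#' Simulate forward/reverse BLAST tables for a species pair
#'
#' For every family, every gene of `species_a` is queried against all
#' genes of `species_a` and `species_b` in the same family (minus
#' itself) in the forward table, and symmetrically for `species_b` in
#' the reverse table.
#'
#' @param families List of [simulate_gene_family()] results.
#' @param species_a,species_b The two species of the reciprocal search.
#' @param seed Integer seed for the rank-preserving bitscore jitter.
#' @return List with `forward` and `reverse`: character vectors of
#'   outfmt-6 lines (possibly empty).
#' @export
simulate_blast_tables <- function(families, species_a, species_b, seed) {
  stopifnot(is.list(families))
  forward <- character(0)
  reverse <- character(0)
  .with_seed(seed, {
    for (fam in families) {
      if (fam$extinct || length(fam$genes) < 2L || is.null(fam$gene_tree))
        next
      genes <- fam$gene_tree$tip.label
      sp <- leaf_species(genes)
      keep <- sp %in% c(species_a, species_b)
      if (sum(keep) < 2L) next
      dmat <- ape::cophenetic.phylo(fam$gene_tree)
      gg <- genes[keep]
      spg <- sp[keep]
      # strictly decreasing bitscore in distance; jitter below half the
      # smallest gap between distinct transformed scores
      dsub <- dmat[gg, gg, drop = FALSE]
      b0 <- 500 * exp(-dsub / 2)
      ud <- sort(unique(as.vector(b0[upper.tri(b0)])), decreasing = TRUE)
      gap <- if (length(ud) > 1) min(diff(sort(ud))) else 1
      eps <- gap / 3
      for (qi in seq_along(gg)) {
        for (si in seq_along(gg)) {
          if (qi == si) next
          b <- b0[qi, si] + stats::runif(1, -eps, eps)
          line <- .blast_line(gg[qi], gg[si], dsub[qi, si], b)
          if (spg[qi] == species_a) forward <- c(forward, line)
          else reverse <- c(reverse, line)
        }
      }
    }
  })
  list(forward = forward, reverse = reverse)
}

#' Write simulated BLAST tables to disk
#'
#' @param tables A [simulate_blast_tables()] result.
#' @param forward_path,reverse_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_blast_tables <- function(tables, forward_path, reverse_path) {
  writeLines(tables$forward, forward_path)
  writeLines(tables$reverse, reverse_path)
  invisible(c(forward_path, reverse_path))
}
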