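#!/usr/bin/env Rscript
# ODD degron scanning over the simulated proteome: strict-consensus and
# core-tetramer hits in each C-terminal tail, tail composition, the
# analytical i.i.d. chance expectation, and a composition-preserving
# permutation p-value for every protein.

suppressMessages(library(spongehif))

sim <- "results/sim"
out <- "results"
seqs <- read_fasta_proteins(file.path(sim, "proteome.fa"))
domains <- read_domain_tsv(file.path(sim, "proteome_domains.tsv"))

hit_rows <- list()
summary_rows <- list()
for (id in names(seqs)) {
  arch <- architecture(id, filter_domains(domains), nchar(seqs[[id]]))
  region <- cterm_region(arch)
  for (mode in c("strict", "core")) {
    h <- scan_motif(seqs[[id]], region, mode)
    if (nrow(h) > 0)
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        protein_id = id, start_1based = h$start + region[1] + 1L,
        match = h$match, mode = mode, variant = h$variant)
  }
  cs <- composition(seqs[[id]], region)
  perm <- motif_permutation_pvalue(seqs[[id]], region, "strict",
                                   n_shuffles = 999, seed = 7)
  summary_rows[[length(summary_rows) + 1L]] <- data.frame(
    protein_id = id, tail_length = cs$length,
    psq_fraction = round(cs$psq_fraction, 4),
    strict_hits = perm$observed,
    core_hits = nrow(scan_motif(seqs[[id]], region, "core")),
    expected_strict = signif(expected_motif_count(cs, "strict"), 4),
    expected_core = signif(expected_motif_count(cs, "core"), 4),
    perm_p_strict = perm$p_value)
}
hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
  data.frame()
summary <- do.call(rbind, summary_rows)
utils::write.table(hits, file.path(out, "degron_hits.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(summary, file.path(out, "degron_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("Degron scan over", length(seqs), "C-terminal tails:\n")
print(summary, row.names = FALSE)
cat("\nHits:\n")
print(hits, row.names = FALSE)
cat("\nReading: only the HIFa-like protein carries a strict-consensus",
    "degron; the ctenophore-like tail matches in core mode only",
    "(its LAMRAPYI text fails the octamer consensus); the P/S/Q-rich",
    "sponge-like tail shows how core tetramers arise by composition",
    "alone, which is why the strict consensus plus a chance null, not",
    "a LAP/RAP match, is the evidence standard.\n")
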