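#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume:
# duplication-loss gene families (with truth records), reciprocal BLAST
# tables for a species pair, and a small bHLH-PAS proteome with planted
# and absent degrons. Everything is seeded and written under
# results/sim/.

suppressMessages(library(spongehif))

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

st <- default_species_tree()
cat("Species tree:", ape::Ntip(st$tree), "species,",
    length(unique(st$clades)), "clades\n")
write_species_map(st$clades, file.path(out, "species_map.tsv"))

# -- gene families ----------------------------------------------------
# rates chosen to give a realistic mix of 1:1, 1:many and lost lineages
n_fam <- 20
fams <- lapply(seq_len(n_fam), function(i)
  simulate_gene_family(st, dup_rate = 0.1, loss_rate = 0.05,
                       seed = 1000 + i, prefix = paste0("f", i)))
for (i in seq_len(n_fam)) {
  if (fams[[i]]$extinct) next
  writeLines(fams[[i]]$newick,
             file.path(out, sprintf("family_%02d.nwk", i)))
  utils::write.table(fams[[i]]$relation_table,
                     file.path(out, sprintf("family_%02d_truth.tsv", i)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
classes <- table(do.call(rbind, lapply(fams, `[[`,
                                       "relation_table"))$class)
cat("Simulated", n_fam, "families; cross-species pair classes:\n")
print(classes)

# -- reciprocal BLAST tables (human vs the Tethya-like demosponge) ----
tb <- simulate_blast_tables(fams, "Homo_sapiens", "Tethya_wilhelma",
                            seed = 77)
write_blast_tables(tb, file.path(out, "blast_forward.tsv"),
                   file.path(out, "blast_reverse.tsv"))
cat("BLAST tables:", length(tb$forward), "forward and",
    length(tb$reverse), "reverse hits\n")

# -- proteome with degron truth ---------------------------------------
plans <- list(
  # vertebrate-like HIFa: strict LAPY degron in the tail
  protein_plan("HIFa_like", tail_length = 300L,
               planted = data.frame(octamer = "LEMLAPYI", offset = 120L)),
  # ctenophore-like near-miss handled downstream in core mode
  protein_plan("cteno_like", tail_length = 250L),
  # sponge-like P/S/Q-rich tail with no degron at all
  protein_plan("sponge_like", tail_length = 400L,
               tail_freqs = c(P = 0.25, S = 0.15, Q = 0.1)))
pr <- simulate_proteome(plans, seed = 42)
# place the LAMRAPYI text (core hit, strict miss) in the ctenophore tail
seqs <- pr$sequences
tail0 <- pr$truth$cteno_like$tail[1]
substr(seqs["cteno_like"], tail0 + 101, tail0 + 108) <- "LAMRAPYI"
pr$sequences <- seqs
pr$fasta <- vapply(names(seqs), function(id) {
  body <- gsub("(.{60})", "\\1\n", seqs[[id]])
  paste0(">", id, "\n", sub("\n$", "", body))
}, character(1))
write_proteome(pr, file.path(out, "proteome.fa"),
               file.path(out, "proteome_domains.tsv"))
tails <- do.call(rbind, lapply(names(pr$truth), function(id)
  data.frame(protein_id = id,
             tail_start = pr$truth[[id]]$tail[1],
             tail_end = pr$truth[[id]]$tail[2])))
utils::write.table(tails, file.path(out, "proteome_tails.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Proteome written:", length(seqs), "proteins; planted strict",
    "degron in HIFa_like only.\n")
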