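# The synthetic-data generators and their truth records.

test_that("event-free families mirror the species tree with all-1:1 relations", {
  st <- sim_system()
  f <- simulate_gene_family(st, 0, 0, seed = 1)
  expect_false(f$extinct)
  expect_equal(ape::Ntip(f$gene_tree), ape::Ntip(st$tree))
  expect_true(all(f$events == "speciation"))
  expect_true(all(f$relation_table$class == "1:1"))
  sp_relab <- st$tree
  sp_relab$tip.label <- paste0(sp_relab$tip.label, "|g1")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(f$gene_tree),
                                         ape::unroot(sp_relab))), 0)
  # conservation: one gene per surviving leaf
  expect_equal(length(f$genes), ape::Ntip(f$gene_tree))
  expect_equal(sum(f$copy_number), length(f$genes))
})

test_that("a loss on the ctenophore stem removes only ctenophores", {
  st <- sim_system()
  # seed chosen so the single drawn loss falls on the ctenophore stem
  f <- simulate_gene_family(st, 0, 0.3, seed = 75)
  cteno <- names(st$clades)[st$clades == "Ctenophora"]
  expect_true(all(f$copy_number[cteno] == 0))
  expect_true(all(f$copy_number[setdiff(names(f$copy_number),
                                        cteno)] == 1))
  expect_true(all(f$relation_table$class == "1:1"))
  expect_true(all(f$verdicts$verdict[f$verdicts$species %in% cteno] ==
                    "absent"))
})

test_that("negative rates are rejected and extinction is an outcome", {
  st <- sim_system()
  expect_error(simulate_gene_family(st, -1, 0, seed = 1), ">= 0")
  f <- simulate_gene_family(st, 0, 100, seed = 2)
  expect_true(f$extinct)
  expect_equal(length(f$genes), 0L)
})

test_that("relation tables equal the event-history replay oracle", {
  st <- sim_system()
  checked <- 0L
  for (s in 1:60) {
    f <- simulate_gene_family(st, 0.1, 0.05, seed = 700 + s)
    if (f$extinct || length(f$genes) < 2) next
    rel <- oracle_relations(f$history)
    # rebuild the pairwise class table from the oracle ortho matrix
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    want <- character(0)
    n <- length(rel$labels)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (rel$species[i] == rel$species[j]) next
      cls <- if (!rel$ortho[i, j]) "paralog" else {
        nB <- sum(rel$ortho[i, rel$species == rel$species[j]])
        nA <- sum(rel$ortho[rel$species == rel$species[i], j])
        if (nA == 1 && nB == 1) "1:1"
        else if (nA == 1 || nB == 1) "1:many" else "many:many"
      }
      want[key(rel$labels[i], rel$labels[j])] <- cls
    }
    got <- setNames(f$relation_table$class,
                    key(f$relation_table$gene_a, f$relation_table$gene_b))
    expect_identical(got[names(want)], want)
    checked <- checked + 1L
  }
  expect_gte(checked, 50L)
})

test_that("relation tables are symmetric up to 1:many orientation", {
  st <- sim_system()
  f <- simulate_gene_family(st, 0.2, 0.05, seed = 11)
  rt <- f$relation_table
  expect_false(any(duplicated(paste(pmin(rt$gene_a, rt$gene_b),
                                    pmax(rt$gene_a, rt$gene_b)))))
  expect_true(all(f$copy_number >= 0))
})

test_that("gene-family simulation is seed-deterministic", {
  st <- sim_system()
  a <- simulate_gene_family(st, 0.1, 0.05, seed = 99)
  b <- simulate_gene_family(st, 0.1, 0.05, seed = 99)
  expect_identical(a$newick, b$newick)
  expect_identical(a$relation_table, b$relation_table)
  c <- simulate_gene_family(st, 0.1, 0.05, seed = 100)
  expect_false(identical(a$newick, c$newick))
})

test_that("proteome truth lists exactly the planted strict hits", {
  plan <- protein_plan("p1", tail_length = 200L,
                       planted = data.frame(octamer = "LEMLAPYI",
                                            offset = 60L))
  pr <- simulate_proteome(list(plan), seed = 21)
  s <- pr$sequences[["p1"]]
  reg <- pr$truth$p1$tail
  hits <- scan_motif(s, reg, "strict")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start + reg[1], pr$truth$p1$planted$start)
  expect_identical(hits$match, "LEMLAPYI")
  # scrubbing holds across seeds: no unplanted strict hits anywhere
  for (sd in 1:10) {
    pr2 <- simulate_proteome(list(plan), seed = sd)
    h2 <- scan_motif(pr2$sequences[["p1"]], mode = "strict")
    expect_equal(h2$start, pr2$truth$p1$planted$start)
  }
})

test_that("tail composition matches its targets within sampling error", {
  plan <- protein_plan("big", tail_length = 10000L,
                       tail_freqs = c(P = 0.2, S = 0.15, Q = 0.1))
  pr <- simulate_proteome(list(plan), seed = 5)
  reg <- pr$truth$big$tail
  cs <- composition(pr$sequences[["big"]], reg)
  targets <- c(P = 0.2, S = 0.15, Q = 0.1)
  for (a in names(targets)) {
    p <- targets[[a]]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(cs$freq[[a]] - p), 3 * se + 1e-3)
  }
})

test_that("zero-length tails end at the last domain with empty truth", {
  plan <- protein_plan("nt", tail_length = 0L)
  pr <- simulate_proteome(list(plan), seed = 2)
  expect_equal(nchar(pr$sequences[["nt"]]),
               max(pr$domains$end[pr$domains$protein_id == "nt"]))
  expect_equal(nrow(pr$truth$nt$planted), 0L)
  expect_error(
    protein_plan("bad", tail_length = 10L,
                 planted = data.frame(octamer = "LEMLAPYI",
                                      offset = 5L)),
    "overlap|outside")
})

test_that("FASTA output is wrapped and read back faithfully", {
  pr <- simulate_proteome(list(protein_plan("w1", tail_length = 150L)),
                          seed = 8)
  fa <- withr::local_tempfile(fileext = ".fa")
  dm <- withr::local_tempfile(fileext = ".tsv")
  write_proteome(pr, fa, dm)
  lines <- readLines(fa)
  expect_true(all(nchar(lines[!grepl("^>", lines)]) <= 60))
  back <- read_fasta_proteins(fa)
  expect_identical(unname(back["w1"]), unname(pr$sequences[["w1"]]))
  expect_equal(read_domain_tsv(dm), pr$domains)
})

test_that("a two-gene 1:1 family yields exactly one reciprocal pair", {
  st <- sim_system()
  fams <- list(simulate_gene_family(st, 0, 0.3, seed = 75))
  tb <- simulate_blast_tables(fams, "Homo_sapiens", "Tethya_wilhelma",
                              seed = 1)
  fp <- withr::local_tempfile(); rp <- withr::local_tempfile()
  write_blast_tables(tb, fp, rp)
  pairs <- reciprocal_best_hits(
    best_hit_per_query(read_blast_tab(fp)),
    best_hit_per_query(read_blast_tab(rp)))
  expect_equal(nrow(pairs), 1L)
  expect_setequal(unlist(pairs[1, ]),
                  c("Homo_sapiens|g1", "Tethya_wilhelma|g1"))
})

test_that("a target-lineage duplication breaks reciprocity for the in-paralogs", {
  st <- sim_system()
  # seed chosen so the only event is a duplication within Tethya
  f <- simulate_gene_family(st, 0.08, 0, seed = 76)
  expect_equal(unname(f$copy_number["Tethya_wilhelma"]), 2L)
  tb <- simulate_blast_tables(list(f), "Homo_sapiens",
                              "Tethya_wilhelma", seed = 2)
  fp <- withr::local_tempfile(); rp <- withr::local_tempfile()
  write_blast_tables(tb, fp, rp)
  fh <- read_blast_tab(fp); rh <- read_blast_tab(rp)
  fwd <- best_hit_per_query(fh)
  # the human query has a unique best hit ...
  expect_equal(length(fwd["Homo_sapiens|g1"]), 1L)
  pairs <- reciprocal_best_hits(fwd, best_hit_per_query(rh))
  # ... but reciprocity fails: each in-paralog's best hit is its sibling
  expect_equal(nrow(pairs), 0L)
  # matching the truth: the human-Tethya relations are 1:many, not 1:1
  ht <- f$relation_table[
    leaf_species(f$relation_table$gene_a) == "Homo_sapiens" &
      leaf_species(f$relation_table$gene_b) == "Tethya_wilhelma", ]
  expect_true(all(ht$class == "1:many"))
})

test_that("empty family lists give empty tables; bitscores track distance", {
  tb <- simulate_blast_tables(list(), "a", "b", seed = 1)
  expect_length(tb$forward, 0L)
  expect_length(tb$reverse, 0L)

  st <- sim_system()
  f <- simulate_gene_family(st, 0.1, 0.05, seed = 13)
  tb2 <- simulate_blast_tables(list(f), "Homo_sapiens",
                               "Nematostella_vectensis", seed = 3)
  fp <- withr::local_tempfile()
  writeLines(tb2$forward, fp)
  fh <- read_blast_tab(fp)
  d <- ape::cophenetic.phylo(f$gene_tree)
  for (q in unique(fh$query_id)) {
    h <- fh[fh$query_id == q, ]
    if (nrow(h) < 2) next
    o <- order(d[q, h$subject_id])
    expect_equal(order(-h$bitscore), o)
  }
})

test_that("experiment traces honour cadence, flat-line and determinism", {
  et0 <- experiment_truth(schedule = data.frame(t_start_s = 0,
                                                percent_as = 100),
                          duration_s = 7200, lambda_per_day = 0,
                          noise_sd = 0, o2_noise_uM = 0, seed = 3)
  sim0 <- simulate_experiment(et0)
  expect_true(all(diff(sim0$area$timestamp_s) == 30))
  expect_true(all(sim0$area$area_px == sim0$area$area_px[1]))
  expect_equal(nrow(sim0$events), 0L)

  et1 <- experiment_truth(seed = 14)
  a <- simulate_experiment(et1)
  b <- simulate_experiment(et1)
  expect_identical(a$area, b$area)
  expect_identical(a$o2, b$o2)
  expect_identical(a$events, b$events)
  expect_error(experiment_truth(cadence_s = 0), "cadence")
  expect_error(
    experiment_truth(schedule = data.frame(t_start_s = 0,
                                           percent_as = 150)),
    "0, 100")
})

test_that("planted events are non-overlapping and refractory-spaced", {
  for (sd in 1:5) {
    sim <- simulate_experiment(experiment_truth(seed = sd))
    ev <- sim$events
    if (nrow(ev) < 2) next
    gaps <- ev$start_s[-1] - ev$end_s[-nrow(ev)]
    expect_true(all(gaps >= 1200))
  }
})

test_that("Poisson event counts match the thinned-process expectation", {
  # lambda = 12/day over 2 days; refractory thinning makes the kept
  # process a renewal process with inter-event time D + Exp(lambda),
  # D = event duration + refractory, so the long-run expectation is
  # T / (D + 1/lambda) -- the independent oracle for the mean count
  counts <- vapply(1:40, function(sd) {
    sim <- simulate_experiment(experiment_truth(
      schedule = data.frame(t_start_s = 0, percent_as = 100),
      duration_s = 2 * 86400, lambda_per_day = 12, noise_sd = 0,
      o2_noise_uM = 0, seed = sd))
    nrow(sim$events)
  }, numeric(1))
  D <- 1800 + 1200
  expected <- 2 * 86400 / (D + 86400 / 12)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 2 * se + 0.5)
})

test_that("rendered frames track the area trace", {
  frames <- render_frames(c(2000, 1000, 500), dim = c(96L, 128L))
  areas <- vapply(frames, function(f) sum(f > 100), numeric(1))
  expect_true(all(diff(areas) < 0))
  expect_true(all(vapply(frames, max, numeric(1)) <= 255))
})
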