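# Gene-tree event labelling, relation classification and the
# presence-absence matrix.

toy_map <- c(human = "Bilateria", mouse = "Bilateria",
             sponge = "Demospongiae", cteno = "Ctenophora",
             choano = "Choanoflagellata")

test_that("newick reading keeps supports and round-trips", {
  tr <- read_newick("(A|1,B|2);")
  expect_equal(ape::Ntip(tr), 2L)
  tr2 <- read_newick("((A|1,B|1x)95,C|1);")
  expect_true("95" %in% tr2$node.label)
  expect_error(read_newick("((A|1,B|2);"), "Newick")
  # round trip preserves topology and labels
  txt <- "((human|a,mouse|b)80,(sponge|c,cteno|d)99);"
  tr3 <- read_newick(txt)
  rt <- read_newick(ape::write.tree(tr3))
  expect_setequal(rt$tip.label, tr3$tip.label)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(rt),
                                         ape::unroot(tr3))), 0)
  expect_setequal(rt$node.label, tr3$node.label)
})

test_that("species overlap labels cherries correctly", {
  t1 <- label_events_species_overlap(
    read_newick("((human|a,mouse|b),sponge|c);"), toy_map)
  expect_true(all(t1$events == "speciation"))
  t2 <- label_events_species_overlap(
    read_newick("((human|a,human|b),sponge|c);"), toy_map)
  expect_equal(sum(t2$events == "duplication"), 1L)
  expect_error(
    label_events_species_overlap(read_newick("(human|a,alien|b);"),
                                 toy_map),
    "alien")
})

test_that("loss-free simulations are labelled exactly; with losses, inferred duplications never exceed truth", {
  st <- sim_system()
  for (s in 1:60) {
    f <- simulate_gene_family(st, 0.15, 0, seed = s)
    tr <- label_events_species_overlap(f$gene_tree, st$clades)
    expect_identical(unname(tr$events), unname(f$events))
  }
  for (s in 1:40) {
    f <- simulate_gene_family(st, 0.1, 0.08, seed = 5000 + s)
    if (f$extinct || length(f$genes) < 2) next
    tr <- label_events_species_overlap(f$gene_tree, st$clades)
    # overlap can miss duplications (complementary losses) but, with
    # exact branch bookkeeping, never invent one
    expect_true(all(which(tr$events == "duplication") %in%
                      which(f$events == "duplication")))
  }
})

test_that("relation classification reproduces the HSN sister-group case", {
  # sponge/ctenophore genes sister to a duplicated HIF-SIM-NPAS block:
  # related to the reference only through pre-duplication positions
  txt <- "((sponge|s1,cteno|c1)100,((human|HIF1A,human|SIM1),human|NPAS3));"
  tr <- label_events_species_overlap(read_newick(txt), toy_map)
  expect_identical(classify_relation(tr, "human|HIF1A", "sponge"),
                   "homolog")
  expect_identical(classify_relation(tr, "human|HIF1A", "cteno"),
                   "homolog")
  # two-leaf orthologs
  tr2 <- label_events_species_overlap(read_newick("(human|x,sponge|y);"),
                                      toy_map)
  expect_identical(classify_relation(tr2, "human|x", "sponge"),
                   "ortholog_1to1")
  expect_identical(classify_relation(tr2, "human|x", "mouse"), "absent")
  expect_error(classify_relation(tr2, "human|zz", "sponge"), "zz")
})

test_that("1:1 verdicts are symmetric between reference and target", {
  st <- sim_system()
  for (s in c(3, 9, 21)) {
    f <- simulate_gene_family(st, 0.1, 0.05, seed = s)
    if (f$extinct || length(f$genes) < 2) next
    tr <- label_events_species_overlap(f$gene_tree, st$clades)
    v <- f$verdicts
    one2one <- v[v$verdict == "ortholog_1to1", , drop = FALSE]
    for (i in seq_len(nrow(one2one))) {
      g <- one2one$gene[i]
      partner_sp <- one2one$species[i]
      partners <- f$genes[leaf_species(f$genes) == partner_sp]
      back <- vapply(partners, function(p)
        classify_relation(tr, p, leaf_species(g)), character(1))
      expect_true("ortholog_1to1" %in% back)
    }
  }
})

test_that("simulated-family verdicts match the event-history replay oracle", {
  st <- sim_system()
  n_checked <- 0L
  for (s in 301:340) {
    f <- simulate_gene_family(st, 0.1, 0.05, seed = s)
    if (f$extinct || length(f$genes) < 2) next
    rel <- oracle_relations(f$history)
    ov <- oracle_verdicts(rel)
    key <- function(d) setNames(d$verdict, paste(d$gene, d$species))
    got <- key(f$verdicts)
    want <- key(ov)
    expect_identical(got[names(want)], want)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 30L)
})

test_that("lineage-duplication flag counts within-clade duplications", {
  # 3 in-paralogs from 2 nested within-clade duplications
  txt <- "(((human|a,human|b),human|c),sponge|d);"
  tr <- label_events_species_overlap(read_newick(txt), toy_map)
  expect_true(flag_lineage_duplications(tr, toy_map, "Bilateria"))
  expect_false(flag_lineage_duplications(tr, toy_map, "Demospongiae"))
  # single duplication is not "multiple"
  txt2 <- "((human|a,human|b),sponge|d);"
  tr2 <- label_events_species_overlap(read_newick(txt2), toy_map)
  expect_false(flag_lineage_duplications(tr2, toy_map, "Bilateria"))
})

test_that("secondary loss requires a non-metazoan homolog", {
  ctx <- function(v) list(
    verdicts = v, outgroups = c("Choanoflagellata", "Capsaspora"))
  v1 <- c(Bilateria = "ortholog_1to1", Demospongiae = "absent",
          Ctenophora = "absent", Choanoflagellata = "homolog")
  expect_identical(call_secondary_loss("EGL9", "Demospongiae", ctx(v1)),
                   "secondary_loss")
  expect_identical(call_secondary_loss("EGL9", "Ctenophora", ctx(v1)),
                   "secondary_loss")
  v2 <- c(Bilateria = "absent", Demospongiae = "absent",
          Choanoflagellata = "absent")
  expect_identical(call_secondary_loss("X", "Demospongiae", ctx(v2)),
                   "absent")
  v3 <- c(Bilateria = "ortholog_1to1", Demospongiae = "absent",
          Choanoflagellata = "absent")
  expect_identical(call_secondary_loss("X", "Demospongiae", ctx(v3)),
                   "absent")
  expect_error(
    call_secondary_loss("X", "Demospongiae",
                        list(verdicts = v1, outgroups = character(0))),
    "outgroup")
})

test_that("matrix assembly validates coverage and round-trips", {
  calls <- expand.grid(component = c("HIFa", "ARNT"),
                       clade = c("Bilateria", "Demospongiae"),
                       stringsAsFactors = FALSE)
  calls$verdict <- "ortholog_1to1"
  calls$lineage_dup <- c(FALSE, FALSE, FALSE, TRUE)
  m <- build_matrix(calls)
  expect_equal(dim(m), c(2L, 2L))
  expect_identical(m["ARNT", "Demospongiae"], "ortholog_1to1+M")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, f)
  m2 <- read_matrix_tsv(f)
  expect_identical(unclass(m)[, ], m2[, ])
  expect_error(build_matrix(calls[-1, ]), "missing")
})
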