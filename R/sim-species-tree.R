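# Fixed, time-calibrated opisthokont species tree used by the
# duplication-loss simulator, with a clade label per species.
#
# The tree is ultrametric (leaves at time 0, root at depth 1 in
# arbitrary time units), binary and rooted, and spans the clades of the
# presence-absence matrix: Bilateria, Cnidaria, Placozoa, Ctenophora,
# the four sponge classes, and the non-metazoan outgroups
# Choanoflagellata and Capsaspora.

.SPECIES_NEWICK <- paste0(
  "(Capsaspora_owczarzaki:1.0,((Monosiga_brevicollis:0.3,",
  "Salpingoeca_rosetta:0.3):0.65,((Mnemiopsis_leidyi:0.3,",
  "Euplokamis_dunlapae:0.3):0.55,((((Amphimedon_queenslandica:0.25,",
  "Tethya_wilhelma:0.25):0.2,Aphrocallistes_vastus:0.45):0.15,",
  "(Sycon_ciliatum:0.5,Oscarella_carmela:0.5):0.1):0.2,",
  "(Trichoplax_adhaerens:0.75,((Nematostella_vectensis:0.35,",
  "Hydra_vulgaris:0.35):0.35,(Homo_sapiens:0.6,",
  "Drosophila_melanogaster:0.6):0.1):0.05):0.05):0.05):0.1):0.05);")

.SPECIES_CLADES <- c(
  Capsaspora_owczarzaki = "Capsaspora",
  Monosiga_brevicollis = "Choanoflagellata",
  Salpingoeca_rosetta = "Choanoflagellata",
  Mnemiopsis_leidyi = "Ctenophora",
  Euplokamis_dunlapae = "Ctenophora",
  Amphimedon_queenslandica = "Demospongiae",
  Tethya_wilhelma = "Demospongiae",
  Aphrocallistes_vastus = "Hexactinellida",
  Sycon_ciliatum = "Calcarea",
  Oscarella_carmela = "Homoscleromorpha",
  Trichoplax_adhaerens = "Placozoa",
  Nematostella_vectensis = "Cnidaria",
  Hydra_vulgaris = "Cnidaria",
  Homo_sapiens = "Bilateria",
  Drosophila_melanogaster = "Bilateria")

#' Default opisthokont species tree
#'
#' A fixed ultrametric species tree (15 species, root depth 1 time
#' unit) with one clade label per species, covering all columns of the
#' presence-absence matrix plus the non-metazoan outgroups.
#'
#' @return List of class `species_tree`: `tree` (an [ape::phylo]),
#'   `clades` (named character vector species -> clade),
#'   `outgroup_clades` (`Choanoflagellata`, `Capsaspora`).
#' @export
default_species_tree <- function() {
  tr <- ape::read.tree(text = .SPECIES_NEWICK)
  structure(list(tree = tr, clades = .SPECIES_CLADES,
                 outgroup_clades = c("Choanoflagellata", "Capsaspora")),
            class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("species_tree: %d species, %d clades\n",
              ape::Ntip(x$tree), length(unique(x$clades))))
  invisible(x)
}

# node depths (time above the leaves) for an ultrametric phylo
.node_depths <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  # distance from root along edges, then convert to height above leaves
  from_root <- numeric(n_all)
  er <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  for (i in seq_len(nrow(er$edge))) {
    p <- er$edge[i, 1]; c <- er$edge[i, 2]
    from_root[c] <- from_root[p] + er$edge.length[i]
  }
  total <- max(from_root[seq_len(n_tip)])
  total - from_root
}
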