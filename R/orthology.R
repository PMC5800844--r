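# Species-overlap orthology classification on gene trees, and the
# per-clade presence / homolog / secondary-loss matrix built from it.
#
# Leaves are labelled "<species>|<gene_id>". An internal node is labelled
# a duplication iff the species sets of its child subtrees intersect
# (species-overlap rule); otherwise it is a speciation. Verdicts against a
# reference gene of defined function follow the ortholog-counting rule
# documented in classify_relation().

#' Species of a leaf label
#'
#' Leaf labels take the form `"<species>|<gene_id>"`; the species is the
#' prefix before the first `|`.
#' @param labels Character vector of leaf labels.
#' @return Character vector of species ids.
#' @export
leaf_species <- function(labels) sub("\\|.*$", "", labels)

#' Read a gene tree from Newick text or file
#'
#' Thin wrapper over [ape::read.tree()] that validates the parse, keeps
#' internal-node labels (bootstrap-style supports) and branch lengths,
#' and checks leaf-label uniqueness.
#'
#' @param text Newick string, or `NULL` if `file` is given.
#' @param file Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text),
    error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  tr
}

#' Root a gene tree for event labelling
#'
#' Event labelling requires a rooted tree. If any configured outgroup
#' species is present among the leaves, the tree is rooted on the clade
#' of those leaves; otherwise midpoint rooting is used. Trees that are
#' already rooted are returned unchanged.
#'
#' @param tree An [ape::phylo] object.
#' @param outgroup_species Character vector of species ids to root on.
#' @return A rooted [ape::phylo] object.
#' @export
root_gene_tree <- function(tree, outgroup_species = character(0)) {
  if (ape::is.rooted(tree)) return(tree)
  sp <- leaf_species(tree$tip.label)
  og <- tree$tip.label[sp %in% outgroup_species]
  if (length(og) > 0) {
    rooted <- tryCatch(ape::root(tree, outgroup = og, resolve.root = TRUE),
                       error = function(e) NULL)
    if (!is.null(rooted)) return(rooted)
  }
  phangorn::midpoint(tree)
}

# children list indexed by node number (tips 1..n, internals n+1..)
.children <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; c <- tree$edge[i, 2]
    ch[[p]] <- c(ch[[p]], c)
  }
  ch
}

# species set of every node, postorder
.node_species_sets <- function(tree) {
  n_tip <- ape::Ntip(tree)
  sets <- vector("list", n_tip + tree$Nnode)
  sp <- leaf_species(tree$tip.label)
  for (i in seq_len(n_tip)) sets[[i]] <- sp[i]
  # walk edges in postorder: child sets are complete before the parent's
  po <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1]; c <- po[i, 2]
    sets[[p]] <- unique(c(sets[[p]], sets[[c]]))
  }
  sets
}

#' Label internal nodes as speciation or duplication by species overlap
#'
#' An internal node is a duplication iff at least two of its child
#' subtrees share a species (for polytomies, children are compared
#' pairwise); otherwise it is a speciation.
#'
#' @param tree A rooted [ape::phylo] gene tree with `"species|gene"`
#'   leaf labels.
#' @param species_map Named character vector mapping species id to clade
#'   label (see [read_species_map()]); every leaf species must be
#'   present.
#' @return `tree` with an added character vector `tree$events` of length
#'   `tree$Nnode` (`"speciation"`/`"duplication"`), indexed in ape's
#'   internal-node order.
#' @export
label_events_species_overlap <- function(tree, species_map) {
  stopifnot(inherits(tree, "phylo"))
  sp <- leaf_species(tree$tip.label)
  unmapped <- setdiff(unique(sp), names(species_map))
  if (length(unmapped) > 0)
    stop("leaf species not in species map: ",
         paste(tree$tip.label[sp %in% unmapped], collapse = ", "))
  n_tip <- ape::Ntip(tree)
  ch <- .children(tree)
  sets <- .node_species_sets(tree)
  events <- character(tree$Nnode)
  for (node in (n_tip + 1):(n_tip + tree$Nnode)) {
    kids <- ch[[node]]
    dup <- FALSE
    if (length(kids) >= 2) {
      for (i in seq_along(kids)[-length(kids)]) {
        for (j in (i + 1):length(kids)) {
          if (length(intersect(sets[[kids[i]]], sets[[kids[j]]])) > 0) {
            dup <- TRUE; break
          }
        }
        if (dup) break
      }
    }
    events[node - n_tip] <- if (dup) "duplication" else "speciation"
  }
  tree$events <- events
  # cache the tip MRCA matrix: classify_relation() is typically called
  # once per (gene, species) pair on the same labelled tree
  tree$mrca_cache <- ape::mrca(tree)
  tree
}

# event label at the MRCA of two tips, from a precomputed mrca matrix
.event_at <- function(tree, mrca_mat, i, j) {
  n_tip <- ape::Ntip(tree)
  node <- mrca_mat[i, j]
  if (node <= n_tip) stop("MRCA of two distinct tips cannot be a tip")
  tree$events[node - n_tip]
}

#' Classify the relation of a reference gene to a target species
#'
#' Given an event-labelled gene tree, let O be the set of target-species
#' leaves whose most recent common ancestor with the reference leaf is a
#' speciation (the reference gene's orthologs in the target species), and
#' R the set of reference-species leaves that are orthologous, in the
#' same sense, to at least one member of O. The verdict is
#' `ortholog_1to1` when |O| = 1 and |R| = 1, `ortholog_1tomany` when
#' |O| > 1 and |R| = 1, `homolog` (many-to-many, or related only through
#' duplication nodes) when |R| > 1 or when |O| = 0 with the target
#' species present in the tree, and `absent` when the target species has
#' no leaf at all.
#'
#' @param tree Event-labelled tree from [label_events_species_overlap()].
#' @param reference_leaf Leaf label of the reference-function gene.
#' @param target_species Species id to classify against.
#' @return One of `"ortholog_1to1"`, `"ortholog_1tomany"`, `"homolog"`,
#'   `"absent"`.
#' @export
classify_relation <- function(tree, reference_leaf, target_species) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$events))
    stop("tree is not event-labelled; run label_events_species_overlap()")
  ref_i <- match(reference_leaf, tree$tip.label)
  if (is.na(ref_i)) stop("reference leaf not in tree: ", reference_leaf)
  sp <- leaf_species(tree$tip.label)
  ref_species <- sp[ref_i]
  # the reference gene is trivially its own 1:1 ortholog; same-species
  # pairs can only join at duplication nodes under the overlap rule
  if (target_species == ref_species) return("ortholog_1to1")
  tgt <- which(sp == target_species)
  if (length(tgt) == 0L) return("absent")
  mm <- if (!is.null(tree$mrca_cache)) tree$mrca_cache
        else ape::mrca(tree)
  O <- tgt[vapply(tgt, function(t)
    .event_at(tree, mm, ref_i, t) == "speciation", logical(1))]
  if (length(O) == 0L) return("homolog")
  refs <- which(sp == ref_species)
  R <- refs[vapply(refs, function(r) {
    any(vapply(O, function(t)
      r != t && .event_at(tree, mm, r, t) == "speciation", logical(1)))
  }, logical(1))]
  n_o <- length(O); n_r <- length(R)
  if (n_o == 1L && n_r == 1L) return("ortholog_1to1")
  if (n_o > 1L && n_r == 1L) return("ortholog_1tomany")
  "homolog"
}

#' Flag multiple lineage-specific duplications within a clade
#'
#' TRUE iff the event-labelled tree contains at least two duplication
#' nodes all of whose descendant species belong to the given clade
#' (rendered as the letter "M" in the presence-absence matrix).
#'
#' @inheritParams label_events_species_overlap
#' @param clade Clade label to test.
#' @return Logical scalar.
#' @export
flag_lineage_duplications <- function(tree, species_map, clade) {
  if (is.null(tree$events))
    stop("tree is not event-labelled; run label_events_species_overlap()")
  n_tip <- ape::Ntip(tree)
  sets <- .node_species_sets(tree)
  n_dup <- 0L
  for (node in (n_tip + 1):(n_tip + tree$Nnode)) {
    if (tree$events[node - n_tip] != "duplication") next
    clades <- unname(species_map[sets[[node]]])
    if (all(!is.na(clades)) && all(clades == clade)) n_dup <- n_dup + 1L
  }
  n_dup >= 2L
}

#' Upgrade an absence to a secondary loss
#'
#' A component absent in a metazoan clade is called a secondary loss iff
#' at least one configured non-metazoan outgroup clade (for instance
#' Choanoflagellata or Capsaspora) has a verdict other than `absent` for
#' the same component — the gene is missing in the clade although
#' homologs persist outside Metazoa.
#'
#' @param component Component name (used in error messages only).
#' @param clade Clade whose verdict is being finalized.
#' @param matrix_context List with elements `verdicts` (named character
#'   vector of per-clade verdicts for this component, covering all clades
#'   including the outgroups) and `outgroups` (character vector of
#'   outgroup clade labels).
#' @return The final verdict for `(component, clade)`.
#' @export
call_secondary_loss <- function(component, clade, matrix_context) {
  v <- matrix_context$verdicts
  og <- matrix_context$outgroups
  if (is.null(og) || length(og) == 0L)
    stop("no outgroup clades configured for component ", component)
  if (!clade %in% names(v))
    stop("no verdict recorded for clade ", clade)
  if (v[[clade]] != "absent") return(v[[clade]])
  og_present <- og[og %in% names(v)]
  if (any(v[og_present] != "absent")) "secondary_loss" else "absent"
}

#' Classify one component tree against every clade
#'
#' Runs [classify_relation()] for every species in the species map,
#' aggregates species verdicts to a per-clade verdict (the strongest
#' relation found in the clade, in the order 1-to-1 > 1-to-many >
#' homolog > absent), applies the secondary-loss upgrade against the
#' outgroup clades, and attaches the lineage-duplication flag.
#'
#' @param tree Rooted gene tree (event labels are added if missing).
#' @param species_map Named character vector, species id -> clade label.
#' @param reference_leaf Leaf label of the reference-function gene.
#' @param component Component name stored in the output.
#' @param outgroup_clades Character vector of non-metazoan clade labels.
#' @return Data.frame with columns `component`, `clade`, `verdict`,
#'   `lineage_dup`.
#' @export
classify_clades <- function(tree, species_map, reference_leaf, component,
                            outgroup_clades) {
  if (is.null(tree$events))
    tree <- label_events_species_overlap(tree, species_map)
  clades <- unique(unname(species_map))
  rank <- c(ortholog_1to1 = 1, ortholog_1tomany = 2, homolog = 3,
            absent = 4)
  per_species <- vapply(names(species_map), function(s)
    classify_relation(tree, reference_leaf, s), character(1))
  verdicts <- vapply(clades, function(cl) {
    vs <- per_species[names(species_map)[species_map == cl]]
    names(rank)[min(rank[vs])]
  }, character(1))
  names(verdicts) <- clades
  ctx <- list(verdicts = verdicts, outgroups = outgroup_clades)
  final <- vapply(clades, function(cl)
    call_secondary_loss(component, cl, ctx), character(1))
  dup <- vapply(clades, function(cl)
    flag_lineage_duplications(tree, species_map, cl), logical(1))
  data.frame(component = component, clade = clades, verdict = unname(final),
             lineage_dup = unname(dup), stringsAsFactors = FALSE)
}

#' Assemble and serialize the presence-absence matrix
#'
#' Builds the component-by-clade matrix of verdict codes from a table of
#' per-(component, clade) calls. Cells carry the verdict, with `+M`
#' appended when the lineage-duplication flag is set.
#'
#' @param calls Data.frame with columns `component`, `clade`, `verdict`,
#'   `lineage_dup`, covering every (component, clade) pair.
#' @param component_order,clade_order Optional orderings; defaults to
#'   order of first appearance.
#' @return A character matrix (components x clades) of cell codes, class
#'   `presence_absence_matrix`.
#' @export
build_matrix <- function(calls, component_order = NULL, clade_order = NULL) {
  stopifnot(all(c("component", "clade", "verdict", "lineage_dup") %in%
                  names(calls)))
  comps <- if (is.null(component_order)) unique(calls$component)
           else component_order
  clades <- if (is.null(clade_order)) unique(calls$clade) else clade_order
  want <- expand.grid(component = comps, clade = clades,
                      stringsAsFactors = FALSE)
  key <- paste(calls$component, calls$clade, sep = "\r")
  missing <- want[!paste(want$component, want$clade, sep = "\r") %in% key, ]
  if (nrow(missing) > 0)
    stop("missing calls for: ",
         paste(missing$component, missing$clade, sep = "/",
               collapse = ", "))
  m <- matrix(NA_character_, length(comps), length(clades),
              dimnames = list(comps, clades))
  cell <- paste0(calls$verdict, ifelse(calls$lineage_dup, "+M", ""))
  m[cbind(match(calls$component, comps), match(calls$clade, clades))] <- cell
  class(m) <- c("presence_absence_matrix", class(m))
  m
}

#' @rdname build_matrix
#' @param matrix A `presence_absence_matrix`.
#' @param path Output/input TSV path.
#' @export
write_matrix_tsv <- function(matrix, path) {
  utils::write.table(as.data.frame(unclass(matrix)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname build_matrix
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  class(m) <- c("presence_absence_matrix", class(m))
  m
}

#' Read a species map TSV
#'
#' Two- or three-column TSV; the last two used columns are species id and
#' clade label (a leading `gene_prefix` column is tolerated and, when
#' present, must equal the species id used in leaf labels).
#'
#' @param path TSV path with a header line.
#' @return Named character vector, species id -> clade label.
#' @export
read_species_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("species map needs at least 2 columns")
  sp <- df[[ncol(df) - 1]]
  if (anyDuplicated(sp)) stop("duplicate species in map")
  setNames(df[[ncol(df)]], sp)
}

#' @rdname read_species_map
#' @param species_map Named character vector, species -> clade.
#' @export
write_species_map <- function(species_map, path) {
  utils::write.table(
    data.frame(species = names(species_map), clade = unname(species_map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
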