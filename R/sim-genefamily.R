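# Gene-family simulation by a birth-death duplication-loss process along
# a fixed, time-calibrated species tree.
#
# The simulation is gene-tree-first: events (duplications, losses) are
# drawn along species-tree branches at constant rates; speciation nodes
# copy every surviving lineage into both descendant branches. Every
# surviving gene is traceable to its recorded event history, from which
# the true orthology relations are replayed. No sequence evolution is
# involved: sequences are only needed by the motif/homology modules.

#' Simulate one gene family with recorded truth
#'
#' @param species_tree A [default_species_tree()]-style object.
#' @param dup_rate,loss_rate Duplication and loss rates in events per
#'   unit time (>= 0).
#' @param seed Integer seed; identical seeds reproduce identical
#'   families.
#' @param prefix Optional gene-id prefix (e.g. `"f3"`), used to keep ids
#'   unique across families.
#' @return List of class `family_truth`:
#'   `extinct` (TRUE when every lineage was lost — a distinct outcome,
#'   not an error); `genes` (leaf labels `"<species>|<id>"`);
#'   `newick` (gene tree with internal labels `S`/`D` for true
#'   speciation/duplication nodes and branch lengths in time units);
#'   `gene_tree` (parsed [ape::phylo], `NULL` when fewer than 2 genes
#'   survive); `events` (named by internal-node index, `"speciation"` /
#'   `"duplication"`, aligned with `gene_tree`); `relation_table`
#'   (cross-species gene pairs with class `1:1`, `1:many`, `many:many`
#'   for true ortholog pairs and `paralog` otherwise); `verdicts`
#'   (per (gene, species) classification replayed from the truth);
#'   `copy_number` (named integer per species); `history` (the raw event
#'   record: id, parent, type, depth, species); `seed`.
#' @export
simulate_gene_family <- function(species_tree, dup_rate, loss_rate, seed,
                                 prefix = "") {
  stopifnot(inherits(species_tree, "species_tree"))
  if (!is.numeric(dup_rate) || dup_rate < 0 ||
      !is.numeric(loss_rate) || loss_rate < 0)
    stop("rates must be >= 0")
  sp_tree <- species_tree$tree
  depths <- .node_depths(sp_tree)
  n_tip <- ape::Ntip(sp_tree)
  children <- .children(sp_tree)
  root <- n_tip + 1L

  env <- new.env()
  env$nodes <- list()
  env$n <- 0L
  add_node <- function(parent, type, depth, species = NA_character_) {
    env$n <- env$n + 1L
    env$nodes[[env$n]] <- list(id = env$n, parent = parent, type = type,
                               depth = depth, species = species,
                               children = integer(0))
    if (parent > 0L)
      env$nodes[[parent]]$children <- c(env$nodes[[parent]]$children,
                                        env$n)
    env$n
  }

  total_rate <- dup_rate + loss_rate
  evolve <- function(parent_id, sp_node, d_top) {
    d_bottom <- depths[sp_node]
    d <- d_top
    repeat {
      dt <- if (total_rate > 0) stats::rexp(1, total_rate) else Inf
      if (d - dt <= d_bottom) {
        if (sp_node <= n_tip) {
          add_node(parent_id, "leaf", d_bottom,
                   species = sp_tree$tip.label[sp_node])
        } else {
          sid <- add_node(parent_id, "speciation", d_bottom)
          for (ch in children[[sp_node]]) evolve(sid, ch, d_bottom)
        }
        return(invisible(NULL))
      }
      d <- d - dt
      if (stats::runif(1) < dup_rate / total_rate) {
        did <- add_node(parent_id, "duplication", d)
        evolve(did, sp_node, d)
        evolve(did, sp_node, d)
        return(invisible(NULL))
      }
      add_node(parent_id, "loss", d)
      return(invisible(NULL))
    }
  }

  .with_seed(seed, {
    rid <- add_node(0L, "speciation", depths[root])
    for (ch in children[[root]]) evolve(rid, ch, depths[root])
  })

  nodes <- env$nodes
  # assign gene ids to surviving leaves in creation order
  counters <- new.env()
  for (i in seq_along(nodes)) {
    if (nodes[[i]]$type == "leaf") {
      sp <- nodes[[i]]$species
      k <- (if (is.null(counters[[sp]])) 0L else counters[[sp]]) + 1L
      counters[[sp]] <- k
      nodes[[i]]$label <- paste0(sp, "|", prefix, "g", k)
    }
  }

  # which history nodes have at least one surviving leaf below
  alive <- logical(length(nodes))
  for (i in rev(seq_along(nodes))) {
    nd <- nodes[[i]]
    alive[i] <- nd$type == "leaf" ||
      (length(nd$children) > 0 && any(alive[nd$children]))
  }

  leaves <- which(vapply(nodes, function(n) n$type == "leaf", logical(1)))
  copy_number <- setNames(integer(n_tip), sp_tree$tip.label)
  for (i in leaves)
    copy_number[nodes[[i]]$species] <- copy_number[nodes[[i]]$species] + 1L

  history <- data.frame(
    id = vapply(nodes, `[[`, integer(1), "id"),
    parent = vapply(nodes, `[[`, integer(1), "parent"),
    type = vapply(nodes, `[[`, character(1), "type"),
    depth = vapply(nodes, `[[`, numeric(1), "depth"),
    species = vapply(nodes, `[[`, character(1), "species"),
    label = vapply(nodes, function(n)
      if (is.null(n$label)) NA_character_ else n$label, character(1)),
    stringsAsFactors = FALSE)

  base <- list(extinct = length(leaves) == 0L,
               copy_number = copy_number, history = history,
               dup_rate = dup_rate, loss_rate = loss_rate, seed = seed)
  if (length(leaves) == 0L)
    return(structure(c(base, list(genes = character(0), newick = NA,
                                  gene_tree = NULL,
                                  events = character(0),
                                  relation_table = .empty_relations(),
                                  verdicts = .empty_verdicts())),
                     class = "family_truth"))

  # pruned newick with S/D internal labels and time branch lengths
  to_newick <- function(i, parent_depth) {
    nd <- nodes[[i]]
    kids <- nd$children[alive[nd$children]]
    bl <- function(d) sprintf(":%.8f", parent_depth - d)
    if (nd$type == "leaf")
      return(paste0(nd$label, bl(nd$depth)))
    if (length(kids) == 1L) return(to_newick(kids, parent_depth))
    lab <- if (nd$type == "duplication") "D" else "S"
    paste0("(", paste(vapply(kids, to_newick, character(1), nd$depth),
                      collapse = ","),
           ")", lab, bl(nd$depth))
  }
  root_id <- 1L
  kids <- nodes[[root_id]]$children[alive[nodes[[root_id]]$children]]
  newick <- if (length(leaves) == 1L) {
    paste0(nodes[[leaves]]$label, ";")
  } else {
    # descend past unary nodes to the first binary survivor
    top <- root_id
    repeat {
      k <- nodes[[top]]$children[alive[nodes[[top]]$children]]
      if (nodes[[top]]$type == "leaf" || length(k) >= 2) break
      top <- k
    }
    nd <- nodes[[top]]
    k <- nd$children[alive[nd$children]]
    lab <- if (nd$type == "duplication") "D" else "S"
    paste0("(", paste(vapply(k, to_newick, character(1), nd$depth),
                      collapse = ","), ")", lab, ";")
  }

  gene_tree <- NULL
  events <- character(0)
  if (length(leaves) >= 2L) {
    gene_tree <- ape::read.tree(text = newick)
    events <- ifelse(gene_tree$node.label == "D", "duplication",
                     "speciation")
    names(events) <- seq_along(events)
  }

  rel <- .true_relations(nodes, leaves, alive, sp_tree$tip.label)
  structure(c(base, list(
    genes = vapply(leaves, function(i) nodes[[i]]$label, character(1)),
    newick = newick, gene_tree = gene_tree, events = events,
    relation_table = rel$pairs, verdicts = rel$verdicts)),
    class = "family_truth")
}

.empty_relations <- function()
  data.frame(gene_a = character(0), gene_b = character(0),
             class = character(0), stringsAsFactors = FALSE)

.empty_verdicts <- function()
  data.frame(gene = character(0), species = character(0),
             verdict = character(0), stringsAsFactors = FALSE)

# replay the recorded event history into pairwise relations and
# per-(gene, species) verdicts
.true_relations <- function(nodes, leaves, alive, all_species = NULL) {
  n_leaf <- length(leaves)
  labels <- vapply(leaves, function(i) nodes[[i]]$label, character(1))
  species <- vapply(leaves, function(i) nodes[[i]]$species, character(1))
  # ancestor id lists (root first excluded; order irrelevant)
  anc <- lapply(leaves, function(i) {
    out <- integer(0)
    p <- nodes[[i]]$parent
    while (p > 0L) { out <- c(out, p); p <- nodes[[p]]$parent }
    out
  })
  ortho <- matrix(FALSE, n_leaf, n_leaf)
  if (n_leaf >= 2) {
    for (i in 1:(n_leaf - 1)) {
      for (j in (i + 1):n_leaf) {
        lca <- anc[[j]][match(TRUE, anc[[j]] %in% anc[[i]])]
        ortho[i, j] <- ortho[j, i] <-
          nodes[[lca]]$type == "speciation"
      }
    }
  }
  pairs <- .empty_relations()
  if (n_leaf >= 2) {
    rows <- list()
    for (i in 1:(n_leaf - 1)) {
      for (j in (i + 1):n_leaf) {
        if (species[i] == species[j]) next
        if (!ortho[i, j]) { cls <- "paralog" } else {
          nB <- sum(ortho[i, species == species[j]])
          nA <- sum(ortho[species == species[i], j])
          cls <- if (nA == 1 && nB == 1) "1:1"
                 else if (nA == 1 || nB == 1) "1:many"
                 else "many:many"
        }
        rows[[length(rows) + 1L]] <-
          data.frame(gene_a = labels[i], gene_b = labels[j], class = cls,
                     stringsAsFactors = FALSE)
      }
    }
    if (length(rows) > 0) pairs <- do.call(rbind, rows)
  }
  if (is.null(all_species)) all_species <- unique(species)
  verd <- list()
  for (i in seq_len(n_leaf)) {
    for (s in setdiff(all_species, species[i])) {
      tgt <- which(species == s)
      O <- tgt[ortho[i, tgt]]
      v <- if (length(tgt) == 0L) "absent"
      else if (length(O) == 0L) "homolog"
      else {
        refs <- which(species == species[i])
        R <- refs[vapply(refs, function(r)
          any(ortho[r, O]), logical(1))]
        if (length(O) == 1L && length(R) == 1L) "ortholog_1to1"
        else if (length(O) > 1L && length(R) == 1L) "ortholog_1tomany"
        else "homolog"
      }
      verd[[length(verd) + 1L]] <-
        data.frame(gene = labels[i], species = s, verdict = v,
                   stringsAsFactors = FALSE)
    }
  }
  verdicts <- if (length(verd) > 0) do.call(rbind, verd)
              else .empty_verdicts()
  list(pairs = pairs, verdicts = verdicts)
}

#' @export
print.family_truth <- function(x, ...) {
  if (x$extinct) cat("family_truth: extinct (no surviving genes)\n")
  else cat(sprintf("family_truth: %d genes in %d species\n",
                   length(x$genes), sum(x$copy_number > 0)))
  invisible(x)
}
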