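# Independent brute-force oracles used across the suite. These
# deliberately avoid the package's own code paths.

# --- event-history replay: pairwise relations from the raw history ----
# Walks parent pointers in the recorded event table; never touches the
# package's tree, LCA or labelling code.
oracle_relations <- function(history) {
  leaves <- history[history$type == "leaf", , drop = FALSE]
  n <- nrow(leaves)
  parent_of <- history$parent
  type_of <- history$type
  ancestors <- function(id) {
    out <- integer(0)
    p <- parent_of[id]
    while (p > 0L) { out <- c(out, p); p <- parent_of[p] }
    out
  }
  anc <- lapply(leaves$id, ancestors)
  is_ortho <- function(i, j) {
    lca <- anc[[j]][match(TRUE, anc[[j]] %in% anc[[i]])]
    type_of[lca] == "speciation"
  }
  ortho <- matrix(FALSE, n, n)
  if (n >= 2)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      ortho[i, j] <- ortho[j, i] <- is_ortho(i, j)
  list(labels = leaves$label, species = leaves$species, ortho = ortho)
}

# per-(gene, species) verdicts replayed from the oracle ortho matrix
oracle_verdicts <- function(rel) {
  out <- list()
  n <- length(rel$labels)
  for (i in seq_len(n)) {
    for (s in setdiff(unique(rel$species), rel$species[i])) {
      tgt <- which(rel$species == s)
      O <- tgt[rel$ortho[i, tgt]]
      v <- if (length(O) == 0L) "homolog" else {
        refs <- which(rel$species == rel$species[i])
        R <- refs[vapply(refs, function(r) any(rel$ortho[r, O]),
                         logical(1))]
        if (length(O) == 1L && length(R) == 1L) "ortholog_1to1"
        else if (length(O) > 1L && length(R) == 1L) "ortholog_1tomany"
        else "homolog"
      }
      out[[length(out) + 1L]] <- data.frame(
        gene = rel$labels[i], species = s, verdict = v,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# --- brute-force best hit: scan every row ----------------------------
oracle_best_hit <- function(hits, query) {
  h <- hits[hits$query_id == query, , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(h))) {
    if (is.null(best)) { best <- h[i, ]; next }
    if (h$bitscore[i] > best$bitscore ||
        (h$bitscore[i] == best$bitscore && h$evalue[i] < best$evalue) ||
        (h$bitscore[i] == best$bitscore && h$evalue[i] == best$evalue &&
         h$subject_id[i] < best$subject_id))
      best <- h[i, ]
  }
  best$subject_id
}

# --- BH step-up by the definition ------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    vals <- m * sorted[i:m] / (i:m)
    adj[o[i]] <- min(1, min(vals))
  }
  adj
}

# --- exhaustive pairwise overlap check / greedy resolution ------------
oracle_resolve <- function(hits) {
  o <- order(-hits$bitscore, hits$start)
  h <- hits[o, , drop = FALSE]
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- max(0, min(h$end[i], h$end[j]) - max(h$start[i], h$start[j]))
      if (ov > 0.5 * min(h$end[i] - h$start[i], h$end[j] - h$start[j]))
        ok <- FALSE
    }
    keep[i] <- ok
  }
  out <- h[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# --- rasterized ellipse area (pixel-counting oracle) ------------------
oracle_ellipse_area <- function(a, b, dim = c(128L, 128L),
                                angle = 0) {
  cy <- (dim[1] + 1) / 2; cx <- (dim[2] + 1) / 2
  yy <- matrix(seq_len(dim[1]), dim[1], dim[2]) - cy
  xx <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE) - cx
  u <- xx * cos(angle) + yy * sin(angle)
  v <- -xx * sin(angle) + yy * cos(angle)
  sum((u / a)^2 + (v / b)^2 <= 1)
}

# --- exhaustive window-probability enumeration on a small alphabet ----
# enumerate all k-mers over `letters` with i.i.d. probabilities `probs`
# and sum the probability of those matching `pattern` (list of allowed
# character vectors, NULL = any)
oracle_window_prob <- function(pattern, letters, probs) {
  k <- length(pattern)
  grid <- as.matrix(do.call(expand.grid,
                            c(rep(list(letters), k),
                              list(stringsAsFactors = FALSE))))
  ok <- rep(TRUE, nrow(grid))
  pr <- rep(1, nrow(grid))
  for (p in seq_len(k)) {
    col <- grid[, p]
    pr <- pr * unname(probs[col])
    if (!is.null(pattern[[p]])) ok <- ok & col %in% pattern[[p]]
  }
  sum(pr[ok])
}

# default simulated study system shared by several tests
sim_system <- function() default_species_tree()
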