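# End-to-end orchestration: comparative (homology -> orthology ->
# presence-absence matrix) and physiology (detection -> rate model ->
# uptake coupling) runs, with logged thresholds and seeds.

# md5 of a deparsed R object, for run provenance
.config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Collapse weakly supported nodes to polytomies
#'
#' Internal nodes whose support value is below `min_support` are
#' collapsed (their branch is contracted), yielding polytomies that the
#' species-overlap labeller treats pairwise.
#'
#' @param tree An [ape::phylo] with numeric node labels in \[0, 100\].
#' @param min_support Support threshold; `NULL` disables collapsing.
#' @return The (possibly multifurcating) tree.
#' @export
collapse_low_support <- function(tree, min_support = NULL) {
  if (is.null(min_support)) return(tree)
  if (is.null(tree$node.label)) return(tree)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  if (any(!is.na(sup) & (sup < 0 | sup > 100)))
    stop("support values must lie in [0, 100]")
  weak <- which(!is.na(sup) & sup < min_support)
  if (length(weak) == 0) return(tree)
  n_tip <- ape::Ntip(tree)
  has_bl <- !is.null(tree$edge.length)
  if (!has_bl) tree$edge.length <- rep(1, nrow(tree$edge))
  weak_nodes <- n_tip + weak
  root <- n_tip + 1L
  idx <- tree$edge[, 2] %in% setdiff(weak_nodes, root)
  tree$edge.length[idx] <- 0
  out <- ape::di2multi(tree, tol = 1e-12)
  if (!has_bl) out$edge.length <- NULL
  out
}

#' Run the comparative (presence-absence) pipeline
#'
#' For every pathway component, roots and event-labels its gene tree,
#' classifies every clade against the component's reference-function
#' gene, applies the secondary-loss upgrade against the outgroup clades,
#' and assembles the presence-absence matrix. The matrix is rendered
#' under both a sponge-sister and a ctenophore-sister column ordering —
#' a pure presentation choice; verdicts are identical.
#'
#' @param config List with elements:
#'   `trees` (named list, component -> Newick string or file path),
#'   `species_map` (named character, species -> clade),
#'   `references` (named character, component -> reference leaf label),
#'   `outgroup_clades` (character),
#'   `min_support` (optional support-collapse threshold),
#'   `clade_order_porifera_first` / `clade_order_ctenophora_first`
#'   (optional explicit column orderings).
#' @return List of class `comparative_run`: `calls`,
#'   `matrix_porifera_sister`, `matrix_ctenophora_sister`, `log`
#'   (data.frame of operations with thresholds), `config_hash`.
#' @export
run_comparative <- function(config) {
  needed <- c("trees", "species_map", "references", "outgroup_clades")
  missing <- needed[!needed %in% names(config)]
  if (length(missing) > 0)
    stop("missing config entries: ", paste(missing, collapse = ", "))
  comps <- names(config$trees)
  no_ref <- setdiff(comps, names(config$references))
  if (length(comps) == 0) stop("no component trees configured")
  if (length(no_ref) > 0)
    stop("components without a reference gene: ",
         paste(no_ref, collapse = ", "))
  hash <- .config_hash(config)
  logs <- list()
  calls <- list()
  for (comp in comps) {
    src <- config$trees[[comp]]
    tree <- if (file.exists(src)) read_newick(file = src)
            else read_newick(text = src)
    outgroup_species <- names(config$species_map)[
      config$species_map %in% config$outgroup_clades]
    tree <- root_gene_tree(tree, outgroup_species)
    tree <- collapse_low_support(tree, config$min_support)
    tree <- label_events_species_overlap(tree, config$species_map)
    calls[[comp]] <- classify_clades(
      tree, config$species_map, config$references[[comp]], comp,
      config$outgroup_clades)
    logs[[comp]] <- data.frame(
      operation = "classify", component = comp,
      reference = config$references[[comp]],
      min_support = if (is.null(config$min_support)) NA_real_
                    else config$min_support,
      config_hash = hash, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  clades <- unique(unname(config$species_map))
  po <- config$clade_order_porifera_first
  co <- config$clade_order_ctenophora_first
  if (is.null(po))
    po <- unique(c(intersect(c("Demospongiae", "Hexactinellida",
                               "Calcarea", "Homoscleromorpha"), clades),
                   clades))
  if (is.null(co))
    co <- unique(c(intersect("Ctenophora", clades), clades))
  m1 <- build_matrix(calls, clade_order = po)
  m2 <- build_matrix(calls, clade_order = co)
  attr(m1, "config_hash") <- hash
  attr(m2, "config_hash") <- hash
  structure(list(calls = calls, matrix_porifera_sister = m1,
                 matrix_ctenophora_sister = m2,
                 log = do.call(rbind, logs), config_hash = hash),
            class = "comparative_run")
}

#' Run the physiology pipeline
#'
#' Detects contraction events per individual, counts events of the
#' requested class per stable oxygen plateau, fits the Poisson
#' log-linear rate model when at least two levels are observed, and
#' (when an O2 trace accompanies an individual's area trace) computes
#' the contraction-coupled uptake contrast.
#'
#' @param experiments Named list (one entry per individual), each a list
#'   with `area` (data.frame `timestamp_s`, `area_px`) and optionally
#'   `o2` (data.frame `timestamp_s`, `o2_uM`).
#' @param plateaus Data.frame with columns `level`, `start_s`, `end_s`:
#'   the stable windows of the oxygen schedule, shared by all
#'   individuals.
#' @param config Optional list: `detector` (a [contraction_config()]),
#'   `class_filter` (event class counted; default `"full_body"`),
#'   `respiration_window` (samples; default 9), `n_shuffles`, `seed`.
#' @return List of class `physiology_run`: `events` (per individual),
#'   `counts` (individual x level with exposures), `rate_fit` (or NULL),
#'   `coupling` (per individual with an O2 trace), `config_hash`.
#' @export
run_physiology <- function(experiments, plateaus, config = list()) {
  stopifnot(is.list(experiments), length(experiments) > 0,
            all(c("level", "start_s", "end_s") %in% names(plateaus)))
  det <- config$detector
  if (is.null(det)) det <- contraction_config()
  cls <- config$class_filter
  if (is.null(cls)) cls <- "full_body"
  seed <- if (is.null(config$seed)) 1 else config$seed
  nsh <- if (is.null(config$n_shuffles)) 999 else config$n_shuffles
  rw <- if (is.null(config$respiration_window)) 9L
        else config$respiration_window
  hash <- .config_hash(list(plateaus = plateaus, config = config))
  events <- list()
  counts <- list()
  coupling <- list()
  for (ind in names(experiments)) {
    ex <- experiments[[ind]]
    ev <- detect_contractions(ex$area, det)
    events[[ind]] <- ev
    for (k in seq_len(nrow(plateaus))) {
      iv <- c(plateaus$start_s[k], plateaus$end_s[k])
      evc <- ev[ev$class == cls, , drop = FALSE]
      counts[[length(counts) + 1L]] <- data.frame(
        individual = ind, level = plateaus$level[k],
        count = sum(evc$start_s >= iv[1] & evc$start_s < iv[2]),
        exposure_days = (iv[2] - iv[1]) / 86400,
        stringsAsFactors = FALSE)
    }
    if (!is.null(ex$o2) && nrow(ev) > 0) {
      rates <- respiration_rate(ex$o2, rw)
      coupling[[ind]] <- tryCatch(
        phase_coupled_uptake(rates, ev, n_shuffles = nsh, seed = seed),
        error = function(e) NULL)
    }
  }
  counts <- do.call(rbind, counts)
  fit <- NULL
  if (length(unique(counts$level)) >= 2 && sum(counts$count) > 0)
    fit <- fit_rate_model(counts)
  structure(list(events = events, counts = counts, rate_fit = fit,
                 coupling = coupling, config_hash = hash),
            class = "physiology_run")
}
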