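## Branch label of the edge above `node` in a rooted species tree.
branch_label <- function(stree, node) {
  n <- length(stree$tip.label)
  if (node <= n) return(stree$tip.label[node])
  if (node == n + 1L) return("root")
  lbl <- stree$node.label
  if (!is.null(lbl) && !is.na(lbl[node - n]) && nzchar(lbl[node - n]))
    lbl[node - n]
  else paste0("node", node)
}

#' Map a foreign ortholog group to a species-tree branch
#'
#' Each foreign ortholog group is treated as one founding HGT event placed,
#' single-gain Dollo-style, on the edge above the most recent common
#' ancestor of the species carrying the group. Groups present in every
#' species map to the root edge: such events occurred anywhere between the
#' origin of the phylum and the base of the tree. Secondary losses are
#' silently absorbed by the MRCA assignment (no gain-plus-loss
#' optimisation).
#'
#' @param species_present Character vector of species (tip labels) in which
#'   the group is found.
#' @param stree Rooted species tree (`phylo`). Unrooted trees are rejected;
#'   rooting is the caller's responsibility.
#' @return Character scalar: the tip label (terminal branch), an internal
#'   node label (or `nodeN`), or `"root"`.
#' @export
map_group_to_branch <- function(species_present, stree) {
  if (!ape::is.rooted(stree))
    stop("species tree must be rooted")
  species_present <- unique(species_present)
  missing <- setdiff(species_present, stree$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "))
  if (!length(species_present)) stop("species_present must be non-empty")
  if (length(species_present) == length(stree$tip.label)) return("root")
  if (length(species_present) == 1L) return(species_present)
  branch_label(stree, ape::getMRCA(stree, species_present))
}

#' Map all foreign groups onto the species tree
#'
#' @param membership Data frame `gene_id`, `group_id` (foreign groups only,
#'   e.g. groups containing at least one class C gene).
#' @param gene_species Data frame `gene_id`, `species`.
#' @param stree Rooted species tree (`phylo`).
#' @return `data.frame`: `group_id`, `branch`, `n_species`.
#' @export
map_groups_to_branches <- function(membership, gene_species, stree) {
  mb <- as.data.table(membership)
  gs <- as.data.table(gene_species)[, .(gene_id, species)]
  d <- merge(mb, gs, by = "gene_id")
  if (nrow(d) < nrow(mb))
    stop("genes with no species assignment: ",
         paste(head(setdiff(mb$gene_id, gs$gene_id), 5L), collapse = ", "))
  out <- d[, .(branch = map_group_to_branch(unique(species), stree),
               n_species = length(unique(species))), by = group_id]
  setorder(out, group_id)
  setDF(out)
  out
}

#' Per-branch HGT event counts
#'
#' Counts the ortholog groups mapping to every branch of the species tree
#' (the per-branch event numbers of a taxon phylogeny figure). Branches with
#' no events are reported with count 0; the counts sum to the number of
#' assigned groups.
#'
#' @param assignments Data frame from [map_groups_to_branches()].
#' @param stree Rooted species tree (`phylo`).
#' @return `data.frame`: `branch`, `count`, one row per tree edge (the root
#'   edge included as `"root"`).
#' @export
branch_event_counts <- function(assignments, stree) {
  n <- length(stree$tip.label)
  nodes <- seq_len(n + stree$Nnode)
  branches <- vapply(nodes, branch_label, character(1), stree = stree)
  tab <- table(factor(assignments$branch, levels = unique(branches)))
  out <- data.frame(branch = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  unknown <- setdiff(assignments$branch, out$branch)
  if (length(unknown))
    stop("assignments to branches not in tree: ",
         paste(unknown, collapse = ", "))
  out
}
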