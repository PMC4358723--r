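#' Eligibility for phylogenetic validation
#'
#' Only genes with any metazoan match of bitscore at or above
#' `validation_met_bitscore_min` can be tested: without metazoan sequences in
#' the tree there is nothing for the foreign gene to be (non-)monophyletic
#' with. Genes below the cutoff are `not_applicable`; for those, the absence
#' of metazoan matches combined with strong non-metazoan matches is itself
#' the evidence of foreignness.
#'
#' @param scores Gene score table with a `best_met` column.
#' @param thresholds An [hgt_thresholds()] object.
#' @return Logical vector.
#' @export
validation_eligible <- function(scores, thresholds = hgt_thresholds()) {
  t <- as_thresholds(thresholds)
  met <- ifelse(is.na(scores$best_met), 0, scores$best_met)
  met >= t$validation_met_bitscore_min
}

#' Monophyly on an unrooted tree
#'
#' A tip set is monophyletic in the unrooted sense when removal of a single
#' edge bipartitions the tips into exactly the set and its complement.
#' Multifurcations are treated as soft polytomies: the set is monophyletic if
#' some resolution of the polytomy would make it so. Singleton sets and the
#' full tip set are monophyletic by convention. The result is invariant under
#' re-rooting and tip-order permutation.
#'
#' @param tree A `phylo` object (rooted trees are treated as unrooted).
#' @param tips Character vector of tip labels (or integer tip indices).
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((a1,a2),(b1,b2));")
#' is_monophyletic(tr, c("a1", "a2"))  # TRUE
#' is_monophyletic(tr, c("a1", "b1"))  # FALSE
is_monophyletic <- function(tree, tips) {
  n <- length(tree$tip.label)
  idx <- if (is.character(tips)) match(tips, tree$tip.label) else as.integer(tips)
  if (anyNA(idx)) stop("tips not in tree: ",
                       paste(tips[is.na(idx)], collapse = ", "))
  if (!length(idx)) stop("tip set must be non-empty")
  idx <- unique(idx)
  if (length(idx) == 1L || length(idx) == n) return(TRUE)
  in_set <- rep(FALSE, n)
  in_set[idx] <- TRUE

  desc <- phangorn::Descendants(tree, seq_len(n + tree$Nnode), type = "tips")
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  root <- n + 1L
  for (v in as.integer(names(children))) {
    parts <- lapply(children[[as.character(v)]], function(ch) desc[[ch]])
    if (v != root) {
      comp <- setdiff(seq_len(n), desc[[v]])
      if (length(comp)) parts <- c(parts, list(comp))
    }
    pure <- vapply(parts, function(p) {
      s <- in_set[p]
      all(s) || !any(s)
    }, logical(1))
    if (all(pure)) return(TRUE)
  }
  FALSE
}

## taxon labels and tip categories for a validation tree
tree_taxa <- function(tree, focal_tips, delim = "|") {
  labels <- tree$tip.label
  missing <- setdiff(focal_tips, labels)
  if (length(missing))
    stop("focal tips not in tree: ", paste(missing, collapse = ", "))
  other <- setdiff(labels, focal_tips)
  info <- parse_tip_labels(other, delim)
  list(labels = labels, focal = focal_tips, other = other,
       taxon = setNames(info$taxon, info$label))
}

## all bipartition sides (as tip-label sets) of a tree
bipartition_sides <- function(tree) {
  n <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, seq_len(n + tree$Nnode), type = "tips")
  sides <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    side <- desc[[child]]
    sides[[length(sides) + 1L]] <- tree$tip.label[side]
  }
  sides
}

#' Monophyly-based validation of a foreign gene tree
#'
#' Applies the topological validation rule to an unrooted, taxon-labelled
#' gene tree. Own-phylum tips are set aside first (in recent transfers the
#' best own-phylum matches are not orthologs of the foreign gene, so their
#' placement is uninformative). The tree is then:
#'
#' * `validated_single_donor` - the focal tips plus all tips of exactly one
#'   donor kingdom form a bipartition side; since the side contains nothing
#'   else, every metazoan tip is excluded from it by construction;
#' * `validated_multiple_donors` - focal plus the union of two or more
#'   kingdoms forms such a side;
#' * `not_validated` - no donor-only grouping exists; the reason records
#'   whether the focal tips instead group monophyletically with the
#'   metazoans (`groups_with_metazoa`) or with neither set.
#'
#' A tree with no metazoan tips outside the own phylum can still validate:
#' the metazoan condition is vacuous. With `strict = FALSE` the donor test
#' relaxes to "focal nested within a clade containing only tips of one
#' kingdom" (the kingdom need not be complete).
#'
#' @param tree A `phylo` object or Newick string; tip labels `id|TAXON` with
#'   taxa from [taxon_groups()].
#' @param focal_tips Tip labels of the foreign gene's own sequences.
#' @param own_phylum Taxon label treated as the focal species' phylum.
#'   Default `"own_phylum"`.
#' @param delim Tip label delimiter. Default `"|"`.
#' @param strict Use the strict (whole-kingdom) donor test. Default `TRUE`.
#' @return List of class `hgt_validation`: `status`, `donor` (kingdom,
#'   `"ambiguous"`, or `NA`), `reason`, `rescue` (always `FALSE` here).
#' @export
validate_gene_tree <- function(tree, focal_tips, own_phylum = "own_phylum",
                               delim = "|", strict = TRUE) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  tt <- tree_taxa(tree, focal_tips, delim)
  res <- function(status, donor = NA_character_, reason = NA_character_)
    structure(list(status = status, donor = donor, reason = reason,
                   rescue = FALSE), class = "hgt_validation")

  own <- names(tt$taxon)[tt$taxon == own_phylum]
  if (length(own)) {
    keep <- setdiff(tt$labels, own)
    if (length(keep) < 3L)
      return(res("not_validated", reason = "too_few_tips_after_pruning"))
    tree <- ape::keep.tip(tree, keep)
    tt <- tree_taxa(tree, focal_tips, delim)
  }
  met <- names(tt$taxon)[tt$taxon == "metazoa"]
  kingdoms <- intersect(donor_kingdoms(), unique(tt$taxon))
  if (!length(kingdoms))
    return(res("not_validated", reason = "no_nonmetazoan_tips"))

  king_tips <- function(ks) names(tt$taxon)[tt$taxon %in% ks]
  single <- character()
  for (k in kingdoms) {
    ok <- if (strict) {
      is_monophyletic(tree, c(tt$focal, king_tips(k)))
    } else {
      sides <- bipartition_sides(tree)
      any(vapply(sides, function(s) {
        all(tt$focal %in% s) &&
          all(s %in% c(tt$focal, king_tips(k))) &&
          any(s %in% king_tips(k))
      }, logical(1)))
    }
    if (ok) single <- c(single, k)
  }
  if (length(single))
    return(res("validated_single_donor",
               donor = if (length(single) == 1L) single else "ambiguous"))

  if (length(kingdoms) >= 2L) {
    for (m in 2:length(kingdoms)) {
      combos <- combn(kingdoms, m, simplify = FALSE)
      for (ks in combos) {
        if (is_monophyletic(tree, c(tt$focal, king_tips(ks))))
          return(res("validated_multiple_donors", donor = "ambiguous"))
      }
    }
  }
  met_grouping <- length(met) > 0 &&
    is_monophyletic(tree, c(tt$focal, met))
  res("not_validated",
      reason = if (met_grouping) "groups_with_metazoa"
               else "no_donor_grouping")
}

#' @export
print.hgt_validation <- function(x, ...) {
  cat("validation:", x$status,
      if (!is.na(x$donor)) paste0("(donor: ", x$donor, ")") else "",
      if (isTRUE(x$rescue)) "[rescued]" else "", "\n")
  invisible(x)
}

#' Contamination rescue check
#'
#' Around one in eight unvalidated trees fails validation only because a
#' single metazoan-labelled protein sits inside a non-metazoan clade - the
#' signature of a contaminated database entry rather than genuine metazoan
#' ancestry. For each metazoan tip whose smallest non-trivial bipartition
#' side contains no other metazoan tip and at least one non-metazoan tip,
#' this relabels that tip to the side's majority donor kingdom and re-runs
#' validation. Returns `TRUE` if any single relabelling validates the tree.
#' Evaluating rescue on an already-validated tree is a precondition
#' violation: the function warns and returns `NA`.
#'
#' @inheritParams validate_gene_tree
#' @return `TRUE`, `FALSE`, or `NA` (precondition violated).
#' @export
contamination_rescue <- function(tree, focal_tips,
                                 own_phylum = "own_phylum", delim = "|",
                                 strict = TRUE) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  base <- validate_gene_tree(tree, focal_tips, own_phylum, delim, strict)
  if (base$status != "not_validated") {
    warning("rescue evaluated on a tree that is not 'not_validated'")
    return(NA)
  }
  tt <- tree_taxa(tree, focal_tips, delim)
  own <- names(tt$taxon)[tt$taxon == own_phylum]
  work <- if (length(own)) ape::keep.tip(tree, setdiff(tt$labels, own)) else tree
  wt <- tree_taxa(work, focal_tips, delim)
  met <- names(wt$taxon)[wt$taxon == "metazoa"]
  if (!length(met)) return(FALSE)

  sides <- bipartition_sides(work)
  ntip <- length(work$tip.label)
  for (m_tip in met) {
    containing <- lapply(sides, function(s)
      if (m_tip %in% s) s else setdiff(work$tip.label, s))
    sizes <- lengths(containing)
    ok <- sizes >= 2L & sizes <= ntip - 1L
    if (!any(ok)) next
    side <- containing[ok][[which.min(sizes[ok])]]
    others <- setdiff(side, m_tip)
    other_taxa <- wt$taxon[intersect(others, names(wt$taxon))]
    if (any(other_taxa == "metazoa")) next
    kt <- other_taxa[other_taxa %in% donor_kingdoms()]
    if (!length(kt)) next
    counts <- table(factor(kt, levels = donor_kingdoms()))
    new_kingdom <- names(counts)[which.max(counts)]  # ties: kingdom order
    relab <- tree
    info <- parse_tip_labels(m_tip, delim)
    relab$tip.label[relab$tip.label == m_tip] <-
      paste0(info$id, delim, new_kingdom)
    v <- validate_gene_tree(relab, focal_tips, own_phylum, delim, strict)
    if (v$status %in% c("validated_single_donor", "validated_multiple_donors"))
      return(TRUE)
  }
  FALSE
}

#' Agreement between phylogenetic and bitscore-based donor
#'
#' For a validated tree with an unambiguous donor kingdom, reports whether
#' the phylogenetically inferred donor matches the bitscore-based donor from
#' [assign_donor_taxon()]. `NA` when the tree is not validated or the donor
#' is ambiguous.
#'
#' @param outcome An `hgt_validation` result.
#' @param score_donor Donor kingdom from the bitscore reduction.
#' @return `TRUE`, `FALSE`, or `NA`.
#' @export
phylo_origin <- function(outcome, score_donor) {
  if (!outcome$status %in% c("validated_single_donor",
                             "validated_multiple_donors")) return(NA)
  if (is.na(outcome$donor) || outcome$donor == "ambiguous") return(NA)
  identical(outcome$donor, score_donor)
}
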