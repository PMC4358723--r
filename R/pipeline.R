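#' Run the full HGT detection pipeline on a study
#'
#' Convenience driver chaining every stage on an `hgt_study` (generated by
#' [generate_study()] or re-read by [read_study()]): best-hit reduction and
#' gene scoring, viral class V exclusion (before ortholog grouping, so viral
#' artefacts cannot seed groups), similarity-graph Markov clustering,
#' class C/B/A assignment, phylogenetic validation with contamination
#' rescue, scaffold linkage, intron contingency tests, and event mapping of
#' foreign ortholog groups onto the species tree.
#'
#' @param study An `hgt_study`.
#' @param thresholds An [hgt_thresholds()] object.
#' @return Object of class `hgt_result`: list with `scores` (classified gene
#'   table), `membership`, `validation`, `linkage`, `intron_all`,
#'   `intron_bacterial`, `events` and `event_counts`.
#' @export
run_study_pipeline <- function(study, thresholds = hgt_thresholds()) {
  stopifnot(inherits(study, "hgt_study"))
  t <- as_thresholds(thresholds)

  best <- reduce_best_hits(study$hits)
  scores <- gene_scores(best, study$tx2gene)

  viral_genes <- scores$gene_id[flag_viral(scores, t)]
  g <- build_similarity_graph(study$pairwise, t)
  drop <- intersect(igraph::V(g)$name, viral_genes)
  if (length(drop)) g <- igraph::delete_vertices(g, drop)
  membership <- mcl_cluster(g, inflation = t$mcl_inflation)
  classified <- assign_hgt_classes(scores, membership, t)

  ## phylogenetic validation of eligible candidates with a gene tree
  cand <- classified$gene_id[class_at_least(classified$hgt_class, "C") &
                               validation_eligible(classified, t)]
  cand <- intersect(cand, names(study$gene_trees))
  val <- rbindlist(lapply(cand, function(gn) {
    tr <- ape::read.tree(text = study$gene_trees[[gn]])
    v <- validate_gene_tree(tr, paste0(gn, "|focal"))
    resc <- if (v$status == "not_validated")
      isTRUE(contamination_rescue(tr, paste0(gn, "|focal"))) else FALSE
    sd <- classified$donor[classified$gene_id == gn]
    data.table(gene_id = gn, status = v$status, donor_tree = v$donor,
               reason = v$reason, rescue = resc,
               agree = phylo_origin(v, sd))
  }))
  if (!nrow(val))
    val <- data.table(gene_id = character(), status = character(),
                      donor_tree = character(), reason = character(),
                      rescue = logical(), agree = logical())

  linkage <- linkage_test(study$gene_models, classified, "C", t)
  intron_all <- intron_contingency(study$gene_models, classified, "C",
                                   thresholds = t)
  intron_bact <- intron_contingency(study$gene_models, classified, "C",
                                    origin = "bacteria", thresholds = t)

  ## founding events: groups containing at least one class C gene
  cls <- as.data.table(classified)
  fg_groups <- unique(cls[class_at_least(hgt_class, "C"), group_id])
  mb <- cls[group_id %in% fg_groups, .(gene_id, group_id)]
  stree <- ape::read.tree(text = study$species_tree)
  gene_sp <- unique(as.data.table(study$tx2gene)[, .(gene_id, species)])
  events <- map_groups_to_branches(mb, gene_sp, stree)
  counts <- branch_event_counts(events, stree)

  structure(list(scores = classified, membership = membership,
                 validation = setDF(val), linkage = linkage,
                 intron_all = intron_all, intron_bacterial = intron_bact,
                 events = events, event_counts = counts),
            class = "hgt_result")
}

#' @export
print.hgt_result <- function(x, ...) {
  cls <- table(x$scores$hgt_class)
  cat("HGT pipeline result:\n")
  cat(sprintf("  genes scored: %d (C: %d, B: %d, A: %d, class V: %d)\n",
              nrow(x$scores), sum(cls[c("C", "B", "A")]),
              sum(cls[c("B", "A")]), cls[["A"]], sum(x$scores$class_v)))
  if (nrow(x$validation))
    cat(sprintf("  validated: %d/%d trees (+%d rescued)\n",
                sum(grepl("^validated", x$validation$status)),
                nrow(x$validation), sum(x$validation$rescue)))
  cat(sprintf("  unlinked foreign genes: %d/%d\n",
              sum(!x$linkage$linked), nrow(x$linkage)))
  invisible(x)
}

#' Score pipeline predictions against planted truth
#'
#' Compares an [run_study_pipeline()] result with the planted labels of the
#' generating study. Planted foreign genes are the ancient, recent and
#' contaminant categories - all three carry the foreign bitscore signature,
#' and contaminants are expected to be flagged by the linkage control rather
#' than by scores. Returns, per class, precision and recall of the predicted
#' class against the planted foreign set; the fraction of planted
#' contaminants left unlinked; the fraction of planted events (ancient and
#' recent) whose ortholog group maps to the true species-tree branch; and
#' validation/donor-agreement summaries.
#'
#' @param result An `hgt_result`.
#' @param truth Truth table from [truth_labels()].
#' @return List with elements `precision` (named vector over C/B/A),
#'   `recall`, `contaminant_unlinked_rate`, `event_branch_accuracy`,
#'   `validation_rate`, `donor_agreement`, `n_true_foreign`.
#' @export
evaluate_recovery <- function(result, truth) {
  stopifnot(inherits(result, "hgt_result"))
  sc <- as.data.table(result$scores)
  tr <- as.data.table(truth)
  if (!setequal(sc$gene_id, tr$gene_id))
    stop("gene ids in prediction and truth do not match")
  d <- merge(sc, tr[, .(gene_id, category, family_id, event_branch)],
             by = "gene_id")
  foreign_true <- d$category %in% c("ancient_HGT", "recent_HGT",
                                    "contaminant")
  precision <- recall <- setNames(numeric(3), c("C", "B", "A"))
  for (L in c("C", "B", "A")) {
    pred <- class_at_least(d$hgt_class, L) & !d$class_v
    tp <- sum(pred & foreign_true)
    precision[L] <- if (sum(pred)) tp / sum(pred) else NA_real_
    recall[L] <- if (sum(foreign_true)) tp / sum(foreign_true) else NA_real_
  }

  contam <- tr$gene_id[tr$category == "contaminant"]
  lk <- as.data.table(result$linkage)
  lk_c <- lk[gene_id %in% contam]
  contaminant_unlinked <- if (nrow(lk_c)) mean(!lk_c$linked) else NA_real_

  ev_truth <- unique(tr[category %in% c("ancient_HGT", "recent_HGT"),
                        .(family_id, event_branch)])
  ev <- as.data.table(result$events)
  ok <- vapply(seq_len(nrow(ev_truth)), function(i) {
    members <- tr$gene_id[tr$family_id == ev_truth$family_id[i]]
    grp <- unique(d$group_id[d$gene_id %in% members])
    if (length(grp) != 1L) return(FALSE)  # split/merged group: a miss
    br <- ev$branch[ev$group_id == grp]
    length(br) == 1L && br == ev_truth$event_branch[i]
  }, logical(1))
  event_accuracy <- if (nrow(ev_truth)) mean(ok) else NA_real_

  val <- result$validation
  validation_rate <- if (nrow(val))
    mean(grepl("^validated", val$status)) else NA_real_
  donor_agreement <- if (nrow(val) && any(!is.na(val$agree)))
    mean(val$agree, na.rm = TRUE) else NA_real_

  list(precision = precision, recall = recall,
       contaminant_unlinked_rate = contaminant_unlinked,
       event_branch_accuracy = event_accuracy,
       validation_rate = validation_rate,
       donor_agreement = donor_agreement,
       n_true_foreign = sum(tr$category %in%
                              c("ancient_HGT", "recent_HGT",
                                "contaminant")))
}
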