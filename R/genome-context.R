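## Ordered class helper: rank of a gene's class against a requested class.
class_at_least <- function(hgt_class, level = c("C", "B", "A")) {
  level <- match.arg(level)
  as.integer(factor(as.character(hgt_class),
                    levels = c("native", "C", "B", "A"))) >=
    match(level, c("native", "C", "B", "A"))
}

#' Scaffold linkage of foreign genes to native genes
#'
#' A foreign gene found on the same scaffold/contig as at least one native
#' gene (HGT index below `h_min`, including genes with no non-metazoan hit at
#' all) is considered linked. Unlinked foreign genes are candidates for
#' assembly contamination: a contaminating sequence carries no flanking
#' native genes. The linked fraction is invariant under scaffold renaming.
#'
#' @param models Gene model table from [read_gene_models()].
#' @param scores Classified score table from [assign_hgt_classes()].
#' @param hgt_class Minimum class of the foreign genes tested
#'   (`"C"`, `"B"`, `"A"`). Default `"C"`.
#' @param thresholds An [hgt_thresholds()] object (native cutoff `h_min`).
#' @return `data.frame`, one row per foreign gene with a gene model:
#'   `gene_id`, `scaffold`, `linked`, `n_native_on_scaffold`. Foreign genes
#'   without a model are dropped with a warning and listed in the
#'   `"unplaced"` attribute.
#' @export
linkage_test <- function(models, scores, hgt_class = "C",
                         thresholds = hgt_thresholds()) {
  t <- as_thresholds(thresholds)
  sc <- as.data.table(scores)
  mod <- as.data.table(models)[, .(scaffold = scaffold[1L]), by = gene_id]
  native <- sc$gene_id[is.na(sc$h) | sc$h < t$h_min]
  foreign <- sc$gene_id[class_at_least(sc$hgt_class, hgt_class)]

  unplaced <- setdiff(foreign, mod$gene_id)
  if (length(unplaced))
    warning(length(unplaced), " foreign genes without a gene model are ",
            "excluded from the linkage denominator")
  native_per_scaffold <- mod[gene_id %in% native, .N, by = scaffold]
  out <- mod[gene_id %in% setdiff(foreign, unplaced)]
  out <- merge(out, native_per_scaffold, by = "scaffold", all.x = TRUE)
  out[is.na(N), N := 0L]
  setnames(out, "N", "n_native_on_scaffold")
  out[, linked := n_native_on_scaffold >= 1L]
  setcolorder(out, c("gene_id", "scaffold", "linked", "n_native_on_scaffold"))
  setorder(out, gene_id)
  setDF(out)
  attr(out, "unplaced") <- unplaced
  out
}

## Pearson chi-squared on a 2x2 table, flagged unreliable when any expected
## cell < 1 or the table is degenerate (a zero margin).
contingency_chisq <- function(tab, correct = FALSE, alpha = 0.05) {
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    return(structure(list(table = tab, statistic = NA_real_,
                          p_value = NA_real_, significant = FALSE,
                          reliable = FALSE),
                     class = "hgt_contingency"))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  structure(list(table = tab,
                 statistic = unname(ct$statistic),
                 p_value = unname(ct$p.value),
                 significant = ct$p.value <= alpha,
                 reliable = all(ct$expected >= 1)),
            class = "hgt_contingency")
}

#' @export
print.hgt_contingency <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi-squared = %.4g, p = %.3g%s%s\n",
              x$statistic, x$p_value,
              if (isTRUE(x$significant)) " (significant at 0.05)" else "",
              if (!isTRUE(x$reliable)) " [unreliable: low expected counts]"
              else ""))
  invisible(x)
}

#' Intron-presence contingency test for foreign vs native genes
#'
#' Compares the proportion of intron-bearing genes between foreign genes of a
#' given class (optionally restricted to one donor kingdom, e.g. bacteria)
#' and native genes, with a Pearson chi-squared test. A gene "has introns"
#' when any of its transcripts has two or more exons. Recently transferred
#' prokaryotic genes have had little time to gain introns, so a deficit of
#' introns among bacterial-origin foreign genes indicates recent transfer
#' (or contamination); parity with native genes indicates domesticated,
#' older transfers.
#'
#' @inheritParams linkage_test
#' @param origin Optional donor kingdom restricting the foreign set.
#' @param correct Apply Yates' continuity correction. Default `FALSE`
#'   (plain Pearson).
#' @param alpha Significance threshold. Default 0.05.
#' @return Object of class `hgt_contingency`: `table` (2x2,
#'   foreign/native x introns/no introns), `statistic`, `p_value`,
#'   `significant`, `reliable` (FALSE when any expected cell < 1 or the
#'   table is degenerate).
#' @export
intron_contingency <- function(models, scores, hgt_class = "C",
                               origin = NULL, correct = FALSE,
                               alpha = 0.05,
                               thresholds = hgt_thresholds()) {
  sc <- as.data.table(scores)
  mod <- as.data.table(models)
  has_introns <- mod[, .(introns = any(exon_count >= 2L)), by = gene_id]

  foreign <- class_at_least(sc$hgt_class, hgt_class) & !sc$class_v
  if (!is.null(origin)) foreign <- foreign & !is.na(sc$donor) &
      sc$donor == origin
  native <- as.character(sc$hgt_class) == "native" & !sc$class_v

  grp <- data.table(gene_id = sc$gene_id,
                    set = ifelse(foreign, "foreign",
                                 ifelse(native, "native", NA_character_)))
  grp <- merge(grp[!is.na(set)], has_introns, by = "gene_id")
  tab <- matrix(c(
    sum(grp$set == "foreign" & grp$introns),
    sum(grp$set == "foreign" & !grp$introns),
    sum(grp$set == "native" & grp$introns),
    sum(grp$set == "native" & !grp$introns)
  ), nrow = 2L, byrow = TRUE,
  dimnames = list(c("foreign", "native"), c("introns", "no_introns")))
  contingency_chisq(tab, correct = correct, alpha = alpha)
}

#' Export foreign gene positions
#'
#' Writes a TSV of scaffold, coordinates, strand and class for every foreign
#' gene, sorted by (scaffold, start) so repeated runs are byte-identical.
#' Plotting genome-location figures is left to the caller.
#'
#' @inheritParams linkage_test
#' @param path Output TSV path.
#' @return The written data frame, invisibly.
#' @export
export_positions <- function(models, scores, path, hgt_class = "C") {
  sc <- as.data.table(scores)
  keep <- class_at_least(sc$hgt_class, hgt_class)
  foreign <- sc[keep, .(gene_id, hgt_class)]
  mod <- as.data.table(models)[
    , .(scaffold = scaffold[1L], start = min(start), end = max(end),
        strand = strand[1L]), by = gene_id]
  out <- merge(foreign, mod, by = "gene_id")
  setcolorder(out, c("scaffold", "start", "end", "strand", "gene_id",
                     "hgt_class"))
  setorder(out, scaffold, start, gene_id)
  fwrite(out, path, sep = "\t")
  invisible(setDF(out))
}
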