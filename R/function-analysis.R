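#' GO-term enrichment among foreign genes
#'
#' For every GO term annotating at least one foreign gene, computes the
#' upper-tail hypergeometric probability of drawing at least the observed
#' number of term-annotated genes when sampling the foreign set from the
#' background, applies Benjamini-Hochberg correction across the tested
#' terms, and flags enrichment at `alpha`. Terms are tested as annotated (no
#' GO-graph ancestor propagation) unless `propagate` supplies a term-to-
#' ancestors list.
#'
#' @param foreign Character vector of foreign gene ids (subset of
#'   `background`).
#' @param background Character vector of background gene ids (typically all
#'   annotated genes of the species).
#' @param ann A `go_annotation` object ([read_go()] / [go_annotation()]).
#' @param alpha Enrichment threshold on the (adjusted) p-value. Default 0.05.
#' @param use_adjusted Apply the threshold to BH-adjusted p-values
#'   (default); `FALSE` thresholds raw p-values instead.
#' @param propagate Optional named list mapping each term to its ancestor
#'   terms; annotations are propagated upward before testing.
#' @return `data.frame`: `term_id`, `foreign_count`, `background_count`,
#'   `p`, `p_adj`, `enriched`, `enzyme`. Empty foreign set gives an empty
#'   table.
#' @export
go_enrichment <- function(foreign, background, ann, alpha = 0.05,
                          use_adjusted = TRUE, propagate = NULL) {
  stopifnot(inherits(ann, "go_annotation"))
  bad <- setdiff(foreign, background)
  if (length(bad))
    stop("foreign genes not in background: ", paste(head(bad, 5L),
                                                    collapse = ", "))
  g2t <- ann$gene_to_terms
  if (!is.null(propagate))
    g2t <- lapply(g2t, function(ts)
      unique(c(ts, unlist(propagate[ts], use.names = FALSE))))

  empty <- data.frame(term_id = character(), foreign_count = integer(),
                      background_count = integer(), p = numeric(),
                      p_adj = numeric(), enriched = logical(),
                      enzyme = logical())
  if (!length(foreign)) return(empty)

  long <- data.table(
    gene_id = rep(names(g2t), lengths(g2t)),
    term_id = unlist(g2t, use.names = FALSE)
  )[gene_id %in% background]
  long <- unique(long)
  N <- length(unique(background))
  n <- length(unique(foreign))
  bg_count <- long[, .(background_count = .N), by = term_id]
  fg_count <- long[gene_id %in% foreign, .(foreign_count = .N), by = term_id]
  if (!nrow(fg_count)) return(empty)

  tab <- merge(fg_count, bg_count, by = "term_id")
  tab[, p := phyper(foreign_count - 1L, background_count,
                    N - background_count, n, lower.tail = FALSE)]
  tab[, p_adj := p.adjust(p, method = "BH")]
  tab[, enriched := (if (use_adjusted) p_adj else p) <= alpha]
  tab[, enzyme := unname(ann$enzyme_flag[term_id])]
  setorder(tab, p, term_id)
  setcolorder(tab, c("term_id", "foreign_count", "background_count"))
  setDF(tab)
  tab
}

#' Enzyme over-representation among enriched GO terms
#'
#' Tests whether GO terms enriched in foreign genes are more likely to
#' describe enzymatic activities than un-enriched terms, with a Pearson
#' chi-squared test on the 2x2 (enriched x enzyme) table. Horizontally
#' acquired genes are expected to be operational - typically enzymes - so
#' the enriched-term enzyme percentage should exceed the un-enriched one.
#'
#' @param enrichment Table from [go_enrichment()].
#' @param correct Yates' continuity correction. Default `FALSE`.
#' @param alpha Significance threshold. Default 0.05.
#' @return Object of class `hgt_contingency` with additional fields
#'   `pct_enzyme_enriched` and `pct_enzyme_unenriched` (percentages), or a
#'   list with `status = "insufficient_terms"` when no term is enriched (or
#'   none un-enriched).
#' @export
enzyme_over_representation <- function(enrichment, correct = FALSE,
                                       alpha = 0.05) {
  enr <- enrichment$enriched
  enz <- enrichment$enzyme
  if (!sum(enr) || !sum(!enr))
    return(structure(list(status = "insufficient_terms",
                          n_enriched = sum(enr),
                          n_unenriched = sum(!enr)),
                     class = "hgt_enzyme_test"))
  tab <- matrix(c(sum(enr & enz), sum(enr & !enz),
                  sum(!enr & enz), sum(!enr & !enz)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("enriched", "unenriched"),
                                c("enzyme", "non_enzyme")))
  out <- contingency_chisq(tab, correct = correct, alpha = alpha)
  out$pct_enzyme_enriched <- 100 * tab[1L, 1L] / sum(tab[1L, ])
  out$pct_enzyme_unenriched <- 100 * tab[2L, 1L] / sum(tab[2L, ])
  out$status <- "ok"
  out
}

#' Native genes with the HGT-mimicking loss pattern
#'
#' The gene-loss alternative hypothesis: an apparently foreign gene could be
#' ancestral but lost in every other metazoan lineage. For a transfer at the
#' base of the focal phylum to be mimicked by loss, at least one loss is
#' required at each branchpoint between the metazoan root and the phylum
#' (six in the reference species tree). This function finds the native genes
#' with exactly that pattern: no match with bitscore >= `threshold` to any
#' species of any branchpoint. These genes form the control set whose GO
#' profile is contrasted with the foreign genes'.
#'
#' @param native_genes Character vector of native gene ids.
#' @param bitscores Numeric matrix of best bitscores, genes x species
#'   (rownames gene ids, colnames species ids); absent scores may be 0 or
#'   missing rows/columns.
#' @param branchpoints Named list of character vectors: the species sets at
#'   each branchpoint, ordered from the metazoan root toward the focal
#'   phylum.
#' @param threshold Bitscore above which a gene counts as present.
#'   Default 100.
#' @return List of class `hgt_loss_pattern`: `members` (gene ids lost at
#'   every branchpoint) and `loss_flags` (logical genes x branchpoints
#'   matrix).
#' @export
loss_pattern_native_set <- function(native_genes, bitscores, branchpoints,
                                    threshold = 100) {
  if (!length(branchpoints)) stop("branchpoints must be a non-empty list")
  if (is.null(names(branchpoints)))
    names(branchpoints) <- paste0("bp", seq_along(branchpoints))
  flags <- matrix(FALSE, nrow = length(native_genes),
                  ncol = length(branchpoints),
                  dimnames = list(native_genes, names(branchpoints)))
  for (j in seq_along(branchpoints)) {
    sp <- intersect(branchpoints[[j]], colnames(bitscores))
    if (!length(sp)) {
      flags[, j] <- TRUE  # no scored species: nothing contradicts a loss
      next
    }
    m <- match(native_genes, rownames(bitscores))
    best <- rep(0, length(native_genes))
    got <- !is.na(m)
    sub <- bitscores[m[got], sp, drop = FALSE]
    best[got] <- apply(sub, 1L, max)
    flags[, j] <- best < threshold
  }
  structure(list(members = native_genes[rowSums(flags) == ncol(flags)],
                 loss_flags = flags),
            class = "hgt_loss_pattern")
}
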