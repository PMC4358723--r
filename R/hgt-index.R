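#' Reduce hits to per-transcript best bitscores
#'
#' For every transcript, takes the maximum bitscore over (i) metazoan hits,
#' excluding the focal species' own phylum, (ii) each non-metazoan cellular
#' kingdom, and (iii) viral hits, kept separate because the direction of a
#' virus-animal transfer is ambiguous. The best non-metazoan bitscore is the
#' maximum over the five cellular kingdoms and the donor is the kingdom
#' achieving it (ties broken by the fixed order of [donor_kingdoms()]).
#' Absence of a hit is encoded as bitscore 0 with an `NA` subject.
#'
#' @param hits Hit table from [read_hits()] (columns `query_id`,
#'   `subject_id`, `taxon`, `bitscore`).
#' @param exclude_own_phylum If `TRUE` (default), hits labelled `own_phylum`
#'   are excluded from the metazoan best. Setting `FALSE` folds them into
#'   metazoa, which restricts detection to transfers younger than the phylum.
#' @return `data.frame`, one row per transcript: `transcript_id`, `best_met`,
#'   `best_met_subject`, `best_nonmet`, `best_nonmet_subject`, `donor`,
#'   `best_viral`, one `best_<kingdom>` column per donor kingdom, and
#'   `overall_best` (maximum over both databases, used for gene-level
#'   transcript inheritance).
#' @export
reduce_best_hits <- function(hits, exclude_own_phylum = TRUE) {
  dt <- as.data.table(hits)
  need <- c("query_id", "subject_id", "taxon", "bitscore")
  if (!all(need %in% names(dt)))
    stop("hits must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(dt$taxon), taxon_groups())
  if (length(bad))
    stop("unknown taxon labels: ", paste(bad, collapse = ", "))

  transcripts <- sort(unique(dt$query_id))
  met_taxa <- if (exclude_own_phylum) "metazoa" else c("metazoa", "own_phylum")

  ## best (bitscore, lexicographically smallest subject) per query x subset
  best_of <- function(sub) {
    if (!nrow(sub))
      return(data.table(query_id = character(), bitscore = numeric(),
                        subject_id = character()))
    setorder(sub, query_id, -bitscore, subject_id)
    sub[, .SD[1L], by = query_id][, .(query_id, bitscore, subject_id)]
  }
  pick <- function(taxa) best_of(dt[taxon %in% taxa,
                                    .(query_id, bitscore, subject_id)])

  out <- data.table(transcript_id = transcripts)
  met <- pick(met_taxa)
  out[, best_met := 0][, best_met_subject := NA_character_]
  m <- match(out$transcript_id, met$query_id)
  out$best_met[!is.na(m)] <- met$bitscore[m[!is.na(m)]]
  out$best_met_subject[!is.na(m)] <- met$subject_id[m[!is.na(m)]]

  for (k in donor_kingdoms()) {
    bk <- pick(k)
    col <- paste0("best_", k)
    out[, (col) := 0]
    m <- match(out$transcript_id, bk$query_id)
    set(out, which(!is.na(m)), col, bk$bitscore[m[!is.na(m)]])
  }
  vir <- pick("viruses")
  out[, best_viral := 0]
  m <- match(out$transcript_id, vir$query_id)
  out$best_viral[!is.na(m)] <- vir$bitscore[m[!is.na(m)]]

  kcols <- paste0("best_", donor_kingdoms())
  kmat <- as.matrix(out[, ..kcols])
  out[, best_nonmet := do.call(pmax, c(as.list(as.data.frame(kmat)), list(0)))]
  ## donor: first kingdom (in tie-break order) achieving the max
  donor_idx <- apply(kmat, 1L, function(r)
    if (max(r) <= 0) NA_integer_ else which(r == max(r))[1L])
  out[, donor := ifelse(is.na(donor_idx), NA_character_,
                        donor_kingdoms()[donor_idx])]
  ## subject of the best non-metazoan (cellular) hit
  nm <- best_of(dt[taxon %in% donor_kingdoms(),
                   .(query_id, bitscore, subject_id)])
  out[, best_nonmet_subject := NA_character_]
  m <- match(out$transcript_id, nm$query_id)
  out$best_nonmet_subject[!is.na(m)] <- nm$subject_id[m[!is.na(m)]]

  out[, overall_best := pmax(best_met, best_nonmet, best_viral)]
  setDF(out)
  out
}

#' HGT index h
#'
#' `h` is the bitscore of the best non-metazoan (cellular) match minus the
#' bitscore of the best metazoan match. Positive values indicate a gene more
#' similar to non-metazoan than to metazoan proteins, the signature of
#' horizontal acquisition. A missing metazoan match contributes 0 (absence
#' must fall below every threshold); a missing non-metazoan match leaves `h`
#' undefined (`NA`) and the gene native by fiat.
#'
#' @param best_nonmet Best non-metazoan bitscore(s), or a data frame from
#'   [reduce_best_hits()] (columns `best_nonmet`, `best_met`).
#' @param best_met Best metazoan bitscore(s); ignored when `best_nonmet` is a
#'   data frame.
#' @return Numeric vector of HGT indices (`NA` where no non-metazoan hit).
#' @export
#' @examples
#' compute_h(135, 39.3)  # 95.7, the gob-1 worked example
#' compute_h(150, 0)     # no metazoan hit counts as 0
compute_h <- function(best_nonmet, best_met = NULL) {
  if (is.data.frame(best_nonmet)) {
    best_met <- best_nonmet$best_met
    best_nonmet <- best_nonmet$best_nonmet
  }
  met <- pmax(ifelse(is.na(best_met), 0, best_met), 0)
  ifelse(is.na(best_nonmet) | best_nonmet <= 0, NA_real_, best_nonmet - met)
}

#' Gene-level scores by transcript inheritance
#'
#' Each gene inherits its best scores (and hence `h`) from the transcript
#' whose single highest bitscore over both databases is maximal; ties are
#' broken by lexicographic transcript id for reproducibility.
#'
#' @param best Per-transcript table from [reduce_best_hits()].
#' @param tx2gene Data frame mapping `transcript_id` to `gene_id`.
#' @return `data.frame`, one row per gene: `gene_id`, `source_transcript`,
#'   the inherited best-score columns, `donor` and `h`.
#' @export
gene_scores <- function(best, tx2gene) {
  b <- as.data.table(best)
  map <- as.data.table(tx2gene)[, .(transcript_id, gene_id)]
  missing <- setdiff(b$transcript_id, map$transcript_id)
  if (length(missing))
    stop("transcripts with no gene mapping: ",
         paste(head(missing, 5L), collapse = ", "))
  b <- merge(b, map, by = "transcript_id")
  setorder(b, gene_id, -overall_best, transcript_id)
  g <- b[, .SD[1L], by = gene_id]
  setnames(g, "transcript_id", "source_transcript")
  g[, h := compute_h(best_nonmet, best_met)]
  setcolorder(g, c("gene_id", "source_transcript"))
  setorder(g, gene_id)
  setDF(g)
  g
}

#' Candidate (class C) foreign-gene test
#'
#' A gene is class C when `h >= h_min`, its best non-metazoan bitscore is at
#' least `nonmet_bitscore_min`, and it is not flagged as viral class V.
#'
#' @param scores Gene score table from [gene_scores()].
#' @param thresholds An [hgt_thresholds()] object.
#' @param viral Logical vector of class-V flags; computed by [flag_viral()]
#'   when not supplied.
#' @return Logical vector, one element per gene.
#' @export
classify_class_c <- function(scores, thresholds = hgt_thresholds(),
                             viral = NULL) {
  t <- as_thresholds(thresholds)
  if (is.null(viral)) viral <- flag_viral(scores, t)
  h <- scores$h
  !is.na(h) & h >= t$h_min & scores$best_nonmet >= t$nonmet_bitscore_min &
    !viral
}

#' Donor kingdom of a foreign gene
#'
#' The likely taxon of origin is the kingdom of the best-matching
#' non-metazoan protein, as computed in [reduce_best_hits()]; ties are broken
#' by the fixed order of [donor_kingdoms()].
#'
#' @param scores Gene score (or per-transcript best) table carrying a `donor`
#'   column.
#' @return Character vector of donor kingdoms (`NA` where no non-metazoan
#'   hit).
#' @export
assign_donor_taxon <- function(scores) {
  scores$donor
}

#' Viral class V flag
#'
#' Candidate foreign genes whose signal is viral: the gene would pass the
#' class C gates if its best viral bitscore were counted as the non-metazoan
#' best, while its best cellular (non-viral non-metazoan) hit fails those
#' gates. Such genes are excluded from classes C/B/A and reported separately,
#' because the direction of a virus-animal transfer cannot be resolved.
#'
#' @inheritParams classify_class_c
#' @return Logical vector, one element per gene. Class V and class C are
#'   disjoint by construction.
#' @export
flag_viral <- function(scores, thresholds = hgt_thresholds()) {
  t <- as_thresholds(thresholds)
  met <- pmax(ifelse(is.na(scores$best_met), 0, scores$best_met), 0)
  viral_c <- scores$best_viral > 0 &
    (scores$best_viral - met) >= t$h_min &
    scores$best_viral >= t$nonmet_bitscore_min
  h <- compute_h(scores$best_nonmet, scores$best_met)
  cellular_c <- !is.na(h) & h >= t$h_min &
    scores$best_nonmet >= t$nonmet_bitscore_min
  viral_c & !cellular_c
}
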