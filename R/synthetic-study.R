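#' Parameters for a synthetic HGT study
#'
#' Defines the statistical structure of a generated multi-species study.
#' Genes are planted in one of five categories: `native` (vertically
#' inherited), `ancient_HGT` (one founding event on an internal species-tree
#' branch, present as orthologs in every descendant species), `recent_HGT`
#' (one species only), `contaminant` (foreign-scored sequence on a
#' foreign-only scaffold, intronless) and `viral_artifact` (viral-only
#' signal). Bitscores are simulated directly - the pipeline consumes scores,
#' so simulating at the score level is the minimal faithful model; no
#' sequence evolution is involved.
#'
#' Native genes draw best-metazoan bitscores around `mu_met_native` and (when
#' they have a non-metazoan hit at all) best non-metazoan bitscores around
#' `mu_nonmet_native` < `mu_met_native`, giving strongly negative `h`.
#' Foreign genes reverse the pattern: best-metazoan around `mu_met_foreign`
#' and best non-metazoan around `mu_met_foreign + delta`, so `delta` is the
#' planted HGT signal in bitscore units.
#'
#' @param n_species Number of species (pectinate species tree). Default 4,
#'   a Caenorhabditis-like clade; 12 gives a Drosophila-like one.
#' @param genes_per_species Genes simulated per species. Default 500.
#' @param fraction_ancient,fraction_recent,fraction_contaminant,fraction_viral
#'   Fractions of gene slots planted in each foreign category (defaults
#'   0.02, 0.02, 0.01, 0; fractions must sum to at most 1).
#' @param delta Planted HGT signal (mean of best non-metazoan minus best
#'   metazoan bitscore for foreign genes). Default 60.
#' @param sigma Bitscore noise standard deviation. Default 5.
#' @param mu_met_native,mu_nonmet_native,mu_met_foreign Bitscore means (see
#'   above). Defaults 200, 110, 60.
#' @param p_nonmet_native Probability a native gene has any non-metazoan
#'   hit. Default 0.7.
#' @param p_intron_native Probability a native (or ancient foreign,
#'   domesticated) gene has introns. Default 0.95.
#' @param p_intron_recent_bacterial Intron probability for recently
#'   transferred bacterial genes, which have had little time to gain
#'   introns. Default 0.3.
#' @param p_enzyme_native,p_enzyme_foreign Probability that a drawn GO term
#'   is enzymatic, for native and foreign genes. Defaults 0.25, 0.6.
#' @param n_go_terms Size of the GO term pool. Default 60.
#' @param genes_per_scaffold Genes per (non-contaminant) scaffold.
#'   Default 20.
#' @param donor_weights Named sampling weights over [donor_kingdoms()] for
#'   planted donors (bacteria and protists dominate).
#' @param tree_noise Probability that a planted foreign gene's tree is drawn
#'   with a topology that fails validation (emulates imperfect real trees).
#'   Default 0.
#' @param seed RNG seed; identical seeds give byte-identical studies.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_species = 4L,
                       genes_per_species = 500L,
                       fraction_ancient = 0.02,
                       fraction_recent = 0.02,
                       fraction_contaminant = 0.01,
                       fraction_viral = 0,
                       delta = 60,
                       sigma = 5,
                       mu_met_native = 200,
                       mu_nonmet_native = 110,
                       mu_met_foreign = 60,
                       p_nonmet_native = 0.7,
                       p_intron_native = 0.95,
                       p_intron_recent_bacterial = 0.3,
                       p_enzyme_native = 0.25,
                       p_enzyme_foreign = 0.6,
                       n_go_terms = 60L,
                       genes_per_scaffold = 20L,
                       donor_weights = c(bacteria = 0.55, protists = 0.2,
                                         fungi = 0.12, plants = 0.08,
                                         archaea = 0.05),
                       tree_noise = 0,
                       seed = 1L) {
  p <- as.list(environment())
  fr <- fraction_ancient + fraction_recent + fraction_contaminant +
    fraction_viral
  if (fr > 1) stop("foreign fractions must sum to at most 1")
  if (any(c(fraction_ancient, fraction_recent, fraction_contaminant,
            fraction_viral) < 0)) stop("fractions must be non-negative")
  if (delta <= 0) stop("delta must be positive")
  if (sigma <= 0) stop("sigma must be positive")
  probs <- c(p_nonmet_native, p_intron_native, p_intron_recent_bacterial,
             p_enzyme_native, p_enzyme_foreign, tree_noise)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (n_species < 2L) stop("need at least 2 species")
  if (!setequal(names(donor_weights), donor_kingdoms()) &&
      !all(names(donor_weights) %in% donor_kingdoms()))
    stop("donor_weights names must be donor kingdoms")
  structure(p, class = "sim_params")
}

## Pectinate rooted species tree with labelled internal nodes
## (anc02 = ancestor of the first two species, ..., root).
pectinate_tree <- function(species) {
  n <- length(species)
  core <- sprintf("(%s:1,%s:1)", species[1L], species[2L])
  if (n > 2L) {
    for (i in 3:n)
      core <- sprintf("(%sanc%02d:1,%s:1)", core, i - 1L, species[i])
  }
  paste0(core, "root;")
}

## species below each internal branch of the pectinate tree
pectinate_descendants <- function(species) {
  n <- length(species)
  if (n == 2L) return(list(root = species))
  d <- lapply(2:(n - 1L), function(k) species[seq_len(k)])
  names(d) <- sprintf("anc%02d", 2:(n - 1L))
  c(d, list(root = species))
}

#' Generate a synthetic multi-species HGT study
#'
#' Produces a fully consistent study - hit tables, taxon map, within-taxon
#' pairwise similarity table, gene models, GO tables, gene trees, species
#' tree - together with planted truth labels for every gene. Identical seeds
#' give identical studies; writing to `dir` is byte-deterministic.
#'
#' @param params A [sim_params()] object.
#' @param dir Optional directory: the study is also written in the standard
#'   on-disk formats ([write_study()]).
#' @return Object of class `hgt_study`: list with `params`, `species`,
#'   `species_tree` (Newick string), `hits`, `taxon_map`, `tx2gene`,
#'   `pairwise`, `gene_models`, `go_gene`, `go_terms`, `gene_trees` (named
#'   Newick strings) and `truth`.
#' @export
generate_study <- function(params = sim_params(), dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)

  species <- sprintf("sp%02d", seq_len(p$n_species))
  stree <- pectinate_tree(species)
  desc <- pectinate_descendants(species)
  internal <- names(desc)

  G <- p$genes_per_species
  cat_slot <- sample(
    c("ancient", "recent", "contaminant", "viral", "native"), G,
    replace = TRUE,
    prob = c(p$fraction_ancient, p$fraction_recent, p$fraction_contaminant,
             p$fraction_viral,
             1 - p$fraction_ancient - p$fraction_recent -
               p$fraction_contaminant - p$fraction_viral))
  branch_slot <- rep(NA_character_, G)
  branch_slot[cat_slot == "ancient"] <-
    sample(internal, sum(cat_slot == "ancient"), replace = TRUE)
  special_slot <- rep(NA_character_, G)
  spec_idx <- cat_slot %in% c("recent", "contaminant", "viral")
  special_slot[spec_idx] <- sample(species, sum(spec_idx), replace = TRUE)
  dw <- p$donor_weights[intersect(donor_kingdoms(), names(p$donor_weights))]
  donor_slot <- sample(names(dw), G, replace = TRUE, prob = dw)

  genes <- CJ(slot = seq_len(G), species = species)
  genes[, category := "native"]
  sl <- genes$slot
  is_anc <- cat_slot[sl] == "ancient" &
    mapply(function(b, s) s %in% desc[[b]], branch_slot[sl], genes$species)
  genes[is_anc, category := "ancient_HGT"]
  genes[cat_slot[sl] == "recent" & species == special_slot[sl],
        category := "recent_HGT"]
  genes[cat_slot[sl] == "contaminant" & species == special_slot[sl],
        category := "contaminant"]
  genes[cat_slot[sl] == "viral" & species == special_slot[sl],
        category := "viral_artifact"]
  genes[, gene_id := sprintf("%s_g%04d", species, slot)]
  genes[, family_id := sprintf("f%05d%s", slot,
                               ifelse(category == "native", "n", "x"))]
  genes[, donor := ifelse(category %in%
                            c("ancient_HGT", "recent_HGT"),
                          donor_slot[slot],
                          ifelse(category == "contaminant", "bacteria",
                                 NA_character_))]
  genes[, event_branch := NA_character_]
  genes[category == "ancient_HGT", event_branch := branch_slot[slot]]
  genes[category == "recent_HGT", event_branch := species]
  setorder(genes, species, slot)

  n_genes <- nrow(genes)
  lab <- genes$category
  foreign_scored <- lab %in% c("ancient_HGT", "recent_HGT")

  best_met <- numeric(n_genes)
  best_nonmet <- numeric(n_genes)
  best_viral <- numeric(n_genes)
  nat <- lab == "native"
  best_met[nat] <- rnorm(sum(nat), p$mu_met_native, p$sigma)
  has_nm <- nat & runif(n_genes) < p$p_nonmet_native
  best_nonmet[has_nm] <- rnorm(sum(has_nm), p$mu_nonmet_native, p$sigma)
  best_met[foreign_scored] <- rnorm(sum(foreign_scored), p$mu_met_foreign,
                                    p$sigma)
  best_nonmet[foreign_scored] <- rnorm(sum(foreign_scored),
                                       p$mu_met_foreign + p$delta, p$sigma)
  con <- lab == "contaminant"
  best_nonmet[con] <- rnorm(sum(con), p$mu_met_foreign + p$delta + 30,
                            p$sigma)
  vir <- lab == "viral_artifact"
  best_met[vir] <- rnorm(sum(vir), p$mu_met_foreign, p$sigma)
  best_viral[vir] <- rnorm(sum(vir), p$mu_met_foreign + p$delta, p$sigma)
  clamp <- function(x) round(pmax(x, 25), 1)
  best_met[best_met > 0] <- clamp(best_met[best_met > 0])
  best_nonmet[best_nonmet > 0] <- clamp(best_nonmet[best_nonmet > 0])
  best_viral[best_viral > 0] <- clamp(best_viral[best_viral > 0])

  nonmet_kingdom <- rep(NA_character_, n_genes)
  nonmet_kingdom[!is.na(genes$donor)] <- genes$donor[!is.na(genes$donor)]
  nonmet_kingdom[has_nm] <- sample(names(dw), sum(has_nm), replace = TRUE,
                                   prob = dw)

  ## ---- hits -------------------------------------------------------------
  n_tx <- 1L + rbinom(n_genes, 1L, 0.1)
  ev_of <- function(bs) signif(10 ^ (-pmin(bs, 500) / 3), 3)
  hit_parts <- list()
  add_hits <- function(sel, subject, taxon, bitscore) {
    if (!any(sel)) return(invisible(NULL))
    hit_parts[[length(hit_parts) + 1L]] <<- data.table(
      gene_row = which(sel), subject = subject[sel], taxon = taxon[sel],
      bitscore = bitscore[sel])
    invisible(NULL)
  }
  gid <- genes$gene_id
  add_hits(best_met > 0, paste0("met_", gid), rep("metazoa", n_genes),
           best_met)
  extra_met <- best_met > 0 & runif(n_genes) < 0.3
  add_hits(extra_met, paste0("met2_", gid), rep("metazoa", n_genes),
           clamp(best_met - runif(n_genes, 10, 40)))
  own <- nat & runif(n_genes) < 0.3
  add_hits(own, paste0("own_", gid), rep("own_phylum", n_genes),
           clamp(best_met + runif(n_genes, 5, 30)))
  add_hits(best_nonmet > 0, paste0(substr(nonmet_kingdom, 1L, 3L), "_", gid),
           nonmet_kingdom, best_nonmet)
  sec <- foreign_scored & runif(n_genes) < 0.3
  other_k <- vapply(nonmet_kingdom, function(k)
    if (is.na(k)) NA_character_
    else sample(setdiff(names(dw), k), 1L), character(1))
  add_hits(sec, paste0(substr(other_k, 1L, 3L), "2_", gid), other_k,
           clamp(best_nonmet - 40 - runif(n_genes, 0, 20)))
  hsp <- best_nonmet > 0 & runif(n_genes) < 0.15
  add_hits(hsp, paste0(substr(nonmet_kingdom, 1L, 3L), "_", gid),
           nonmet_kingdom, clamp(best_nonmet - 15))
  add_hits(best_viral > 0, paste0("vir_", gid), rep("viruses", n_genes),
           best_viral)
  hits1 <- rbindlist(hit_parts)
  hits1[, query_id := paste0("t1_", gid[gene_row])]
  two_tx <- which(n_tx == 2L)
  hits2 <- hits1[gene_row %in% two_tx]
  hits2[, query_id := paste0("t2_", gid[gene_row])]
  hits2[, bitscore := clamp(bitscore - 20)]
  hits <- rbind(hits1, hits2)
  hits[, evalue := ev_of(bitscore)]
  hits[, gene_row := NULL]
  setnames(hits, "subject", "subject_id")
  setcolorder(hits, c("query_id", "subject_id", "taxon", "bitscore",
                      "evalue"))
  setorder(hits, query_id, subject_id, -bitscore)
  taxon_map <- hits[, .(taxon = taxon[1L]), by = subject_id]
  taxon_map_v <- setNames(taxon_map$taxon, taxon_map$subject_id)

  tx2gene <- rbind(
    data.table(transcript_id = paste0("t1_", gid), gene_id = gid,
               species = genes$species),
    data.table(transcript_id = paste0("t2_", gid[two_tx]),
               gene_id = gid[two_tx], species = genes$species[two_tx]))
  setorder(tx2gene, gene_id, transcript_id)

  ## ---- pairwise similarity (within-taxon all-vs-all) --------------------
  fam <- split(gid, genes$family_id)
  fam <- fam[lengths(fam) >= 2L]
  pair_list <- lapply(fam, function(m) {
    idx <- CJ(a = m, b = m)[a != b]
    idx
  })
  pairs <- rbindlist(pair_list)
  pairs[, evalue := signif(10 ^ (-runif(.N, 50, 120)), 3)]
  pairs[, bitscore := round(runif(.N, 200, 400), 1)]
  n_noise <- max(1L, round(0.01 * n_genes))
  noise <- data.table(a = sample(gid, n_noise, replace = TRUE),
                      b = sample(gid, n_noise, replace = TRUE))
  noise <- noise[a != b]
  noise[, evalue := signif(10 ^ (-runif(.N, 1, 4.5)), 3)]
  noise[, bitscore := round(runif(.N, 30, 50), 1)]
  pairwise <- rbind(pairs, noise)
  setnames(pairwise, c("a", "b"), c("query_id", "subject_id"))
  setorder(pairwise, query_id, subject_id, evalue)

  ## ---- gene models ------------------------------------------------------
  genes[, is_contaminant := category == "contaminant"]
  genes[, pos := seq_len(.N), by = .(species, is_contaminant)]
  genes[, scaffold := ifelse(
    is_contaminant,
    sprintf("%s_ctg%03d", species, pos),
    sprintf("%s_scf%03d", species,
            ceiling(pos / p$genes_per_scaffold)))]
  genes[, slot_on_scf := seq_len(.N), by = scaffold]
  genes[, start := 1L + (slot_on_scf - 1L) * 1500L]
  genes[, end := start + 1199L]
  genes[, strand := ifelse(slot_on_scf %% 2L == 1L, "+", "-")]

  p_intron <- ifelse(lab == "contaminant", 0,
              ifelse(lab == "recent_HGT" & genes$donor == "bacteria" &
                       !is.na(genes$donor),
                     p$p_intron_recent_bacterial, p$p_intron_native))
  has_intron <- runif(n_genes) < p_intron
  exon_count <- ifelse(has_intron, 2L + sample(0:3, n_genes, TRUE), 1L)

  gm <- genes[, .(gene_id, species, scaffold, start, end, strand)]
  gm[, exon_count := exon_count]
  gene_models <- merge(tx2gene, gm, by = c("gene_id", "species"))
  setcolorder(gene_models, c("gene_id", "transcript_id", "species",
                             "scaffold", "start", "end", "strand",
                             "exon_count"))
  setorder(gene_models, gene_id, transcript_id)

  ## ---- GO annotation ----------------------------------------------------
  ## term pool: about a quarter of GO terms describe enzyme activities (the
  ## share observed among un-enriched terms in real annotation sets); foreign
  ## genes concentrate on a small enzyme-biased marker set
  terms <- sprintf("GO:%07d", seq_len(p$n_go_terms))
  n_enz <- max(1L, round(0.26 * p$n_go_terms))
  enzyme <- c(rep(TRUE, n_enz), rep(FALSE, p$n_go_terms - n_enz))
  enz_terms <- terms[enzyme]
  non_terms <- terms[!enzyme]
  marker_enz <- enz_terms[seq_len(min(10L, length(enz_terms)))]
  marker_non <- non_terms[seq_len(min(4L, length(non_terms)))]

  n_terms_per_gene <- sample(1:3, n_genes, TRUE)
  draw_gene <- rep(seq_len(n_genes), n_terms_per_gene)
  nd <- length(draw_gene)
  is_foreign_draw <- lab[draw_gene] %in%
    c("ancient_HGT", "recent_HGT", "contaminant")
  use_marker <- is_foreign_draw & runif(nd) < 0.7
  p_enz_draw <- ifelse(is_foreign_draw, p$p_enzyme_foreign,
                       p$p_enzyme_native)
  pick_enz <- runif(nd) < p_enz_draw
  term_drawn <- character(nd)
  i1 <- use_marker & pick_enz
  term_drawn[i1] <- sample(marker_enz, sum(i1), TRUE)
  i2 <- use_marker & !pick_enz
  term_drawn[i2] <- sample(marker_non, sum(i2), TRUE)
  i3 <- !use_marker & pick_enz
  term_drawn[i3] <- sample(enz_terms, sum(i3), TRUE)
  i4 <- !use_marker & !pick_enz
  term_drawn[i4] <- sample(non_terms, sum(i4), TRUE)
  go_gene <- unique(data.table(gene_id = gid[draw_gene],
                               term_id = term_drawn))
  setorder(go_gene, gene_id, term_id)
  go_terms <- data.table(term_id = terms, enzyme = enzyme)

  ## ---- gene trees for planted foreign genes -----------------------------
  tree_rows <- which(foreign_scored)
  noisy <- runif(n_genes) < p$tree_noise
  gene_trees <- character(0)
  if (length(tree_rows)) {
    k <- genes$donor[tree_rows]
    focal <- paste0(gid[tree_rows], "|focal")
    good <- sprintf(
      "((%s:1,(d1|%s:1,d2|%s:1):1):1,((m1|metazoa:1,m2|metazoa:1):1,o1|own_phylum:1):1);",
      focal, k, k)
    bad <- sprintf(
      "((%s:1,m1|metazoa:1):1,(d1|%s:1,d2|%s:1):1,(m2|metazoa:1,o1|own_phylum:1):1);",
      focal, k, k)
    gene_trees <- setNames(ifelse(noisy[tree_rows], bad, good),
                           gid[tree_rows])
    gene_trees <- gene_trees[order(names(gene_trees))]
  }

  truth <- genes[, .(gene_id, species, category, donor, family_id,
                     event_branch)]
  setorder(truth, gene_id)

  study <- structure(list(
    params = p,
    species = species,
    species_tree = stree,
    hits = setDF(hits),
    taxon_map = taxon_map_v,
    tx2gene = setDF(tx2gene[, .(transcript_id, gene_id, species)]),
    pairwise = setDF(pairwise),
    gene_models = setDF(gene_models),
    go_gene = setDF(go_gene),
    go_terms = setDF(go_terms),
    gene_trees = gene_trees,
    truth = setDF(truth)
  ), class = "hgt_study")
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' @export
print.hgt_study <- function(x, ...) {
  cat(sprintf(
    "synthetic HGT study: %d species, %d genes (%d planted foreign), seed %d\n",
    length(x$species), nrow(x$truth),
    sum(x$truth$category != "native"), x$params$seed))
  print(table(x$truth$category))
  invisible(x)
}

#' Planted truth labels of a synthetic study
#'
#' @param study An `hgt_study` from [generate_study()].
#' @return `data.frame`: `gene_id`, `species`, `category`, `donor`,
#'   `family_id`, `event_branch`.
#' @export
truth_labels <- function(study) {
  stopifnot(inherits(study, "hgt_study"))
  study$truth
}

#' Write a synthetic study to disk in the standard formats
#'
#' Emits exactly the formats the readers consume: `hits.tsv` and
#' `pairwise.tsv` (12-column outfmt-6), `taxon_map.tsv`, `genes.gff3`,
#' `species_tree.nwk`, `trees/<gene>.nwk`, `gene2go.tsv`, `go_terms.tsv`,
#' `tx2gene.tsv` and `truth.tsv`. Output is byte-deterministic for a given
#' study.
#'
#' @param study An `hgt_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "trees"), showWarnings = FALSE)
  writeLines(study$species_tree, file.path(dir, "species_tree.nwk"))

  fmt_outfmt6 <- function(q, s, ev, bs) {
    data.table(qseqid = q, sseqid = s, pident = "90.0", length = "200",
               mismatch = "20", gapopen = "1", qstart = "1", qend = "600",
               sstart = "1", send = "200",
               evalue = formatC(ev, format = "e", digits = 2),
               bitscore = sprintf("%.1f", bs))
  }
  fwrite(fmt_outfmt6(study$hits$query_id, study$hits$subject_id,
                     study$hits$evalue, study$hits$bitscore),
         file.path(dir, "hits.tsv"), sep = "\t", col.names = FALSE)
  tm <- data.table(subject_id = names(study$taxon_map),
                   taxon = unname(study$taxon_map))
  setorder(tm, subject_id)
  fwrite(tm, file.path(dir, "taxon_map.tsv"), sep = "\t",
         col.names = FALSE)
  fwrite(fmt_outfmt6(study$pairwise$query_id, study$pairwise$subject_id,
                     study$pairwise$evalue, study$pairwise$bitscore),
         file.path(dir, "pairwise.tsv"), sep = "\t", col.names = FALSE)

  ## GFF3: gene -> mRNA -> exons; exon spans tile the gene span
  gm <- as.data.table(study$gene_models)
  lines <- c("##gff-version 3")
  genes <- gm[, .SD[1L], by = gene_id]
  setorder(genes, scaffold, start, gene_id)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    lines <- c(lines, sprintf(
      "%s\thgtscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      g$scaffold, g$start, g$end, g$strand, g$gene_id))
    txs <- gm[gene_id == g$gene_id]
    for (j in seq_len(nrow(txs))) {
      tx <- txs[j]
      lines <- c(lines, sprintf(
        "%s\thgtscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        tx$scaffold, tx$start, tx$end, tx$strand, tx$transcript_id,
        tx$gene_id))
      ec <- tx$exon_count
      ex_start <- tx$start + (seq_len(ec) - 1L) * 220L
      ex_end <- ex_start + 99L
      ex_end[ec] <- tx$end
      lines <- c(lines, sprintf(
        "%s\thgtscan\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        tx$scaffold, ex_start, ex_end, tx$strand, tx$transcript_id,
        seq_len(ec), tx$transcript_id))
    }
  }
  writeLines(lines, file.path(dir, "genes.gff3"))

  fwrite(as.data.table(study$go_gene), file.path(dir, "gene2go.tsv"),
         sep = "\t", col.names = FALSE)
  go_t <- as.data.table(study$go_terms)
  go_t[, enzyme := ifelse(enzyme, "TRUE", "FALSE")]
  fwrite(go_t, file.path(dir, "go_terms.tsv"), sep = "\t",
         col.names = FALSE)
  for (g in names(study$gene_trees))
    writeLines(study$gene_trees[[g]],
               file.path(dir, "trees", paste0(g, ".nwk")))
  fwrite(as.data.table(study$tx2gene), file.path(dir, "tx2gene.tsv"),
         sep = "\t")
  fwrite(as.data.table(study$truth), file.path(dir, "truth.tsv"),
         sep = "\t")
  invisible(dir)
}

#' Read a synthetic study back from disk
#'
#' Re-reads a directory written by [write_study()] through the package's own
#' readers ([read_hits()], [read_gene_models()], [read_go()], ...), so a
#' write/read cycle also exercises every parser.
#'
#' @param dir Study directory.
#' @return An `hgt_study` (without `params`).
#' @export
read_study <- function(dir) {
  taxon_map <- read_taxon_map(file.path(dir, "taxon_map.tsv"))
  hits <- read_hits(file.path(dir, "hits.tsv"), taxon_map)
  pw_raw <- read_outfmt6(file.path(dir, "pairwise.tsv"))
  pairwise <- data.frame(query_id = pw_raw$qseqid,
                         subject_id = pw_raw$sseqid,
                         evalue = pw_raw$evalue, bitscore = pw_raw$bitscore)
  tx2gene <- setDF(fread(file.path(dir, "tx2gene.tsv")))
  truth <- setDF(fread(file.path(dir, "truth.tsv")))
  gene_models <- read_gene_models(file.path(dir, "genes.gff3"))
  m <- match(gene_models$gene_id, truth$gene_id)
  gene_models$species <- truth$species[m]
  go <- read_go(file.path(dir, "gene2go.tsv"),
                file.path(dir, "go_terms.tsv"))
  tree_files <- list.files(file.path(dir, "trees"), pattern = "\\.nwk$",
                           full.names = TRUE)
  gene_trees <- setNames(vapply(tree_files, function(f)
    readLines(f, n = 1L), character(1)),
    sub("\\.nwk$", "", basename(tree_files)))
  stree <- readLines(file.path(dir, "species_tree.nwk"), n = 1L)
  structure(list(
    params = NULL,
    species = sort(unique(truth$species)),
    species_tree = stree,
    hits = hits, taxon_map = taxon_map, tx2gene = tx2gene,
    pairwise = pairwise, gene_models = gene_models,
    go_gene = data.frame(
      gene_id = rep(names(go$gene_to_terms),
                    lengths(go$gene_to_terms)),
      term_id = unlist(go$gene_to_terms, use.names = FALSE)),
    go_terms = data.frame(term_id = names(go$enzyme_flag),
                          enzyme = unname(go$enzyme_flag)),
    gene_trees = gene_trees, truth = truth
  ), class = "hgt_study")
}
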