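#' @section File formats:
#' Alignment hits are 12-column BLAST `outfmt 6` tables (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore). Gene
#' models are GFF3 (1-based inclusive coordinates, kept as-is throughout).
#' Trees are Newick with tip labels of the form `id|TAXON`. GO annotation is a
#' pair of two-column TSVs.
#' @name hgtscan-formats
#' @keywords internal
NULL

OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

## Parse a 12-column outfmt-6-like TSV, reporting the first malformed line.
read_outfmt6 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(data.table(qseqid = character(), sseqid = character(),
                      evalue = numeric(), bitscore = numeric()))
  raw <- fread(path, header = FALSE, sep = "\t", colClasses = "character",
               fill = TRUE, quote = "")
  if (ncol(raw) < 12L) {
    nf <- count.fields(path, sep = "\t", quote = "")
    stop("malformed outfmt-6 row at line ", which(nf < 12L)[1L],
         " of ", path, ": expected 12 tab-separated columns")
  }
  ev <- suppressWarnings(as.numeric(raw[[11L]]))
  bs <- suppressWarnings(as.numeric(raw[[12L]]))
  bad <- which(is.na(ev) | is.na(bs) | is.na(raw[[1L]]) | is.na(raw[[2L]]) |
                 raw[[1L]] == "" | raw[[2L]] == "")
  if (length(bad))
    stop("malformed outfmt-6 row at line ", bad[1L], " of ", path)
  data.table(qseqid = raw[[1L]], sseqid = raw[[2L]], evalue = ev,
             bitscore = bs)
}

#' Read a subject-to-taxon map
#'
#' Two-column TSV (`subject_id`, `taxon`) assigning every subject protein to
#' one of [taxon_groups()].
#'
#' @param path Path to the TSV (no header).
#' @return Named character vector, subject id to taxon label.
#' @export
read_taxon_map <- function(path) {
  tab <- fread(path, header = FALSE, sep = "\t", colClasses = "character")
  if (ncol(tab) < 2L) stop("taxon map must have two columns: ", path)
  bad <- setdiff(unique(tab[[2L]]), taxon_groups())
  if (length(bad))
    stop("unknown taxon labels in ", path, ": ", paste(bad, collapse = ", "))
  setNames(tab[[2L]], tab[[1L]])
}

#' Read alignment hits with taxon labels attached
#'
#' Reads a 12-column BLAST outfmt-6-like TSV and attaches a [taxon_groups()]
#' label to every subject. All rows are kept, including repeated HSPs for the
#' same (query, subject) pair; the maximum-bitscore reduction happens later in
#' [reduce_best_hits()], so provenance is preserved.
#'
#' @param path Path to the hits TSV.
#' @param taxon_map Named character vector (subject id to taxon), a
#'   two-column data frame, or a path readable by [read_taxon_map()].
#' @param unmapped Policy for subject ids absent from `taxon_map`:
#'   `"error"` (default; silently dropping hits would bias `h`) or `"drop"`
#'   (drop with a warning).
#' @return `data.frame` with columns `query_id`, `subject_id`, `taxon`,
#'   `bitscore`, `evalue`; zero rows for an empty file.
#' @export
read_hits <- function(path, taxon_map, unmapped = c("error", "drop")) {
  unmapped <- match.arg(unmapped)
  if (is.character(taxon_map) && length(taxon_map) == 1L && is.null(names(taxon_map)))
    taxon_map <- read_taxon_map(taxon_map)
  if (is.data.frame(taxon_map))
    taxon_map <- setNames(as.character(taxon_map[[2L]]),
                          as.character(taxon_map[[1L]]))
  raw <- read_outfmt6(path)
  hits <- data.table(query_id = raw$qseqid, subject_id = raw$sseqid,
                     taxon = unname(taxon_map[raw$sseqid]),
                     bitscore = raw$bitscore, evalue = raw$evalue)
  miss <- is.na(hits$taxon)
  if (any(miss)) {
    ids <- unique(hits$subject_id[miss])
    if (unmapped == "error")
      stop("subject ids missing from taxon map: ",
           paste(head(ids, 5L), collapse = ", "),
           if (length(ids) > 5L) sprintf(" (and %d more)", length(ids) - 5L))
    warning("dropping ", sum(miss), " hits with unmapped subjects")
    hits <- hits[!miss]
  }
  if (any(hits$bitscore <= 0)) stop("bitscores must be positive: ", path)
  if (any(hits$evalue < 0)) stop("e-values must be non-negative: ", path)
  setDF(hits)
  hits
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon features linked by `ID`/`Parent` into a tidy
#' per-transcript table. Coordinates stay GFF3-native (1-based inclusive).
#' The intron count of a transcript is its exon count minus one.
#'
#' @param path Path to a GFF3 file.
#' @return `data.frame` with columns `gene_id`, `transcript_id`, `species`
#'   (NA unless encoded upstream), `scaffold`, `start`, `end`, `strand`,
#'   `exon_count` (one row per transcript).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))

  genes <- which(typ == "gene")
  tx <- which(typ %in% c("mRNA", "transcript"))
  ex <- which(typ == "exon")
  if (!length(genes)) stop("no gene features in ", path)

  tx_par <- parent[tx]
  orphan_tx <- is.na(tx_par) | !(tx_par %in% id[genes])
  if (any(orphan_tx)) {
    warning("skipping ", sum(orphan_tx), " transcripts with no parent gene")
    tx <- tx[!orphan_tx]; tx_par <- tx_par[!orphan_tx]
  }
  ex_par <- parent[ex]
  orphan_ex <- is.na(ex_par) | !(ex_par %in% id[tx])
  if (any(orphan_ex)) {
    warning("skipping ", sum(orphan_ex), " exons with no resolvable parent")
    ex <- ex[!orphan_ex]; ex_par <- ex_par[!orphan_ex]
  }
  no_tx <- setdiff(id[genes], tx_par)
  if (length(no_tx))
    stop("genes with zero transcripts: ", paste(head(no_tx, 5L), collapse = ", "))

  ex_count <- table(ex_par)
  ex_dt <- data.table(tx = ex_par,
                      start = GenomicRanges::start(gr)[ex],
                      end = GenomicRanges::end(gr)[ex])
  span <- ex_dt[, .(start = min(start), end = max(end)), by = tx]

  out <- data.table(
    gene_id = tx_par,
    transcript_id = id[tx],
    scaffold = as.character(GenomicRanges::seqnames(gr))[tx],
    start = GenomicRanges::start(gr)[tx],
    end = GenomicRanges::end(gr)[tx],
    strand = as.character(GenomicRanges::strand(gr))[tx],
    exon_count = as.integer(ex_count[id[tx]])
  )
  ## span from exons where available (transcript line may be a stub)
  m <- match(out$transcript_id, span$tx)
  got <- !is.na(m)
  out$start[got] <- pmin(out$start[got], span$start[m[got]])
  out$end[got] <- pmax(out$end[got], span$end[m[got]])
  out$exon_count[is.na(out$exon_count)] <- 0L
  if (any(out$exon_count < 1L))
    stop("transcripts with zero exons: ",
         paste(head(out$transcript_id[out$exon_count < 1L], 5L), collapse = ", "))
  setorder(out, gene_id, transcript_id)
  setDF(out)
  out
}

#' Read a taxon-labelled Newick tree
#'
#' Reads a Newick file and parses tip labels of the form `id<delim>TAXON`
#' into per-tip metadata. Topology and branch lengths are preserved by
#' [ape::read.tree()]; the returned `phylo` carries attributes `tip_info`
#' (data frame with `label`, `id`, `taxon`), `rooted` and `degenerate`
#' (fewer than 3 tips).
#'
#' @param path Path to a Newick file (or a Newick string via `text`).
#' @param delim Delimiter between id and taxon in tip labels. Default `"|"`.
#' @param text Optional Newick string instead of a file.
#' @return An [ape::read.tree()] `phylo` object with tip metadata attached.
#' @export
read_tree <- function(path, delim = "|", text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick: ", if (is.null(text)) path else text)
  info <- parse_tip_labels(tree$tip.label, delim)
  attr(tree, "tip_info") <- info
  attr(tree, "rooted") <- ape::is.rooted(tree)
  attr(tree, "degenerate") <- length(tree$tip.label) < 3L
  tree
}

parse_tip_labels <- function(labels, delim = "|") {
  parts <- strsplit(labels, delim, fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop("tip labels not parseable with delimiter '", delim, "': ",
         paste(head(labels[bad], 5L), collapse = ", "))
  taxon <- vapply(parts, function(p) p[length(p)], character(1))
  id <- vapply(parts, function(p)
    paste(p[-length(p)], collapse = delim), character(1))
  data.frame(label = labels, id = id, taxon = taxon,
             stringsAsFactors = FALSE)
}

#' Read GO annotation tables
#'
#' Reads a gene-to-term TSV (`gene_id`, `term_id`; one row per annotation)
#' and a term-to-enzyme-flag TSV (`term_id`, `enzyme` in TRUE/FALSE or 0/1).
#' Every term referenced by a gene must carry an enzyme flag.
#'
#' @param gene2term_path Path to the gene-to-term TSV (no header).
#' @param term_flag_path Path to the term-flag TSV (no header).
#' @return An object of class `go_annotation`: list with `gene_to_terms`
#'   (named list of character vectors) and `enzyme_flag` (named logical).
#' @export
read_go <- function(gene2term_path, term_flag_path) {
  g2t <- fread(gene2term_path, header = FALSE, sep = "\t",
               colClasses = "character")
  flags <- fread(term_flag_path, header = FALSE, sep = "\t",
                 colClasses = "character")
  enzyme <- setNames(as.logical(flags[[2L]]) |
                       flags[[2L]] %in% c("1", "true", "TRUE"),
                     flags[[1L]])
  go_annotation(split(g2t[[2L]], g2t[[1L]]), enzyme)
}

#' Construct a GO annotation object
#'
#' @param gene_to_terms Named list: gene id to character vector of term ids.
#' @param enzyme_flag Named logical: term id to whether the term describes an
#'   enzymatic activity.
#' @return Object of class `go_annotation`.
#' @export
go_annotation <- function(gene_to_terms, enzyme_flag) {
  used <- unique(unlist(gene_to_terms, use.names = FALSE))
  missing_flags <- setdiff(used, names(enzyme_flag))
  if (length(missing_flags))
    stop("terms with no enzyme flag: ", paste(missing_flags, collapse = ", "))
  structure(list(gene_to_terms = gene_to_terms, enzyme_flag = enzyme_flag),
            class = "go_annotation")
}

#' Write the per-gene HGT report
#'
#' One row per scored gene: bitscores, `h`, class, donor, ortholog group,
#' `h_orth`, validation outcome and linkage flag where available. Rows are
#' sorted by gene id, so re-running on the same input yields a byte-identical
#' file.
#'
#' @param scores Gene score table from [assign_hgt_classes()] (or
#'   [gene_scores()]).
#' @param path Output TSV path.
#' @param validation Optional validation table (`gene_id`, `status`, ...).
#' @param linkage Optional linkage table from [linkage_test()].
#' @return The written data frame, invisibly.
#' @export
write_gene_report <- function(scores, path, validation = NULL, linkage = NULL) {
  out <- as.data.table(scores)
  if (!is.null(validation)) {
    v <- as.data.table(validation)[, .(gene_id, validation = status)]
    out <- merge(out, v, by = "gene_id", all.x = TRUE)
  }
  if (!is.null(linkage)) {
    l <- as.data.table(linkage)[, .(gene_id, linked)]
    out <- merge(out, l, by = "gene_id", all.x = TRUE)
  }
  setorder(out, gene_id)
  fwrite(out, path, sep = "\t")
  invisible(setDF(out))
}
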