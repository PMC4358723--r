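#' Build the within-taxon protein similarity graph
#'
#' Edges connect protein/gene pairs whose all-vs-all alignment e-value passes
#' the cutoff; the weight of an edge is symmetrised as the maximum of the two
#' directions. The default weight transform is `-log10(evalue)` capped at
#' 200 (the common Markov-clustering practice; an e-value of zero saturates
#' the cap); raw bitscores are available via `weight = "bitscore"`.
#'
#' @param pairwise Data frame of within-taxon alignments with columns
#'   `query_id`, `subject_id`, `evalue` and (for bitscore weighting)
#'   `bitscore`. Self-alignments are dropped.
#' @param thresholds An [hgt_thresholds()] object
#'   (`orthograph_evalue_max` is the edge cutoff).
#' @param weight `"neglog_evalue"` (default) or `"bitscore"`.
#' @param cap Cap applied to `-log10(evalue)` weights. Default 200.
#' @param species_of Optional named character vector (node to species),
#'   stored as a vertex attribute.
#' @return An undirected weighted [igraph::graph] whose vertices are the
#'   proteins seen in `pairwise`.
#' @export
build_similarity_graph <- function(pairwise, thresholds = hgt_thresholds(),
                                   weight = c("neglog_evalue", "bitscore"),
                                   cap = 200, species_of = NULL) {
  weight <- match.arg(weight)
  t <- as_thresholds(thresholds)
  dt <- as.data.table(pairwise)
  if (!all(c("query_id", "subject_id", "evalue") %in% names(dt)))
    stop("pairwise table needs columns query_id, subject_id, evalue")
  nodes <- sort(unique(c(dt$query_id, dt$subject_id)))
  dt <- dt[evalue <= t$orthograph_evalue_max & query_id != subject_id]
  if (weight == "neglog_evalue") {
    dt[, w := pmin(-log10(pmax(evalue, 1e-300)), cap)]
    dt[evalue == 0, w := cap]
  } else {
    if (!"bitscore" %in% names(dt))
      stop("bitscore column required for weight = 'bitscore'")
    dt[, w := bitscore]
  }
  ## symmetrise: max over the two directions
  dt[, `:=`(a = pmin(query_id, subject_id), b = pmax(query_id, subject_id))]
  und <- dt[, .(w = max(w)), by = .(a, b)]
  g <- igraph::graph_from_data_frame(und[, .(a, b, weight = w)],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  if (!is.null(species_of))
    igraph::V(g)$species <- unname(species_of[igraph::V(g)$name])
  g
}

## Dense MCL on one adjacency matrix; returns integer membership.
mcl_dense <- function(A, inflation, expansion = 2L, prune = 1e-5,
                      max_iter = 200L, tol = 1e-8) {
  n <- nrow(A)
  if (n == 1L) return(structure(1L, converged = TRUE))
  ## self-loops: each node's maximum incident weight (1 for isolated nodes)
  loop <- apply(A, 1L, max)
  loop[loop <= 0] <- 1
  diag(A) <- loop
  norm_cols <- function(M) sweep(M, 2L, colSums(M), "/")
  M <- norm_cols(A)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    Mn <- M
    for (e in seq_len(expansion - 1L)) Mn <- Mn %*% M
    Mn <- norm_cols(Mn ^ inflation)
    Mn[Mn < prune] <- 0
    Mn <- norm_cols(Mn)
    delta <- max(abs(Mn - M))
    M <- Mn
    if (delta < tol) { converged <- TRUE; break }
  }
  keep <- M > 1e-9
  adj <- keep | t(keep)
  memb <- rep(NA_integer_, n)
  cl <- 0L
  for (v in seq_len(n)) {
    if (!is.na(memb[v])) next
    cl <- cl + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      if (!is.na(memb[u])) next
      memb[u] <- cl
      queue <- c(queue, which(adj[u, ] & is.na(memb)))
    }
  }
  structure(memb, converged = converged)
}

#' Markov clustering (MCL) of a similarity graph
#'
#' Clusters the similarity graph into ortholog groups by the Markov Cluster
#' algorithm: add self-loops (weight = maximum incident weight), column-
#' normalise to a stochastic matrix, then iterate expansion (matrix power),
#' inflation (entrywise power followed by column renormalisation) and pruning
#' of sub-threshold entries until the matrix change falls below `tol`.
#' Clusters are the connected components of the converged flow matrix. The
#' computation is carried out per connected component of the input graph
#' (clusters can never span components), which keeps the dense iteration
#' feasible on large sparse graphs.
#'
#' @param g Similarity graph from [build_similarity_graph()].
#' @param inflation Inflation parameter (> 1). Default 15, which yields
#'   fine-grained groups appropriate for closely related species.
#' @param expansion Expansion power. Default 2.
#' @param prune Entries below this value are removed each iteration.
#'   Default 1e-5.
#' @param max_iter Iteration cap; non-convergence returns the current
#'   clustering with attribute `converged = FALSE` and a warning.
#' @param tol Convergence tolerance on the maximum absolute matrix change.
#'   Default 1e-8.
#' @return `data.frame` with columns `gene_id`, `group_id`; every vertex is
#'   assigned to exactly one group (singletons allowed). Group ids are
#'   `OG` numbers ordered by each group's lexicographically smallest member.
#' @export
mcl_cluster <- function(g, inflation = 15, expansion = 2L, prune = 1e-5,
                        max_iter = 200L, tol = 1e-8) {
  if (igraph::vcount(g) == 0L)
    return(data.frame(gene_id = character(), group_id = character()))
  if (inflation <= 1) stop("inflation must be > 1")
  comp <- igraph::components(g)
  clusters <- list()
  all_converged <- TRUE
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    names_ci <- igraph::V(g)$name[vs]
    if (length(vs) == 1L) {
      clusters[[length(clusters) + 1L]] <- names_ci
      next
    }
    sub <- igraph::induced_subgraph(g, vs)
    A <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = FALSE)
    memb <- mcl_dense(A, inflation, expansion, prune, max_iter, tol)
    if (!attr(memb, "converged")) all_converged <- FALSE
    nm <- igraph::V(sub)$name
    for (k in sort(unique(as.integer(memb))))
      clusters[[length(clusters) + 1L]] <- nm[memb == k]
  }
  if (!all_converged)
    warning("MCL did not converge within max_iter on some components; ",
            "returning current clustering")
  clusters <- clusters[order(vapply(clusters, min, character(1)))]
  out <- data.table(
    gene_id = unlist(clusters, use.names = FALSE),
    group_id = rep(sprintf("OG%05d", seq_along(clusters)),
                   lengths(clusters))
  )
  setorder(out, group_id, gene_id)
  structure(setDF(out), converged = all_converged)
}

#' Group-average HGT index and group-level metazoan maximum
#'
#' `h_orth` is the arithmetic mean of the member genes' `h`. Members without
#' an `h` value (no non-metazoan hit) are excluded from the mean by default
#' but still contribute to `group_max_met`, the group's maximum best-metazoan
#' bitscore, which vetoes class A.
#'
#' @param membership Data frame `gene_id`, `group_id` from [mcl_cluster()].
#' @param scores Gene score table from [gene_scores()].
#' @param include_unscored If `TRUE`, members without `h` enter the mean as
#'   `NA` (propagating `NA` to `h_orth`). Default `FALSE`.
#' @return `data.frame`: `group_id`, `n_members`, `h_orth` (`NA` when no
#'   member carries `h`), `group_max_met`.
#' @export
compute_h_orth <- function(membership, scores, include_unscored = FALSE) {
  mb <- as.data.table(membership)
  sc <- as.data.table(scores)[, .(gene_id, h, best_met)]
  d <- merge(mb, sc, by = "gene_id", all.x = TRUE)
  stat <- d[, .(
    n_members = .N,
    h_orth = if (include_unscored) mean(h)
             else if (all(is.na(h))) NA_real_ else mean(h, na.rm = TRUE),
    group_max_met = max(c(best_met, 0), na.rm = TRUE)
  ), by = group_id]
  setorder(stat, group_id)
  setDF(stat)
  stat
}

#' Class B test
#'
#' A class C gene is class B when the average HGT index of its ortholog group
#' (`h_orth`) is at least `h_min`: the gene is, on average, predicted foreign
#' in every tested species it is found in.
#'
#' @param class_c Logical vector of class C calls.
#' @param h_orth Group-average `h` aligned with `class_c`.
#' @param thresholds An [hgt_thresholds()] object.
#' @return Logical vector.
#' @export
classify_class_b <- function(class_c, h_orth, thresholds = hgt_thresholds()) {
  t <- as_thresholds(thresholds)
  class_c & !is.na(h_orth) & h_orth >= t$h_min
}

#' Class A test
#'
#' A class B gene is class A when neither it nor any member of its ortholog
#' group has a metazoan match with bitscore at or above
#' `classA_met_bitscore_max`: the strictest class, with only very poor
#' metazoan alignments anywhere in the group.
#'
#' @param class_b Logical vector of class B calls.
#' @param best_met Gene best-metazoan bitscores aligned with `class_b`.
#' @param group_max_met Group maximum best-metazoan bitscores.
#' @param thresholds An [hgt_thresholds()] object.
#' @return Logical vector.
#' @export
classify_class_a <- function(class_b, best_met, group_max_met,
                             thresholds = hgt_thresholds()) {
  t <- as_thresholds(thresholds)
  met <- pmax(ifelse(is.na(best_met), 0, best_met), 0)
  gmax <- pmax(ifelse(is.na(group_max_met), 0, group_max_met), 0)
  class_b & met < t$classA_met_bitscore_max &
    gmax < t$classA_met_bitscore_max
}

#' Assign nested HGT classes to gene scores
#'
#' Joins ortholog-group statistics onto the gene score table and assigns the
#' nested classes: `native < C < B < A` (ordered factor `hgt_class`), plus
#' the disjoint viral flag `class_v`. Genes absent from the membership table
#' become singleton groups of their own.
#'
#' @param scores Gene score table from [gene_scores()].
#' @param membership Data frame `gene_id`, `group_id` from [mcl_cluster()];
#'   `NULL` treats every gene as a singleton group.
#' @param thresholds An [hgt_thresholds()] object.
#' @return `scores` augmented with `group_id`, `h_orth`, `group_max_met`,
#'   `class_v` and `hgt_class`.
#' @export
assign_hgt_classes <- function(scores, membership = NULL,
                               thresholds = hgt_thresholds()) {
  t <- as_thresholds(thresholds)
  sc <- as.data.table(scores)
  if (is.null(membership))
    membership <- data.frame(gene_id = character(), group_id = character())
  mb <- as.data.table(membership)
  loose <- setdiff(sc$gene_id, mb$gene_id)
  if (length(loose)) {
    n0 <- length(unique(mb$group_id))
    mb <- rbind(mb, data.table(
      gene_id = sort(loose),
      group_id = sprintf("SG%05d", n0 + seq_along(loose))))
  }
  stat <- as.data.table(compute_h_orth(mb, sc))
  sc <- merge(sc, mb, by = "gene_id", all.x = TRUE)
  sc <- merge(sc, stat, by = "group_id", all.x = TRUE)
  sc[, class_v := flag_viral(sc, t)]
  cC <- classify_class_c(sc, t, viral = sc$class_v)
  cB <- classify_class_b(cC, sc$h_orth, t)
  cA <- classify_class_a(cB, sc$best_met, sc$group_max_met, t)
  sc[, hgt_class := factor(
    ifelse(cA, "A", ifelse(cB, "B", ifelse(cC, "C", "native"))),
    levels = c("native", "C", "B", "A"), ordered = TRUE)]
  setcolorder(sc, c("gene_id", "group_id"))
  setorder(sc, gene_id)
  setDF(sc)
  sc
}
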