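## Independent oracles, written with naive loops so they share no code path
## with the package implementations they check.

## Brute-force dense MCL: same algorithm, coded with explicit loops.
mcl_oracle <- function(A, inflation = 15, expansion = 2, prune = 1e-5,
                       max_iter = 200, tol = 1e-8) {
  n <- nrow(A)
  for (i in seq_len(n)) {
    mx <- 0
    for (j in seq_len(n)) if (A[i, j] > mx) mx <- A[i, j]
    A[i, i] <- if (mx > 0) mx else 1
  }
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    s <- 0
    for (i in seq_len(n)) s <- s + A[i, j]
    for (i in seq_len(n)) M[i, j] <- A[i, j] / s
  }
  for (it in seq_len(max_iter)) {
    ## expansion: M2 = M %*% M (expansion power 2), by loops
    M2 <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(n)) acc <- acc + M[i, k] * M[k, j]
      M2[i, j] <- acc
    }
    for (e in seq_len(expansion - 2)) stop("oracle supports expansion 2")
    ## inflation + renormalise
    for (i in seq_len(n)) for (j in seq_len(n)) M2[i, j] <- M2[i, j] ^ inflation
    for (j in seq_len(n)) {
      s <- 0
      for (i in seq_len(n)) s <- s + M2[i, j]
      for (i in seq_len(n)) M2[i, j] <- M2[i, j] / s
    }
    ## prune + renormalise
    for (i in seq_len(n)) for (j in seq_len(n))
      if (M2[i, j] < prune) M2[i, j] <- 0
    for (j in seq_len(n)) {
      s <- 0
      for (i in seq_len(n)) s <- s + M2[i, j]
      for (i in seq_len(n)) M2[i, j] <- M2[i, j] / s
    }
    delta <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      d <- abs(M2[i, j] - M[i, j])
      if (d > delta) delta <- d
    }
    M <- M2
    if (delta < tol) break
  }
  ## clusters: connected components of the nonzero pattern (symmetrised)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (M[i, j] > 1e-9 || M[j, i] > 1e-9) adj[i, j] <- TRUE
  memb <- rep(NA_integer_, n)
  cl <- 0
  for (v in seq_len(n)) {
    if (!is.na(memb[v])) next
    cl <- cl + 1
    stack <- v
    while (length(stack)) {
      u <- stack[1]; stack <- stack[-1]
      if (!is.na(memb[u])) next
      memb[u] <- cl
      for (w in seq_len(n)) if (adj[u, w] && is.na(memb[w]))
        stack <- c(stack, w)
    }
  }
  memb
}

## canonical form of a partition given as membership over named nodes
canon_partition <- function(nodes, membership) {
  cl <- split(nodes, membership)
  cl <- lapply(cl, sort)
  unname(cl[order(vapply(cl, `[`, "", 1))])
}

## tips below a node, by recursive edge-matrix traversal (independent of
## phangorn)
oracle_desc_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, oracle_desc_tips, tree = tree))
}

## edge-enumeration monophyly test for binary trees
mono_oracle <- function(tree, tips) {
  n <- length(tree$tip.label)
  S <- sort(match(tips, tree$tip.label))
  if (length(S) == 1 || length(S) == n) return(TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    side <- sort(oracle_desc_tips(tree, tree$edge[e, 2]))
    other <- sort(setdiff(seq_len(n), side))
    if (identical(side, S) || identical(other, S)) return(TRUE)
  }
  FALSE
}

## exact upper-tail hypergeometric via factorials (valid for N <= 30)
hyper_oracle <- function(k, K, n, N) {
  ch <- function(a, b) {
    if (b < 0 || b > a) return(0)
    factorial(a) / (factorial(b) * factorial(a - b))
  }
  tot <- 0
  for (j in seq(k, min(K, n))) tot <- tot + ch(K, j) * ch(N - K, n - j)
  tot / ch(N, n)
}

## closed-form Pearson chi-squared
pearson_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

## random symmetric weighted adjacency matrix on n nodes
random_adjacency <- function(n, p_edge = 0.4) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) A[i, j] <- A[j, i] <- runif(1, 0.5, 10)
  }
  A
}

## hits table builder
make_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(query_id = r[[1]], subject_id = r[[2]], taxon = r[[3]],
               bitscore = as.numeric(r[[4]]),
               evalue = if (length(r) > 4) as.numeric(r[[5]]) else 1e-30,
               stringsAsFactors = FALSE)))
}

## gob-1 and its three homologs, reproducing the published worked example:
## best non-metazoan 135 vs best metazoan 39.3 for gob-1, homolog h values
## 102, 97.1 and 86.4, homolog best-metazoan scores 37, 38.9 and 36.6.
gob1_fixture <- function() {
  hits <- make_hits(
    list("t_gob1", "P_bact1", "bacteria", 135),
    list("t_gob1", "P_met1", "metazoa", 39.3),
    list("t_hom1", "P_bact2", "bacteria", 139),
    list("t_hom1", "P_met2", "metazoa", 37),
    list("t_hom2", "P_bact3", "bacteria", 136),
    list("t_hom2", "P_met3", "metazoa", 38.9),
    list("t_hom3", "P_bact4", "bacteria", 123.0),
    list("t_hom3", "P_met4", "metazoa", 36.6))
  tx2gene <- data.frame(
    transcript_id = c("t_gob1", "t_hom1", "t_hom2", "t_hom3"),
    gene_id = c("gob-1", "hom1", "hom2", "hom3"))
  membership <- data.frame(
    gene_id = c("gob-1", "hom1", "hom2", "hom3"),
    group_id = "OG00001")
  list(hits = hits, tx2gene = tx2gene, membership = membership)
}
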