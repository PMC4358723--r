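test_that("similarity graph applies the e-value cutoff and symmetrises weights", {
  pw <- data.frame(
    query_id = c("a", "b", "a", "c", "d", "e"),
    subject_id = c("b", "a", "c", "a", "e", "d"),
    evalue = c(1e-20, 1e-18, 1e-4, 1e-4, 1e-8, 1e-6),
    bitscore = c(200, 190, 40, 40, 90, 80))
  g <- build_similarity_graph(pw)
  expect_equal(igraph::vcount(g), 5L)
  expect_equal(igraph::ecount(g), 2L)          # a-c at 1e-4 fails the 1e-5 cutoff
  w_ab <- igraph::E(g, P = c("a", "b"))$weight
  expect_equal(w_ab, 20)                        # max(-log10) of the two directions

  ## boundary: exactly at the cutoff is kept
  pw2 <- data.frame(query_id = "x", subject_id = "y", evalue = 1e-5)
  expect_equal(igraph::ecount(build_similarity_graph(pw2)), 1L)

  ## 5 proteins, 4 significant pairs -> 5 nodes, 4 edges
  pw3 <- data.frame(query_id = c("p1", "p2", "p3", "p4"),
                    subject_id = c("p2", "p3", "p4", "p5"),
                    evalue = 1e-30)
  g3 <- build_similarity_graph(pw3)
  expect_equal(igraph::vcount(g3), 5L)
  expect_equal(igraph::ecount(g3), 4L)
})

test_that("MCL recovers components and splits weakly bridged cliques", {
  ## two disjoint triangles -> exactly the two components
  tri <- function(v) data.frame(query_id = v[c(1, 2, 3)],
                                subject_id = v[c(2, 3, 1)], evalue = 1e-30)
  g <- build_similarity_graph(rbind(tri(c("a1", "a2", "a3")),
                                    tri(c("b1", "b2", "b3"))))
  cl <- mcl_cluster(g)
  expect_equal(length(unique(cl$group_id)), 2L)
  expect_equal(sort(cl$gene_id[cl$group_id == cl$group_id[cl$gene_id == "a1"]]),
               c("a1", "a2", "a3"))

  ## single edge -> one cluster of both nodes
  g1 <- build_similarity_graph(data.frame(query_id = "A", subject_id = "B",
                                          evalue = 1e-30))
  cl1 <- mcl_cluster(g1)
  expect_equal(length(unique(cl1$group_id)), 1L)

  ## barbell: two K4 joined by one weak edge; inflation 15 cuts the bridge
  k4 <- function(v) {
    idx <- t(combn(v, 2))
    data.frame(query_id = idx[, 1], subject_id = idx[, 2], evalue = 1e-50)
  }
  pw <- rbind(k4(paste0("L", 1:4)), k4(paste0("R", 1:4)),
              data.frame(query_id = "L1", subject_id = "R1", evalue = 1e-6))
  gb <- build_similarity_graph(pw)
  clb <- mcl_cluster(gb, inflation = 15)
  parts <- canon_partition(clb$gene_id, clb$group_id)
  expect_equal(parts, list(sort(paste0("L", 1:4)), sort(paste0("R", 1:4))))
})

test_that("mcl_cluster agrees with the loop-coded dense MCL oracle", {
  set.seed(2024)
  for (i in 1:30) {
    n <- sample(3:10, 1)
    A <- random_adjacency(n)
    nodes <- sprintf("n%02d", seq_len(n))
    dimnames(A) <- list(nodes, nodes)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    got <- mcl_cluster(g, inflation = 15)
    want <- mcl_oracle(A, inflation = 15)
    expect_equal(canon_partition(got$gene_id, got$group_id),
                 canon_partition(nodes, want))
  }
})

test_that("clusters partition the nodes and never span components", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(6:14, 1)
    A <- random_adjacency(n, p_edge = 0.25)
    nodes <- sprintf("n%02d", seq_len(n))
    dimnames(A) <- list(nodes, nodes)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    cl <- mcl_cluster(g, inflation = sample(c(2, 5, 15), 1))
    expect_setequal(cl$gene_id, nodes)            # coverage
    expect_equal(anyDuplicated(cl$gene_id), 0L)   # disjointness
    comp <- igraph::components(g)$membership
    for (grp in split(cl$gene_id, cl$group_id))
      expect_equal(length(unique(comp[grp])), 1L) # refinement of components
  }
})

test_that("h_orth averages member h values; unscored members veto class A only", {
  fx <- gob1_fixture()
  scores <- gene_scores(reduce_best_hits(fx$hits), fx$tx2gene)
  st <- compute_h_orth(fx$membership, scores)
  expect_equal(st$h_orth, 95.3)                  # mean(95.7, 102, 97.1, 86.4)
  expect_equal(st$group_max_met, 39.3)

  one <- compute_h_orth(data.frame(gene_id = "g", group_id = "G"),
                        data.frame(gene_id = "g", h = 40, best_met = 10))
  expect_equal(one$h_orth, 40)

  sym <- compute_h_orth(data.frame(gene_id = c("g1", "g2"), group_id = "G"),
                        data.frame(gene_id = c("g1", "g2"), h = c(30, -30),
                                   best_met = c(0, 0)))
  expect_equal(sym$h_orth, 0)

  ## no member carries h: h_orth undefined, class B impossible
  none <- compute_h_orth(data.frame(gene_id = "g", group_id = "G"),
                         data.frame(gene_id = "g", h = NA_real_,
                                    best_met = 120))
  expect_true(is.na(none$h_orth))
  expect_false(classify_class_b(TRUE, none$h_orth))

  ## unscored member excluded from the mean but vetoing class A
  mixed <- compute_h_orth(
    data.frame(gene_id = c("g1", "g2"), group_id = "G"),
    data.frame(gene_id = c("g1", "g2"), h = c(90, NA), best_met = c(20, 150)))
  expect_equal(mixed$h_orth, 90)
  expect_false(classify_class_a(TRUE, 20, mixed$group_max_met))
})

test_that("classes B and A apply the group-level gates", {
  expect_true(classify_class_b(TRUE, 95.3))       # gob-1 group
  expect_false(classify_class_b(TRUE, 29))        # boundary
  expect_true(classify_class_b(TRUE, 30))
  expect_false(classify_class_b(FALSE, 200))      # must be class C first

  expect_true(classify_class_a(TRUE, 39.3, 39.3)) # gob-1: all met < 100
  expect_false(classify_class_a(TRUE, 99.9, 150)) # group-mate veto
  expect_true(classify_class_a(TRUE, 0, 0))       # singleton, no metazoan hit
  expect_false(classify_class_a(FALSE, 0, 0))     # must be class B first
})

test_that("assign_hgt_classes nests A within B within C and keeps V disjoint", {
  fx <- gob1_fixture()
  scores <- gene_scores(reduce_best_hits(fx$hits), fx$tx2gene)
  cls <- assign_hgt_classes(scores, fx$membership)
  expect_equal(as.character(cls$hgt_class), rep("A", 4))
  expect_equal(cls$h_orth, rep(95.3, 4))

  ## genes missing from the membership become singleton groups
  cls2 <- assign_hgt_classes(scores, fx$membership[1:2, ])
  expect_equal(length(unique(cls2$group_id)), 3L)
  expect_false(any(is.na(cls2$group_id)))
})
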