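test_that("validation eligibility gates on the best metazoan bitscore", {
  sc <- data.frame(best_met = c(39.3, 50, 0, 49.9, NA))
  expect_equal(validation_eligible(sc), c(FALSE, TRUE, FALSE, FALSE, FALSE))
})

test_that("is_monophyletic matches the unrooted bipartition definition", {
  tr <- ape::read.tree(text = "((a1,a2),(b1,b2));")
  expect_true(is_monophyletic(tr, c("a1", "a2")))
  tr2 <- ape::read.tree(text = "((a1,b1),(a2,b2));")
  expect_false(is_monophyletic(tr2, c("a1", "a2")))
  expect_true(is_monophyletic(tr2, "a1"))                 # singleton
  expect_true(is_monophyletic(tr2, tr2$tip.label))        # full set
  ## soft polytomy: some resolution of a star groups any pair
  star <- ape::read.tree(text = "(a,b,c,d);")
  expect_true(is_monophyletic(star, c("a", "b")))
  expect_true(is_monophyletic(star, c("a", "c")))
})

test_that("is_monophyletic equals the edge-enumeration oracle on random trees", {
  set.seed(31)
  for (i in 1:200) {
    tr <- ape::unroot(ape::rtree(9))
    k <- sample(2:7, 1)
    tips <- sample(tr$tip.label, k)
    expect_equal(is_monophyletic(tr, tips), mono_oracle(tr, tips),
                 info = paste("draw", i))
  }
})

test_that("is_monophyletic is invariant under re-rooting and tip permutation", {
  set.seed(17)
  for (i in 1:25) {
    tr <- ape::rtree(8)
    tips <- sample(tr$tip.label, sample(2:5, 1))
    base <- is_monophyletic(tr, tips)
    rr <- ape::root(tr, outgroup = sample(tr$tip.label, 1), resolve.root = TRUE)
    expect_equal(is_monophyletic(rr, tips), base)
    expect_equal(is_monophyletic(tr, rev(tips)), base)
    rot <- ape::rotateConstr(tr, sample(tr$tip.label))
    expect_equal(is_monophyletic(rot, tips), base)
  }
})

test_that("gene trees validate by donor-only grouping with own phylum set aside", {
  ## canonical single-donor fixture
  v1 <- validate_gene_tree(
    "((focal|focal,(b1|bacteria,b2|bacteria)),((m1|metazoa,m2|metazoa),p1|own_phylum));",
    "focal|focal")
  expect_equal(v1$status, "validated_single_donor")
  expect_equal(v1$donor, "bacteria")

  ## canonical metazoan-grouping fixture
  v2 <- validate_gene_tree(
    "((focal|focal,m1|metazoa),(b1|bacteria,b2|bacteria),m2|metazoa);",
    "focal|focal")
  expect_equal(v2$status, "not_validated")
  expect_equal(v2$reason, "groups_with_metazoa")

  ## multiple potential donors: union of two kingdoms
  v3 <- validate_gene_tree(
    "((focal|focal,(f1|fungi,p1|protists)),(m1|metazoa,m2|metazoa));",
    "focal|focal")
  expect_equal(v3$status, "validated_multiple_donors")
  expect_equal(v3$donor, "ambiguous")

  ## no non-metazoan tips at all
  v4 <- validate_gene_tree(
    "((focal|focal,m1|metazoa),(m2|metazoa,m3|metazoa));", "focal|focal")
  expect_equal(v4$status, "not_validated")
  expect_equal(v4$reason, "no_nonmetazoan_tips")

  ## no metazoan tips outside own phylum: donor grouping suffices
  v5 <- validate_gene_tree(
    "((focal|focal,(b1|bacteria,b2|bacteria)),(o1|own_phylum,o2|own_phylum));",
    "focal|focal")
  expect_equal(v5$status, "validated_single_donor")
})

test_that("own-phylum tips do not break donor monophyly", {
  ## an own-phylum tip interleaved with the donors is pruned before testing
  v <- validate_gene_tree(
    "((focal|focal,(b1|bacteria,(o1|own_phylum,b2|bacteria))),(m1|metazoa,m2|metazoa));",
    "focal|focal")
  expect_equal(v$status, "validated_single_donor")
  expect_equal(v$donor, "bacteria")
})

test_that("relaxed mode accepts a focal gene nested inside a donor clade", {
  ## focal splits the bacteria, so the strict whole-kingdom test fails
  nwk <- "((b1|bacteria,(focal|focal,b2|bacteria)),(m1|metazoa,(b3|bacteria,m2|metazoa)));"
  expect_equal(validate_gene_tree(nwk, "focal|focal")$status, "not_validated")
  expect_equal(validate_gene_tree(nwk, "focal|focal", strict = FALSE)$status,
               "validated_single_donor")
})

test_that("a single stray metazoan tip can rescue an unvalidated tree", {
  nwk <- "((focal|focal,(b1|bacteria,ms|metazoa)),(m1|metazoa,m2|metazoa));"
  expect_equal(validate_gene_tree(nwk, "focal|focal")$status, "not_validated")
  expect_true(contamination_rescue(nwk, "focal|focal"))

  ## already-validated tree: precondition violation
  ok <- "((focal|focal,(b1|bacteria,b2|bacteria)),(m1|metazoa,m2|metazoa));"
  expect_warning(r <- contamination_rescue(ok, "focal|focal"), "not 'not_validated'")
  expect_true(is.na(r))

  ## every metazoan tip adjacent to another metazoan: no rescue candidate
  paired <- "((focal|focal,m1|metazoa),(m2|metazoa,m3|metazoa),(b1|bacteria,b2|bacteria));"
  expect_equal(validate_gene_tree(paired, "focal|focal")$status, "not_validated")
  expect_false(contamination_rescue(paired, "focal|focal"))
})

test_that("rescue never changes the recorded validated outcomes of a study", {
  st <- generate_study(sim_params(genes_per_species = 300, tree_noise = 0.3,
                                  fraction_ancient = 0.05,
                                  fraction_recent = 0.05, seed = 8))
  res <- run_study_pipeline(st)
  val <- res$validation
  expect_true(nrow(val) > 0)
  expect_true(all(!val$rescue[grepl("^validated", val$status)]))
  expect_true(any(val$status == "not_validated"))  # noise plants failures
})

test_that("phylogenetic and bitscore donors are compared only when unambiguous", {
  ok <- structure(list(status = "validated_single_donor", donor = "bacteria",
                       reason = NA, rescue = FALSE), class = "hgt_validation")
  expect_true(phylo_origin(ok, "bacteria"))
  expect_false(phylo_origin(ok, "fungi"))
  amb <- ok; amb$donor <- "ambiguous"
  expect_true(is.na(phylo_origin(amb, "bacteria")))
  nv <- ok; nv$status <- "not_validated"; nv$donor <- NA
  expect_true(is.na(phylo_origin(nv, "bacteria")))
})

test_that("noiseless planted trees give full donor agreement", {
  st <- generate_study(sim_params(genes_per_species = 300,
                                  fraction_ancient = 0.05,
                                  fraction_recent = 0.05, seed = 21))
  res <- run_study_pipeline(st)
  expect_true(nrow(res$validation) > 10)
  expect_true(all(grepl("^validated", res$validation$status)))
  expect_equal(mean(res$validation$agree, na.rm = TRUE), 1)
})
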