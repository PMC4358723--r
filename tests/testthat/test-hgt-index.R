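test_that("best-hit reduction takes maxima per subset with own-phylum excluded", {
  hits <- make_hits(
    list("t1", "b1", "bacteria", 80), list("t1", "b2", "bacteria", 100),
    list("t1", "b3", "bacteria", 120), list("t1", "b4", "bacteria", 95),
    list("t1", "b5", "bacteria", 110),
    list("t1", "f1", "fungi", 90), list("t1", "f2", "fungi", 95),
    list("t1", "m1", "metazoa", 60), list("t1", "o1", "own_phylum", 300))
  b <- reduce_best_hits(hits)
  expect_equal(b$best_bacteria, 120)
  expect_equal(b$best_fungi, 95)
  expect_equal(b$best_nonmet, 120)
  expect_equal(b$donor, "bacteria")
  expect_equal(b$best_met, 60)        # own_phylum 300 excluded

  only_own <- make_hits(list("t2", "o1", "own_phylum", 250))
  b2 <- reduce_best_hits(only_own)
  expect_equal(b2$best_met, 0)        # no-hit marker
  expect_true(is.na(b2$best_met_subject))

  b3 <- reduce_best_hits(only_own, exclude_own_phylum = FALSE)
  expect_equal(b3$best_met, 250)
})

test_that("compute_h subtracts best metazoan from best non-metazoan bitscore", {
  expect_equal(compute_h(135, 39.3), 95.7)   # gob-1
  expect_equal(compute_h(100, 100), 0)
  expect_equal(compute_h(150, 0), 150)        # missing metazoan match -> 0
  expect_true(is.na(compute_h(0, 150)))       # no non-metazoan hit: undefined
  ## data frame interface
  b <- reduce_best_hits(make_hits(list("t", "b", "bacteria", 135),
                                  list("t", "m", "metazoa", 39.3)))
  expect_equal(compute_h(b), 95.7)
})

test_that("h is shift-invariant and monotone in its two scores", {
  set.seed(42)
  for (i in 1:50) {
    nm <- runif(1, 50, 300); mt <- runif(1, 30, 300); c0 <- runif(1, -20, 50)
    expect_equal(compute_h(nm + c0, mt + c0), compute_h(nm, mt))
    eps <- runif(1, 0.1, 10)
    expect_gt(compute_h(nm + eps, mt), compute_h(nm, mt))
    expect_lt(compute_h(nm, mt + eps), compute_h(nm, mt))
  }
})

test_that("genes inherit h from the transcript with the highest bitscore", {
  hits <- make_hits(
    list("tA", "b1", "bacteria", 135), list("tA", "m1", "metazoa", 40),
    list("tB", "b2", "bacteria", 120), list("tB", "m2", "metazoa", 80))
  sc <- gene_scores(reduce_best_hits(hits),
                    data.frame(transcript_id = c("tA", "tB"),
                               gene_id = "g1"))
  expect_equal(sc$source_transcript, "tA")
  expect_equal(sc$h, 95)

  ## tie on the overall maximum: lexicographically first transcript wins
  hits2 <- make_hits(
    list("tA", "b1", "bacteria", 80),
    list("tB", "b2", "bacteria", 95), list("tC", "b3", "bacteria", 95))
  sc2 <- gene_scores(reduce_best_hits(hits2),
                     data.frame(transcript_id = c("tA", "tB", "tC"),
                                gene_id = "g2"))
  expect_equal(sc2$source_transcript, "tB")

  ## single transcript maps to itself
  sc3 <- gene_scores(reduce_best_hits(make_hits(list("tX", "b", "bacteria", 50))),
                     data.frame(transcript_id = "tX", gene_id = "g3"))
  expect_equal(sc3$source_transcript, "tX")
})

test_that("class C gates on h, non-metazoan bitscore and the viral flag", {
  mk <- function(nonmet, met) {
    b <- reduce_best_hits(make_hits(list("t", "b", "bacteria", nonmet),
                                    list("t", "m", "metazoa", met)))
    gene_scores(b, data.frame(transcript_id = "t", gene_id = "g"))
  }
  expect_true(classify_class_c(mk(135, 39.3)))    # gob-1 is at least class C
  expect_false(classify_class_c(mk(529.9, 500)))  # h = 29.9 < 30
  expect_false(classify_class_c(mk(99, 59)))      # nonmet 99 < 100
  expect_true(classify_class_c(mk(100, 70)))      # both boundaries inclusive
})

test_that("donor is the kingdom of the best non-metazoan match, ties by fixed order", {
  b <- reduce_best_hits(make_hits(list("t", "b", "bacteria", 120),
                                  list("t", "f", "fungi", 95)))
  expect_equal(assign_donor_taxon(b), "bacteria")
  b2 <- reduce_best_hits(make_hits(list("t", "f", "fungi", 150),
                                   list("t", "b", "bacteria", 120)))
  expect_equal(assign_donor_taxon(b2), "fungi")   # HAS1-like fungal origin
  b3 <- reduce_best_hits(make_hits(list("t", "b", "bacteria", 100),
                                   list("t", "p", "protists", 100)))
  expect_equal(assign_donor_taxon(b3), "bacteria")  # tie-break order
})

test_that("class V flags viral-only signals and never overlaps class C", {
  mk <- function(...) {
    sc <- gene_scores(reduce_best_hits(make_hits(...)),
                      data.frame(transcript_id = "t", gene_id = "g"))
    sc
  }
  v_only <- mk(list("t", "v", "viruses", 200), list("t", "b", "bacteria", 60),
               list("t", "m", "metazoa", 50))
  expect_true(flag_viral(v_only))
  expect_false(classify_class_c(v_only))

  cellular <- mk(list("t", "v", "viruses", 200),
                 list("t", "b", "bacteria", 180), list("t", "m", "metazoa", 50))
  expect_false(flag_viral(cellular))
  expect_true(classify_class_c(cellular))
  expect_equal(assign_donor_taxon(cellular), "bacteria")

  no_viral <- mk(list("t", "b", "bacteria", 150), list("t", "m", "metazoa", 20))
  expect_false(flag_viral(no_viral))

  ## disjointness on random scores
  set.seed(11)
  sc <- data.frame(gene_id = sprintf("g%03d", 1:200),
                   best_met = round(runif(200, 0, 250), 1),
                   best_nonmet = round(runif(200, 0, 250), 1),
                   best_viral = round(runif(200, 0, 250), 1))
  sc$h <- compute_h(sc$best_nonmet, sc$best_met)
  v <- flag_viral(sc)
  cc <- classify_class_c(sc, viral = v)
  expect_equal(sum(v & cc), 0L)
})

test_that("class C calls match a brute-force re-derivation from raw hits", {
  set.seed(99)
  taxa <- c("metazoa", "own_phylum", donor_kingdoms(), "viruses")
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    hits <- data.frame(
      query_id = paste0("t", sample(1:4, n, TRUE)),
      subject_id = paste0("s", seq_len(n)),
      taxon = sample(taxa, n, TRUE),
      bitscore = round(runif(n, 10, 200), 1),
      evalue = 1e-20)
    tx <- sort(unique(hits$query_id))
    tx2gene <- data.frame(transcript_id = tx, gene_id = tx)
    got <- classify_class_c(gene_scores(reduce_best_hits(hits), tx2gene))

    want <- vapply(tx, function(q) {
      sub <- hits[hits$query_id == q, ]
      mx <- function(tt) {
        v <- sub$bitscore[sub$taxon %in% tt]
        if (length(v)) max(v) else 0
      }
      nonmet <- mx(donor_kingdoms()); met <- mx("metazoa"); vir <- mx("viruses")
      if (nonmet <= 0) return(FALSE)
      h <- nonmet - met
      viral <- vir > 0 && (vir - met) >= 30 && vir >= 100 &&
        !(h >= 30 && nonmet >= 100)
      h >= 30 && nonmet >= 100 && !viral
    }, logical(1))
    expect_equal(got, unname(want))
  }
})
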