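# Toy proteomes are tiny (6-12 proteins of 60-120 aa) so the
# exhaustive dynamic-programming oracle stays fast.

toy_ref <- function(seed = 1) {
  genomes <- list(
    refA = random_proteins(4, c(60, 100), seed = seed),
    refB = random_proteins(4, c(60, 100), seed = seed + 1),
    refC = random_proteins(4, c(60, 100), seed = seed + 2)
  )
  prots <- unlist(lapply(names(genomes), function(g) {
    stats::setNames(genomes[[g]], sprintf("%s_%d", g, seq_along(genomes[[g]])))
  }))
  tax <- data.frame(
    genome_id = names(genomes),
    order = c("Imitervirales", "Algavirales", "Pimascovirales"),
    family = c("IM_01", "AG_02", "PM_05"),
    genus = c("GenusA", "GenusB", "GenusC"), stringsAsFactors = FALSE)
  list(db = aai_reference_db(prots, tax), genomes = genomes)
}

test_that("a query identical to a reference genome scores AAI 100 at AF 100", {
  tr <- toy_ref(11)
  q <- stats::setNames(tr$genomes$refA, sprintf("q_%d", 1:4))
  res <- aai_best_match(q, tr$db)
  expect_identical(res$best_match_genome_id, "refA")
  expect_equal(res$aai, 100)
  expect_equal(res$af, 100)
  expect_identical(res$order, "Imitervirales")
  expect_identical(res$genus, "GenusA")
})

test_that("one-way search returns the best hit per reference genome and none for empty queries", {
  tr <- toy_ref(12)
  q <- stats::setNames(tr$genomes$refB[1:2], c("q_1", "q_2"))
  hits <- one_way_search(q, tr$db)
  # at most one hit per (query protein, reference genome)
  expect_lte(max(table(hits$query_protein_id, hits$ref_genome_id)), 1)
  # exact copies align at 100% identity to their source
  self_hits <- hits[hits$ref_genome_id == "refB", ]
  expect_equal(self_hits$percent_identity, c(100, 100))
  expect_equal(nrow(one_way_search(character(0), tr$db)), 0)
})

test_that("best-per-genome hits match the exhaustive alignment oracle", {
  tr <- toy_ref(13)
  set.seed(14)
  q <- c(mutate_proteome(tr$genomes$refA[1:2], 0.1, seed = 14),
         random_proteins(1, c(60, 80), seed = 15))
  names(q) <- sprintf("q_%d", 1:3)
  hits <- one_way_search(q, tr$db)
  for (qp in names(q)) {
    for (g in names(tr$genomes)) {
      oracle_scores <- vapply(tr$genomes[[g]],
                              function(r) oracle_sw(q[[qp]], r)$score, 0)
      h <- hits[hits$query_protein_id == qp & hits$ref_genome_id == g, ]
      if (nrow(h) == 1) {
        expect_equal(h$score, max(oracle_scores))
        expect_lt(abs(h$percent_identity -
                        oracle_sw(q[[qp]],
                                  tr$genomes[[g]][[which.max(oracle_scores)]])$pid),
                  0.5)
      } else {
        expect_lt(max(oracle_scores), 60)  # below the hit threshold
      }
    }
  }
})

test_that("AAI is the mean best-hit identity and AF the hit fraction", {
  # 10 query proteins, 5 with best hits at identities 100..60
  hits <- data.frame(
    query_protein_id = sprintf("q_%d", 1:5),
    ref_protein_id = sprintf("r_%d", 1:5),
    ref_genome_id = "ref1",
    percent_identity = c(100, 90, 80, 70, 60),
    alignment_length = 100L, score = 200,
    stringsAsFactors = FALSE)
  q <- random_proteins(10, seed = 16)
  res <- compute_aai(hits, q, "ref1")
  expect_equal(res$af, 50)
  expect_equal(res$aai, 80)
  expect_error(compute_aai(hits, character(0), "ref1"), "empty query")
})

test_that("queries below the AF floor report AAI 0 with the raw value retained", {
  hits <- data.frame(
    query_protein_id = "q_1", ref_protein_id = "r_1",
    ref_genome_id = "ref1", percent_identity = 95,
    alignment_length = 100L, score = 300, stringsAsFactors = FALSE)
  q <- random_proteins(10, seed = 17)   # AF = 10 < 20
  res <- compute_aai(hits, q, "ref1")
  expect_equal(res$af, 10)
  expect_equal(res$aai, 0)
  expect_equal(res$aai_raw, 95)
  # AF = 19.9 -> 0; at the floor the value passes
  expect_equal(compute_aai(hits, random_proteins(5, seed = 18), "ref1")$aai, 95)
})

test_that("unrelated queries find no best match and the floor rule zeroes AAI", {
  tr <- toy_ref(19)
  q <- random_proteins(8, c(60, 90), seed = 200)
  res <- aai_best_match(q, tr$db)
  expect_true(is.na(res$best_match_genome_id))
  expect_equal(res$aai, 0)
})

test_that("AAI is invariant to query order and duplicate reference entries, and engineered divergence ranks correctly", {
  tr <- toy_ref(21)
  q <- mutate_proteome(tr$genomes$refC, 0.05, seed = 22)
  names(q) <- sprintf("q_%d", seq_along(q))
  r1 <- aai_best_match(q, tr$db)
  r2 <- aai_best_match(q[rev(seq_along(q))], tr$db)
  expect_equal(r1$aai, r2$aai)
  expect_identical(r1$best_match_genome_id, r2$best_match_genome_id)
  expect_identical(r1$best_match_genome_id, "refC")

  # duplicating a reference genome's proteins under the same genome id
  # changes nothing
  dup_prots <- c(tr$db$proteins, tr$db$proteins[tr$db$genome_of == "refC"])
  names(dup_prots) <- make.unique(names(dup_prots))
  db2 <- aai_reference_db(
    stats::setNames(as.character(dup_prots),
                    c(names(tr$db$proteins),
                      sprintf("refC_%d", 5:8))),
    tr$db$taxonomy)
  r3 <- aai_best_match(q, db2)
  expect_equal(r3$aai, r1$aai)
})

test_that("AAI decreases monotonically with proteome-wide mutation rate", {
  tr <- toy_ref(23)
  aais <- vapply(c(0, 0.05, 0.1, 0.2), function(p) {
    q <- if (p == 0) tr$genomes$refA else
      mutate_proteome(tr$genomes$refA, p, seed = 24)
    names(q) <- sprintf("q_%d", seq_along(q))
    aai_best_match(q, tr$db)$aai
  }, 0)
  expect_equal(aais[1], 100)
  expect_true(all(diff(aais) < 0))
})
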