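test_that("one-to-one pairing keeps the strongest hit per protein", {
  expect_equal(nrow(pair_hits(make_hit_tbl(character(), character(), double()))), 0)

  # one query hitting two subjects: only the stronger pair survives
  h <- make_hit_tbl(c("q1", "q1"), c("s1", "s2"), c(120, 80))
  got <- pair_hits(h)
  expect_equal(nrow(got), 1)
  expect_equal(got$subject_protein, "s1")
  expect_equal(got$bit_score, 120)

  # two disjoint hits are both kept, regardless of input order
  h2 <- make_hit_tbl(c("q1", "q2"), c("s1", "s2"), c(80, 120))
  expect_setequal(pair_hits(h2)$query_protein, c("q1", "q2"))
  expect_equal(pair_hits(h2), pair_hits(h2[2:1, ]))

  # insignificant e-values are discarded before pairing
  h3 <- make_hit_tbl(c("q1", "q2"), c("s1", "s2"), c(80, 120),
                     evalue = c(1e-30, 1e-2))
  expect_equal(pair_hits(h3)$query_protein, "q1")
  expect_equal(nrow(pair_hits(h3, min_evalue = 1e-1)), 2)
})

test_that("greedy pairing matches exhaustive maximum-weight matching on test instances", {
  withr::with_seed(29, {
    for (rep in 1:40) {
      # homolog-dominant instances (each query has one strong true partner,
      # plus weak spurious hits), the structure implant fixtures produce;
      # greedy pairing is provably optimal here and must equal the oracle
      nq <- sample(2:5, 1)
      ns <- nq + sample(0:2, 1)
      diag <- make_hit_tbl(sprintf("q%d", 1:nq), sprintf("s%d", 1:nq),
                           sample(seq(200, 400, by = 7), nq))
      grid <- expand.grid(q = sprintf("q%d", 1:nq), s = sprintf("s%d", 1:ns),
                          stringsAsFactors = FALSE)
      off_diag <- sub("q", "", grid$q) != sub("s", "", grid$s)
      grid <- grid[off_diag & runif(nrow(grid)) < 0.5, , drop = FALSE]
      weak <- make_hit_tbl(grid$q, grid$s,
                           sample(seq(40, 80, by = 1), nrow(grid), replace = TRUE))
      h <- rbind(diag, weak)[sample(nq + nrow(grid)), ]
      greedy <- sum(pair_hits(h)$bit_score)
      optimal <- oracle_matching_value(h)
      expect_lte(greedy, optimal)
      expect_equal(greedy, optimal, tolerance = 1e-12)
    }
  })
})

test_that("PUL scoring sums bits and applies the signature-pair eligibility rule", {
  class_of <- c(q1 = "CAZyme", q2 = "TC", q3 = "CAZyme",
                s1 = "CAZyme", s2 = "TC", s3 = "CAZyme")
  pairs <- make_hit_tbl(c("q1", "q2", "q3"), c("s1", "s2", "s3"),
                        c(120, 80, 45.5))
  m <- score_pul("cgc1", "PUL001", pairs, class_of)
  expect_equal(m$summed_bits, 245.5)
  expect_equal(m$n_cazyme_pairs, 2)
  expect_equal(m$n_other_signature_pairs, 1)
  expect_true(m$eligible)

  # all-CAZyme matches are ineligible: a cluster must also match a
  # transporter/regulator/sensor of the PUL
  m2 <- score_pul("cgc1", "PUL001",
                  make_hit_tbl(c("q1", "q3"), c("s1", "s3"), c(120, 45.5)),
                  class_of)
  expect_false(m2$eligible)
  expect_equal(m2$n_other_signature_pairs, 0)

  # empty pairing scores zero and is ineligible
  m3 <- score_pul("cgc1", "PUL001",
                  make_hit_tbl(character(), character(), double()), class_of)
  expect_equal(m3$summed_bits, 0)
  expect_false(m3$eligible)

  # class must agree on both sides; unknown proteins count as Other
  m4 <- score_pul("cgc1", "PUL001",
                  make_hit_tbl(c("q1", "q2"), c("s2", "s1"), c(100, 90)),
                  class_of)
  expect_equal(m4$summed_bits, 190)
  expect_false(m4$eligible)
})

test_that("score additivity: dropping a pair lowers the sum by its bit score", {
  withr::with_seed(31, {
    pairs <- make_hit_tbl(sprintf("q%d", 1:5), sprintf("s%d", 1:5),
                          round(runif(5, 40, 300), 1))
    class_of <- setNames(rep("CAZyme", 10), c(pairs$query_protein,
                                              pairs$subject_protein))
    full <- score_pul("c", "p", pairs, class_of)$summed_bits
    for (i in 1:5) {
      drop_i <- score_pul("c", "p", pairs[-i, ], class_of)$summed_bits
      expect_equal(full - drop_i, pairs$bit_score[i])
    }
  })
})

test_that("best PUL maximizes summed bits with deterministic tie-breaks", {
  pul_proteins <- tibble::tibble(
    pul_id = rep(c("PUL001", "PUL002", "PUL003"), each = 2),
    protein_id = sprintf("P%d", 1:6),
    gene_class = rep(c("CAZyme", "TC"), 3)
  )
  pul_substrates <- tibble::tibble(
    pul_id = c("PUL001", "PUL002", "PUL003"),
    substrate = c("mucin", "xylan", "starch")
  )
  class_of <- c(a = "CAZyme", b = "TC",
                setNames(pul_proteins$gene_class, pul_proteins$protein_id))

  # PUL001 scores 300, PUL002 scores 250: the 300-bit PUL wins
  hits <- make_hit_tbl(c("a", "b", "a", "b"), c("P1", "P2", "P3", "P4"),
                       c(180, 120, 150, 100))
  got <- best_pul("cgc1", c("a", "b"), pul_proteins, pul_substrates,
                  hits, class_of)
  # exhaustive comparison oracle over candidate PULs
  sums <- c(PUL001 = 180 + 120, PUL002 = 150 + 100)
  expect_equal(got$pul_id, names(which.max(sums)))
  expect_equal(got$substrate, "mucin")
  expect_equal(got$summed_bits, 300)

  # equal score and pair count: lexicographically smaller id wins
  hits_tie <- make_hit_tbl(c("a", "b", "a", "b"), c("P3", "P4", "P5", "P6"),
                           c(150, 100, 150, 100))
  got_tie <- best_pul("cgc1", c("a", "b"), pul_proteins, pul_substrates,
                      hits_tie, class_of)
  expect_equal(got_tie$pul_id, "PUL002")

  # assignment is invariant to hit input order
  withr::with_seed(13, {
    for (rep in 1:10) {
      perm <- hits[sample(nrow(hits)), ]
      expect_equal(best_pul("cgc1", c("a", "b"), pul_proteins,
                            pul_substrates, perm, class_of), got)
    }
  })

  # no eligible PUL (CAZyme-only matches) -> no assignment
  hits_caz <- make_hit_tbl("a", "P1", 500)
  expect_equal(nrow(best_pul("cgc1", c("a", "b"), pul_proteins,
                             pul_substrates, hits_caz, class_of)), 0)

  # a best PUL missing from the substrate map is an error
  expect_error(
    best_pul("cgc1", c("a", "b"), pul_proteins,
             pul_substrates[pul_substrates$pul_id != "PUL001", ],
             hits, class_of),
    "substrate map"
  )
})
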