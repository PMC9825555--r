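asg <- function(ids, subs) tibble::tibble(cgc_id = ids, substrate = subs)

test_that("combining assignments computes union, intersection and agreement", {
  universe <- c("c1", "c2", "c3", "c4")
  out <- combine_assignments(
    asg(c("c1", "c2"), c("starch", "xylan")),
    asg(c("c2", "c3"), c("xylan", "pectin")),
    universe
  )
  expect_equal(out$counts[c("n_union", "n_both", "n_agree")],
               list(n_union = 3L, n_both = 1L, n_agree = 1L))
  expect_equal(out$assignments$cgc_id, universe)
  expect_equal(out$assignments$agree, c(FALSE, TRUE, FALSE, FALSE))

  # agreement is case-insensitive and whitespace-tolerant
  out2 <- combine_assignments(asg("c1", "Starch "), asg("c1", "starch"), "c1")
  expect_equal(out2$counts$n_agree, 1L)

  # disjoint and identical assignment maps
  dis <- combine_assignments(asg("c1", "a"), asg("c2", "b"), universe)
  expect_equal(dis$counts[c("n_both", "n_agree")], list(n_both = 0L, n_agree = 0L))
  same <- combine_assignments(asg(c("c1", "c2"), c("a", "b")),
                              asg(c("c1", "c2"), c("a", "b")), universe)
  expect_equal(same$counts$n_agree, same$counts$n_both)
  expect_equal(same$counts$n_agree, same$counts$n_union)

  expect_error(
    combine_assignments(asg("c9", "a"), asg("c1", "a"), universe),
    "outside the universe"
  )
})

test_that("inclusion-exclusion and ordering invariants hold on random assignment sets", {
  withr::with_seed(43, {
    for (rep in 1:50) {
      universe <- sprintf("c%02d", 1:20)
      pickn <- function() sample(universe, sample(0:20, 1))
      subs <- c("starch", "xylan", "pectin")
      i1 <- pickn()
      i2 <- pickn()
      out <- combine_assignments(
        asg(i1, sample(subs, length(i1), replace = TRUE)),
        asg(i2, sample(subs, length(i2), replace = TRUE)),
        universe
      )
      n <- out$counts
      expect_equal(n$n_union, n$n_a1 + n$n_a2 - n$n_both)
      expect_gte(n$n_agree, 0)
      expect_lte(n$n_agree, n$n_both)
      expect_lte(n$n_both, min(n$n_a1, n$n_a2))
    }
  })
})

test_that("percentages reproduce printed precision with half-up rounding", {
  expect_equal(percentage(4183, 5111, 1), 81.8)
  expect_equal(percentage(41447, 168906, 2), 24.54)
  expect_equal(percentage(0, 10, 2), 0)
  # half-up at the rounding boundary (banker's rounding would give 12.34)
  expect_equal(percentage(12345, 100000, 2), 12.35)
  expect_error(percentage(1, 0), "denominator")
  # scale invariance up to rounding of the same real value
  withr::with_seed(47, {
    for (rep in 1:20) {
      a <- sample(1:500, 1)
      b <- sample(a:1000, 1)
      k <- sample(2:9, 1)
      expect_equal(percentage(k * a, k * b, 2), percentage(a, b, 2))
    }
  })
})

test_that("dataset summary counts genomes, clusters and per-approach coverage", {
  # 3 genomes; G1 and G2 carry a detectable cluster, G3 only scattered genes
  g1 <- genes_from_classes(c("CAZyme", "TC", "Other", "Other"), "G1", "c1")
  g2 <- genes_from_classes(c("Other", "CAZyme", "STP"), "G2", "c1")
  g3 <- genes_from_classes(c("Other", "CAZyme", "Other", "Other", "Other", "TC"),
                           "G3", "c1")
  genes <- dplyr::bind_rows(g1, g2, g3)
  members <- find_cgcs(genes)
  expect_setequal(unique(members$genome_id), c("G1", "G2"))

  hom <- asg(unique(members$cgc_id)[1], "starch")
  vote <- asg(unique(members$cgc_id), c("starch", "xylan"))
  s <- summarize_dataset(genes, members, hom, vote)
  expect_equal(s$counts$n_mags, 3)
  expect_equal(s$counts$n_proteins, 13)
  expect_equal(s$counts$n_cazymes, 3)
  expect_equal(s$counts$n_mags_with_cazymes, 3)
  expect_equal(s$counts$n_mags_with_cgcs, 2)
  expect_equal(s$counts$n_cgcs, 2)
  expect_equal(s$counts$n_cazymes_in_cgcs, 2)
  expect_equal(s$counts$homology$n_cgcs_assigned, 1)
  expect_equal(s$counts$voting$n_cgcs_assigned, 2)
  expect_equal(s$counts$homology$n_mags_assigned, 1)
  expect_equal(s$percentages$pct_mags_with_cgcs, percentage(2, 3, 2))

  # one cluster assigned starch by both approaches counts once in the union
  sc <- s$substrate_counts
  expect_equal(sc$cgc_count[sc$approach == "union" & sc$substrate == "starch"], 1L)
  expect_equal(top_substrates(sc, "union", 1)$substrate, "starch")

  # degenerate dataset: no CAZymes anywhere
  none <- genes_from_classes(rep("Other", 5))
  s0 <- summarize_dataset(none, find_cgcs(none), asg(character(), character()),
                          asg(character(), character()))
  expect_equal(s0$counts$n_cazymes, 0)
  expect_equal(s0$counts$n_cgcs, 0)
  expect_equal(s0$counts$homology$n_cgcs_assigned, 0)
  expect_equal(nrow(s0$substrate_counts), 0)
})
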