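test_that("encoding maps tokens to three states plus missing", {
  tab <- make_table(
    c("a", "b", "c", "d"), rep("All", 4),
    c("C/C", "A/A",
      "C/T", "A/A",
      "T/T", "A/A",
      "-/-", "A/A")
  )
  gm <- encode_genotypes(tab)
  expect_equal(unname(gm$states[, 1]), c(0, 1, 2, NA))
  expect_equal(unname(gm$alleles[, 1]), c("C", "T"))
  # monomorphic locus retained with a single allele, all homozygous-first
  expect_equal(unname(gm$states[, 2]), c(0, 0, 0, 0))
  expect_true(is.na(gm$alleles[2, 2]))
})

test_that("heterozygote tokens are unordered", {
  tab <- make_table(c("a", "b"), c("All", "All"), c("A/T", "T/A"))
  gm <- encode_genotypes(tab)
  expect_equal(unname(gm$states[, 1]), c(1, 1))
})

test_that("multi-allelic and all-missing loci are dropped with a warning", {
  tab <- make_table(
    c("a", "b", "c"), rep("All", 3),
    c("A/A", "-/-", "C/C",
      "C/C", "-/-", "C/C",
      "G/G", "-/-", "C/T")
  )
  expect_warning(gm <- encode_genotypes(tab), "dropped 2 of 3")
  expect_equal(ncol(gm$states), 1L)
  expect_setequal(gm$dropped$reason,
                  c("more than two alleles", "no non-missing call"))

  all_bad <- make_table(c("a", "b", "c"), rep("All", 3),
                        c("A/A", "C/C", "G/G"))
  expect_error(suppressWarnings(encode_genotypes(all_bad)), "no usable loci")
})

test_that("expected progeny is defined only at double-homozygous loci", {
  # loci: AAxAA, AAxBB, HETxAA, AAxNA, BBxBB
  tab <- make_table(
    c("m", "f"), c("Mo", "Fa"),
    c("A/A", "A/A", "A/C", "A/A", "C/C",
      "A/A", "C/C", "A/A", "-/-", "C/C")
  )
  gm <- encode_genotypes(tab)
  ep <- expected_progeny(gm, "m", "f")
  # locus 5 is monomorphic (only C observed), so its homozygote is state 0
  expect_equal(unname(ep$states), c(0, 1, NA, NA, 0))
  expect_error(expected_progeny(gm, "m", "nope"), "unknown individual")
})

test_that("Gower dissimilarity matches its defining examples", {
  x <- rep(0, 100)
  res <- gower_dissimilarity(x, x)
  expect_equal(res$gd, 0)
  expect_equal(res$usable_loci, 100L)

  expect_equal(gower_dissimilarity(rep(0, 10), rep(2, 10))$gd, 1)

  # (HOM_A vs HET), (HOM_A vs MISSING): s = {0.5, -}, w = {1, 0}
  res <- gower_dissimilarity(c(0, 0), c(1, NA))
  expect_equal(res$gd, 0.5)
  expect_equal(res$usable_loci, 1L)

  expect_warning(res <- gower_dissimilarity(c(NA, 0), c(1, NA)),
                 "no comparable loci")
  expect_true(is.na(res$gd))
  expect_equal(res$usable_loci, 0L)

  expect_error(gower_dissimilarity(1:3 * 0, 1:4 * 0), "length")
})

test_that("Gower properties hold against a brute-force oracle", {
  set.seed(42)
  for (rep in 1:20) {
    s <- random_states(10, 10, miss = 0.2)
    i <- sample(10, 1); j <- sample(10, 1)
    x <- s[i, ]; y <- s[j, ]
    got <- suppressWarnings(gower_dissimilarity(x, y))
    ora <- gower_oracle(x, y)
    expect_equal(got$gd, ora$gd)
    expect_equal(got$usable_loci, as.integer(ora$usable_loci))
    # symmetry
    expect_equal(got$gd, suppressWarnings(gower_dissimilarity(y, x))$gd)
    # bounds and self-identity
    if (!is.na(got$gd)) expect_true(got$gd >= 0 && got$gd <= 1)
    if (any(!is.na(x))) expect_equal(gower_dissimilarity(x, x)$gd, 0)
    # a zero-weight locus never changes GD
    if (!is.na(got$gd)) {
      expect_equal(suppressWarnings(
        gower_dissimilarity(c(x, 0), c(y, NA)))$gd, got$gd)
    }
    # invariance under locus permutation
    p <- sample(length(x))
    expect_equal(suppressWarnings(gower_dissimilarity(x[p], y[p]))$gd, got$gd)
  }
})

test_that("vectorised triad scoring equals per-triad recomputation", {
  set.seed(7)
  sim <- simulate_population(sim_config(n_founders = 8, n_families = 2,
                                        sibs_per_family = 2, n_loci = 60,
                                        missing_rate = 0.2, seed = 11))
  gm <- encode_genotypes(sim$table)
  triads <- enumerate_triads(gm)
  rec <- suppressWarnings(score_triads(gm, triads))
  pick <- sample(nrow(rec), 40)
  for (r in pick) {
    ep <- expected_progeny(gm, rec$mother_id[r], rec$father_id[r])
    ko <- gm$states[match(rec$offspring_id[r], gm$ids), ]
    ora <- suppressWarnings(gower_dissimilarity(ep, ko))
    expect_equal(rec$gd[r], ora$gd)
    expect_equal(rec$usable_loci[r], as.integer(ora$usable_loci))
    # expected-progeny states agree with the rule-based oracle
    sm <- gm$states[match(rec$mother_id[r], gm$ids), ]
    sf <- gm$states[match(rec$father_id[r], gm$ids), ]
    expect_equal(unname(ep$states), ep_oracle(sm, sf))
  }
})
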