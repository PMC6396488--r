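test_that("triad enumeration honours class keys and the n^2(n-1)/2 law", {
  roster3 <- data.frame(id = c("A", "B", "C"), class = "All")
  tr3 <- enumerate_triads(roster3)
  expect_equal(nrow(tr3), 9L)  # 3^2 * 2 / 2, brute force
  # brute-force check: unordered pairs x all offspring
  expect_equal(nrow(unique(tr3[, c("mother_id", "father_id")])), 3L)
  expect_true(all(tr3$mother_id != tr3$father_id))

  one <- enumerate_triads(data.frame(id = c("A", "B", "C"),
                                     class = c("Mo", "Fa", "Off")))
  expect_equal(nrow(one), 1L)
  expect_equal(one$mother_id, "A")
  expect_equal(one$offspring_id, "C")
  expect_false(one$self_overlap)

  # Pa qualifies for both parental roles; pair deduplicated
  pa <- enumerate_triads(data.frame(id = c("A", "B", "C"),
                                    class = c("Pa", "Pa", "Off")))
  expect_equal(nrow(pa), 1L)

  # self-overlap flagged where offspring is one of the parents
  expect_equal(sum(tr3$self_overlap), 6L)

  expect_error(enumerate_triads(data.frame(id = "A", class = "Mo")),
               "father|offspring")
})

test_that("77 individuals coded All give exactly 225302 triads", {
  roster <- data.frame(id = sprintf("I%02d", 1:77), class = "All")
  tr <- enumerate_triads(roster)
  expect_identical(nrow(tr), 225302L)
  expect_identical(nrow(tr), as.integer(77^2 * 76 / 2))
})

test_that("gap midpoint and undeterminable conditions follow the contract", {
  g <- find_gap(c(0.001, 0.002, 0.050, 0.051), max_ident = 0.1)
  expect_true(g$determinable)
  expect_equal(g$threshold, 0.026)
  expect_equal(g$gap_size, 0.048)
  expect_equal(g$n_below, 2L)

  expect_false(find_gap(c(0.2, 0.3, 0.4), max_ident = 0.1)$determinable)
  expect_false(find_gap(c(0.01, 0.02), max_ident = 0.1)$determinable)

  # ties resolve to the lower-GD gap (binary-exact spacing)
  tie <- find_gap(c(0.25, 0.5, 0.75), max_ident = 1)
  expect_equal(tie$threshold, 0.375)
})

test_that("evenly spread GDs produce no significant gap and no declarations", {
  # exactly uniform spacing: all gaps identical, Dixon returns 1
  even <- seq(0.001, 0.09, length.out = 40)
  g1 <- find_gap(even, max_ident = 0.1)
  expect_equal(g1$gap_p, 1)

  set.seed(9)
  ragged <- sort(runif(60, 0, 0.09))
  g2 <- find_gap(ragged, max_ident = 0.1)
  expect_gt(g2$gap_p, 0.01)

  rec <- data.frame(
    mother_id = "m", father_id = "f",
    offspring_id = sprintf("k%02d", seq_along(ragged)),
    self_overlap = FALSE, gd = ragged,
    usable_loci = 100L, declared = FALSE, p_value = NA_real_,
    stringsAsFactors = FALSE
  )
  out <- declare_triads(rec, g2, alpha = 0.01)
  expect_equal(sum(out$declared), 0L)
})

test_that("declaration tests candidates against the closest above-gap GDs", {
  # one true-like value far below a tight spurious cluster
  gds <- c(0.002, 0.0025, 0.06 + (0:39) * 0.001)
  rec <- data.frame(
    mother_id = "m", father_id = "f",
    offspring_id = sprintf("k%02d", seq_along(gds)),
    self_overlap = FALSE, gd = gds, usable_loci = 100L,
    declared = FALSE, p_value = NA_real_, stringsAsFactors = FALSE
  )
  gap <- find_gap(gds, max_ident = 0.2)
  expect_true(gap$determinable)
  expect_lt(gap$gap_p, 0.01)
  out <- declare_triads(rec, gap, alpha = 0.01, comparison_sample = 30)
  expect_true(all(out$declared[1:2]))
  expect_equal(sum(out$declared), 2L)
  expect_true(all(out$p_value[out$declared] <= 0.01))

  # a candidate nearly equal to the smallest above-gap value is not declared:
  # the gap sits between 0.055 and the cluster, but 0.055 is no outlier of
  # {0.055} U {0.06, 0.061, ...}
  gds2 <- c(0.055, 0.06 + (0:39) * 0.001)
  rec2 <- rec[seq_along(gds2), ]
  rec2$gd <- gds2
  gap2 <- find_gap(gds2, max_ident = 0.2)
  out2 <- declare_triads(rec2, gap2, alpha = 0.01, comparison_sample = 30)
  expect_equal(sum(out2$declared), 0L)

  # gate contract: insignificant gap declares nothing regardless of gds
  gap_forced <- gap
  gap_forced$gap_p <- 0.5
  out3 <- declare_triads(rec, gap_forced, alpha = 0.01)
  expect_equal(sum(out3$declared), 0L)

  # self-overlap triads are never declared even below threshold
  rec4 <- rec
  rec4$self_overlap[1] <- TRUE
  out4 <- declare_triads(rec4, gap, alpha = 0.01)
  expect_false(out4$declared[1])
  expect_true(out4$declared[2])
})

test_that("true trios score zero GD without error and low GD with error", {
  clean <- simulate_population(sim_config(n_founders = 12, n_families = 3,
                                          sibs_per_family = 2, n_loci = 300,
                                          error_rate = 0, missing_rate = 0,
                                          seed = 21))
  gm <- encode_genotypes(clean$table)
  for (r in seq_len(nrow(clean$truth$trios))) {
    tr <- clean$truth$trios[r, ]
    ep <- expected_progeny(gm, tr$mother_id, tr$father_id)
    ko <- gm$states[match(tr$offspring_id, gm$ids), ]
    expect_identical(gower_dissimilarity(ep, ko)$gd, 0)
  }

  noisy <- simulate_population(sim_config(n_founders = 12, n_families = 3,
                                          sibs_per_family = 2, n_loci = 600,
                                          error_rate = 0.01,
                                          missing_rate = 0.1, seed = 22))
  gm2 <- encode_genotypes(noisy$table)
  rec <- score_triads(gm2, enumerate_triads(gm2))
  key <- paste(pmin(rec$mother_id, rec$father_id),
               pmax(rec$mother_id, rec$father_id), rec$offspring_id)
  tkey <- with(noisy$truth$trios,
               paste(pmin(mother_id, father_id), pmax(mother_id, father_id),
                     offspring_id))
  true_gd <- rec$gd[key %in% tkey]
  false_gd <- rec$gd[!(key %in% tkey) & !rec$self_overlap]
  expect_true(all(true_gd >= 0))
  expect_lt(max(true_gd), min(false_gd))
})
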