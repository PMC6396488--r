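test_that("GDM and GDCV match hand-evaluated formulas", {
  # sigma of {0.1, 0.3} with divisor j-1, re-expressed in units of gd_ik = 0.2
  res <- compute_gdcv(c(0.1, 0.3), 0.2)
  expect_equal(res$sigma_gd, 0.1414214, tolerance = 1e-6)
  expect_equal(res$gdcv, 0.7071068, tolerance = 1e-6)

  res0 <- compute_gdcv(c(0.2, 0.2, 0.2), 0.5)
  expect_equal(res0$sigma_gd, 0)
  expect_equal(res0$gdcv, 0)

  # undefined cases: too few GDs, or a zero-distance "parent"
  expect_true(is.na(compute_gdcv(c(0.2), 0.5)$gdcv))
  expect_true(is.na(compute_gdcv(c(0.1, 0.3), 0)$gdcv))
})

test_that("GDM reduces to a single GD with one co-parent and to 0 for exact EPs", {
  # all individuals homozygous identical: every EP equals the offspring
  tab <- make_table(c("p", "q", "r", "k"), c("Pa", "Pa", "Pa", "Off"),
                    rep("A/A", 4 * 5))
  gm <- encode_genotypes(tab)
  one <- compute_gdm(gm, "p", "k", "q")
  expect_equal(one$gdm, gower_dissimilarity(expected_progeny(gm, "p", "q"),
                                            gm$states[4, ])$gd)
  expect_equal(compute_gdm(gm, "p", "k", c("q", "r"))$gdm, 0)
  expect_error(compute_gdm(gm, "p", "k", character(0)), "empty")
  expect_error(compute_gdm(gm, "p", "k", c("p", "q")), "co-parent")
})

test_that("run_dyad validates inputs and returns coherent records", {
  sim <- simulate_population(sim_config(n_founders = 10, n_families = 2,
                                        sibs_per_family = 2, n_loci = 200,
                                        seed = 13))
  gm <- encode_genotypes(sim$table)
  offs <- gm$ids[grepl("Off", gm$ids)]

  expect_error(run_dyad(gm, offs, gm$ids[1:2]), "at least 3")
  expect_error(run_dyad(gm, offs, gm$ids, confidence = 1.2), "confidence")

  d <- run_dyad(gm, offs, setdiff(gm$ids, offs), confidence = 0.99)
  # z-scores standardised within each offspring's candidate set
  for (k in offs) {
    z <- d$gdm_z[d$offspring_id == k]
    expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-10)
    expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-10)
  }
  # reported pairs are a subset of stage-1 flags
  expect_true(all(!d$stage2_flag | d$stage1_flag))
  # cumulative p is a product of two tail probabilities, hence in [0, 1]
  expect_true(all(d$cumulative_p >= 0 & d$cumulative_p <= 1, na.rm = TRUE))

  # loosening the confidence can only grow the stage-1 flag set
  d_loose <- run_dyad(gm, offs, setdiff(gm$ids, offs), confidence = 0.5)
  key <- paste(d$parent_id, d$offspring_id)
  key_loose <- paste(d_loose$parent_id, d_loose$offspring_id)
  expect_true(all(key[d$stage1_flag] %in% key_loose[d_loose$stage1_flag]))
})

test_that("the remaining parent is recovered when one parent is removed", {
  rp <- data.frame(family = 1:2, parent = c("mother", "father"))
  sim <- simulate_population(sim_config(n_founders = 34, n_families = 2,
                                        sibs_per_family = 3, n_loci = 800,
                                        remove_parents = rp,
                                        generational_labels = TRUE, seed = 17))
  gm <- encode_genotypes(sim$table)
  adults <- gm$ids[gm$classes == "Pa"]
  offs <- gm$ids[gm$classes == "Off"]
  d <- suppressWarnings(run_dyad(gm, offs, adults, confidence = 0.99))
  rep_pairs <- d[d$stage2_flag, ]
  truth <- sim$truth
  expected <- data.frame(
    parent = ifelse(truth$trios$mother_id %in% truth$removed,
                    truth$trios$father_id, truth$trios$mother_id),
    offspring = truth$trios$offspring_id
  )
  expect_setequal(paste(rep_pairs$parent_id, rep_pairs$offspring_id),
                  paste(expected$parent, expected$offspring))
  # the true parent is the GDM minimum among candidates for its offspring
  for (r in seq_len(nrow(expected))) {
    dk <- d[d$offspring_id == expected$offspring[r], ]
    expect_equal(dk$parent_id[which.min(dk$gdm)], expected$parent[r])
  }
})

test_that("offspring unrelated to every candidate yields an empty report", {
  # remove BOTH parents of family 1; no relatives of its offspring remain
  rp <- data.frame(family = c(1, 1), parent = c("mother", "father"))
  sim <- simulate_population(sim_config(n_founders = 24, n_families = 1,
                                        sibs_per_family = 1, n_loci = 800,
                                        remove_parents = rp,
                                        generational_labels = TRUE, seed = 19))
  gm <- encode_genotypes(sim$table)
  adults <- gm$ids[gm$classes == "Pa"]
  offs <- gm$ids[gm$classes == "Off"]
  d <- suppressWarnings(run_dyad(gm, offs, adults, confidence = 0.99))
  expect_equal(sum(d$stage2_flag), 0L)
})
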