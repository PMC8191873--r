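test_that("simulated trees have the requested shape and are reproducible", {
  cfg4 <- sim_config(n_species = c(E = 2L, L = 2L),
                     alignment_length = 20L, n_conserved = 16L, n_drift = 0L,
                     n_clade = 2L, n_mass = 2L, mass_midpoints = c(0, 1))
  tr <- simulate_tree(cfg4, seed = 3)
  expect_identical(length(tr$tip.label), 4L)
  expect_identical(tr$Nnode, 3L)

  cfg <- sim_config(seed = 5)
  t1 <- simulate_tree(cfg)
  t2 <- simulate_tree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_identical(length(t1$tip.label), 67L)
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(t1)), 1, tolerance = 1e-10)
  expect_identical(sort(unique(unname(attr(t1, "clade_of_tip")))),
                   c("Afrotheria", "Euarchontoglires", "Laurasiatheria",
                     "Metatheria"))
})

test_that("masses respect clade bounds and span many orders of magnitude", {
  cfg <- sim_config(seed = 8)
  tr <- simulate_tree(cfg)
  md <- simulate_masses(tr, cfg)
  expect_true(all(md$mass_kg >= 0.006 & md$mass_kg <= 1e4))
  expect_gte(max(md$mass_kg) / min(md$mass_kg), 1e5)

  cfg_c <- sim_config(seed = 8, confounded = TRUE)
  md_c <- simulate_masses(tr, cfg_c)
  big <- md_c$species_id[md_c$mass_kg > 500]
  expect_true(all(md_c$clade[md_c$species_id %in% big] != "Euarchontoglires"))
})

test_that("Brownian masses give variance-standardized log-mass contrasts", {
  cfg <- sim_config(seed = 9)
  tr <- simulate_tree(cfg)
  md <- simulate_masses(tr, cfg, mode = "brownian")
  logm <- setNames(log10(md$mass_kg), md$species_id)
  cs <- contrasts(tr, logm)$contrast
  # affine map of a Brownian trait: contrasts stay zero-mean and homoscedastic
  expect_lt(abs(mean(cs)) / sd(cs), 0.5)
  expect_gt(shapiro.test(cs)$p.value, 0.01)
})

test_that("alignments are deterministic with planted classes as configured", {
  cfg <- sim_config(seed = 11)
  tr <- simulate_tree(cfg)
  md <- simulate_masses(tr, cfg)
  s1 <- simulate_alignment(tr, md, cfg)
  s2 <- simulate_alignment(tr, md, cfg)
  expect_identical(s1$alignment$records, s2$alignment$records)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$alignment$length, 800L)
  expect_identical(as.vector(table(s1$truth$class)[c(
    "clade_marker", "conserved", "drift", "mass_threshold")]),
    c(12L, 632L, 144L, 12L))

  md_bad <- md[-1, ]
  expect_error(simulate_alignment(tr, md_bad, cfg), "differ")
})

test_that("noiseless steep mass sites are perfect steps in mass order", {
  cfg <- sim_config(seed = 12, epsilon = 0, steepness = 1e4)
  tr <- simulate_tree(cfg)
  md <- simulate_masses(tr, cfg)
  sim <- simulate_alignment(tr, md, cfg)
  truth <- sim$truth
  m <- do.call(rbind, strsplit(sim$alignment$records, ""))
  rownames(m) <- names(sim$alignment$records)
  ord <- md$species_id[order(md$mass_kg)]
  for (k in truth$column[truth$class == "mass_threshold"]) {
    col <- m[ord, k]
    runs <- rle(col)$values
    expect_lte(length(runs), 2L)  # one switch along the mass axis at most
  }
})

test_that("with zero drift only planted sites vary", {
  cfg <- sim_config(seed = 13, drift_rate = 0)
  tr <- simulate_tree(cfg)
  md <- simulate_masses(tr, cfg)
  sim <- simulate_alignment(tr, md, cfg)
  prof <- profile_sites(sim$alignment)
  variable <- prof$column[prof$n_distinct > 1L]
  planted <- sim$truth$column[sim$truth$class %in%
                                c("clade_marker", "mass_threshold")]
  expect_true(all(variable %in% planted))
})

test_that("recovery scoring matches hand-computed confusion counts", {
  truth <- data.frame(column = 1:10,
                      class = c(rep("mass_threshold", 4), rep("conserved", 6)),
                      midpoint = c(0, 1, 2, 3, rep(NA, 6)))
  res_perfect <- data.frame(column = 1:4, classification = "mass_only",
                            midpoint_log10_mass = c(0, 1, 2, 3))
  r <- evaluate_recovery(res_perfect, truth)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$precision, 1)
  expect_equal(r$midpoint_abs_err, rep(0, 4))

  res_none <- data.frame(column = integer(), classification = character(),
                         midpoint_log10_mass = numeric())
  r0 <- evaluate_recovery(res_none, truth)
  expect_equal(r0$sensitivity, 0)
  expect_true(is.na(r0$precision))

  res_half <- data.frame(column = c(1, 2, 9), classification = "mass_only",
                         midpoint_log10_mass = c(0.2, 1.3, 0))
  rh <- evaluate_recovery(res_half, truth)
  expect_equal(rh$tp, 2L)
  expect_equal(rh$sensitivity, 0.5)
  expect_equal(rh$precision, 2 / 3)
  expect_identical(rh$false_positives, 9)
  expect_equal(rh$midpoint_abs_err, c(0.2, 0.3))
})

test_that("identity to the smallest species declines with mass end to end", {
  cfg <- sim_config(seed = 14)
  tr <- simulate_tree(cfg)
  md <- simulate_masses(tr, cfg)
  sim <- simulate_alignment(tr, md, cfg)
  ser <- identity_series(sim$alignment, md)
  f <- fit_identity_mass(ser, boot_reps = 100, seed = 2)
  expect_lt(f$gradient, 0)
  # planted signal: 12 step sites over ~4.5 decades of midpoints in an
  # 800-column alignment, i.e. a fraction of a percent per decade
  expect_lt(abs(f$gradient), 0.8)
  expect_true(is.finite(f$gradient_se) && f$gradient_se > 0)
})
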