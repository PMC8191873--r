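# alignment whose column k is given by the k-th character vector
aln_cols <- function(cols, ids = NULL, ref = NULL) {
  m <- do.call(cbind, cols)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(m)))
  seqs <- apply(m, 1, paste, collapse = "")
  names(seqs) <- ids
  new_alignment(seqs, if (is.null(ref)) ids[1] else ref)
}

meta_for <- function(ids, mass, clade = "X") {
  data.frame(species_id = ids, mass_kg = mass, clade = clade,
             stringsAsFactors = FALSE)
}

test_that("site profiles count consensus and distinct amino acids", {
  a <- aln_cols(list(rep("A", 67),
                     c(rep("A", 60), rep("G", 7)),
                     c(rep("-", 66), "A")))
  p <- profile_sites(a)
  expect_equal(p$consensus[1], "A")
  expect_equal(p$consensus_freq[1], 1)
  expect_equal(p$n_distinct[1], 1L)
  expect_equal(p$consensus_freq[2], 60 / 67)
  expect_equal(p$n_distinct[2], 2L)
  expect_false(p$all_gap[3])

  g <- aln_cols(list(rep("A", 4), rep("-", 4)))
  pg <- profile_sites(g)
  expect_true(pg$all_gap[2])
  expect_false(any(select_sites(pg)$column == 2))
})

test_that("site selection applies strict consensus and minor-ratio rules", {
  n <- 100
  cols <- list(c(rep("A", 89), rep("G", 11)),   # consensus 0.89 -> selected
               c(rep("A", 90), rep("G", 10)),   # exactly 0.90 -> not (strict <)
               rep("A", n))                     # monomorphic -> never
  a <- aln_cols(cols)
  sel <- select_sites(profile_sites(a))
  expect_identical(sel$column, 1L)

  selr <- select_sites(profile_sites(a), rule = "minor_ratio")
  expect_identical(sort(selr$column), c(1L, 2L))  # 10 >= 0.1 * 90 passes
  expect_error(select_sites(profile_sites(a), rule = "nonsense"))
})

test_that("planted variable sites are selected exactly", {
  set.seed(77)
  n <- 40
  planted <- sort(sample(1:30, 12))
  cols <- lapply(1:30, function(k) {
    if (k %in% planted) {
      minority <- sample(n, round(0.3 * n))
      col <- rep("A", n); col[minority] <- "P"
      col
    } else rep("L", n)
  })
  sel <- select_sites(profile_sites(aln_cols(cols)))
  expect_identical(sel$column, planted)
})

test_that("binary encoding keeps the top two amino acids, oriented by mass", {
  ids <- sprintf("s%02d", 1:67)
  col <- c(rep("A", 40), rep("P", 20), rep("S", 7))
  a <- aln_cols(list(col), ids = ids)
  # carriers of A are the lightest, S carriers heaviest
  md <- meta_for(ids, c(10^runif(40, -2, -1), 10^runif(20, 1, 2), rep(5, 7)))
  enc <- encode_site(a, 1, md)
  expect_identical(c(enc$aa0, enc$aa1), c("A", "P"))
  expect_identical(length(enc$excluded), 7L)
  expect_identical(enc$n0, 40L)
  expect_identical(enc$n1, 20L)

  # frequency tie: alphabetical pair order, orientation by carrier median mass
  ids4 <- paste0("t", 1:4)
  a4 <- aln_cols(list(c("P", "P", "A", "A")), ids = ids4)
  md4 <- meta_for(ids4, c(0.1, 0.2, 10, 20))
  enc4 <- encode_site(a4, 1, md4)
  expect_identical(enc4$aa0, "P")  # P carriers lighter
  expect_identical(enc4$aa1, "A")

  md4b <- meta_for(ids4, c(1, 2, 1, 2))  # median tie -> alphabetical
  expect_identical(encode_site(a4, 1, md4b)$aa0, "A")

  expect_error(encode_site(aln_cols(list(rep("A", 4)), ids = ids4), 1, md4),
               "monomorphic")
})

test_that("Mann-Whitney p-values match enumeration oracles and wilcox.test", {
  ids <- paste0("s", 1:4)
  a <- aln_cols(list(c("A", "A", "P", "P")), ids = ids)
  md <- meta_for(ids, c(1, 2, 10, 20))
  r <- mass_association(encode_site(a, 1, md), md)
  expect_equal(r$p, 1 / 3)
  expect_identical(r$method, "exact")

  md_tie <- meta_for(ids, c(5, 5, 5, 5))
  expect_equal(mass_association(encode_site(a, 1, md_tie), md_tie)$p, 1)

  # exact path against brute-force enumeration and (tie-free) wilcox.test
  set.seed(12)
  for (rep in 1:10) {
    n0 <- sample(2:5, 1); n1 <- sample(2:5, 1)
    m0 <- round(rlnorm(n0), 2); m1 <- round(rlnorm(n1, 1), 2)
    p <- myomass:::mw_exact_p(m0, m1)
    expect_equal(p, mw_brute_p(m0, m1))
    if (!anyDuplicated(c(m0, m1)))
      expect_equal(p, suppressWarnings(wilcox.test(m0, m1, exact = TRUE)$p.value))
  }

  # normal approximation against wilcox.test and a permutation oracle
  set.seed(13)
  m0 <- rlnorm(30); m1 <- rlnorm(30, 0.6)
  p_approx <- myomass:::mw_approx_p(m0, m1)
  expect_equal(p_approx,
               wilcox.test(m0, m1, exact = FALSE, correct = TRUE)$p.value)
  perm <- replicate(20000, {
    g <- sample(60, 30)
    vals <- c(m0, m1)
    sum(rank(vals)[g])
  })
  e <- 30 * 61 / 2
  w_obs <- sum(rank(c(m0, m1))[1:30])
  p_perm <- mean(abs(perm - e) >= abs(w_obs - e) - 1e-9)
  expect_lt(abs(p_approx - p_perm) / p_perm, 0.10)
})

test_that("mass association is invariant to monotone mass transforms", {
  ids <- paste0("s", 1:20)
  a <- aln_cols(list(rep(c("A", "P"), 10)), ids = ids)
  set.seed(14)
  md <- meta_for(ids, 10^rnorm(20))
  p1 <- mass_association(encode_site(a, 1, md), md)$p
  md2 <- md; md2$mass_kg <- md$mass_kg^3
  p2 <- mass_association(encode_site(a, 1, md2), md2)$p
  md3 <- md; md3$mass_kg <- log1p(md$mass_kg)
  p3 <- mass_association(encode_site(a, 1, md3), md3)$p
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("Fisher exact p matches hand values, enumeration and fisher.test", {
  expect_equal(fisher_exact_p(matrix(c(2, 0, 0, 2), 2)), 1 / 3)
  expect_equal(fisher_exact_p(matrix(c(1, 1, 1, 1), 2)), 1)
  big <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_exact_p(big), fisher_brute_p(big))
  expect_equal(fisher_exact_p(big), fisher.test(big)$p.value)

  set.seed(15)
  for (rep in 1:25) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_p(tab), fisher_brute_p(tab))
    expect_equal(fisher_exact_p(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("clade association builds the 2x2 over the clade pair only", {
  ids <- paste0("s", 1:12)
  a <- aln_cols(list(c(rep("A", 5), rep("P", 5), "A", "P")), ids = ids)
  md <- meta_for(ids, rep(1:12),
                 clade = c(rep("E", 5), rep("L", 5), "M", "M"))
  r <- clade_association(encode_site(a, 1, md), md, c("E", "L"))
  expect_equal(sum(r$table), 10)  # the two M species never enter
  expect_equal(r$p, fisher.test(matrix(c(5, 0, 0, 5), 2))$p.value)
  expect_error(clade_association(encode_site(a, 1, md), md, c("E", "Z")),
               "absent")
})

test_that("Bonferroni thresholds follow alpha / m", {
  expect_equal(adjusted_threshold(0.05, 52), 0.05 / 52)
  expect_equal(signif(adjusted_threshold(0.05, 52), 3), 9.62e-4)
  expect_equal(signif(adjusted_threshold(0.01, 52), 3), 1.92e-4)
  expect_equal(adjusted_threshold(0.05, 1), 0.05)
  expect_error(adjusted_threshold(1.2, 10), "alpha")
  expect_error(adjusted_threshold(0.05, 0), "m_tests")
})

enc_from_states <- function(states, masses) {
  ids <- sprintf("s%03d", seq_along(states))
  md <- meta_for(ids, masses)
  a <- aln_cols(list(ifelse(states == 1, "P", "A")), ids = ids)
  list(enc = encode_site(a, 1, md), md = md)
}

test_that("logistic transition midpoint respects symmetry and mass scaling", {
  logm <- c(-2, -1, -0.5, -0.1, 0.1, 0.5, 1, 2)
  states <- c(0, 0, 1, 0, 1, 0, 1, 1)  # symmetric about log-mass 0
  x <- enc_from_states(states, 10^logm)
  ft <- fit_transition(x$enc, x$md)
  expect_equal(ft$midpoint_log10_mass, 0, tolerance = 1e-6)
  expect_gt(ft$beta1, 0)
  expect_equal(ft$transition_range_log10, 2 * log(9) / ft$beta1)

  # multiplying all masses by 10^c shifts the midpoint by exactly c
  x2 <- enc_from_states(states, 10^(logm + 1.7))
  ft2 <- fit_transition(x2$enc, x2$md)
  expect_equal(ft2$midpoint_log10_mass, ft$midpoint_log10_mass + 1.7,
               tolerance = 1e-5)
  expect_equal(ft2$beta1, ft$beta1, tolerance = 1e-5)
})

test_that("steep noiseless transitions at n = 200 are recovered within 0.1", {
  set.seed(16)
  logm <- runif(200, log10(0.006), 4)
  states <- as.integer(logm > 1.5)
  x <- enc_from_states(states, 10^logm)
  ft <- fit_transition(x$enc, x$md)
  expect_true(ft$separation)
  expect_identical(ft$method, "firth")
  expect_lt(abs(ft$midpoint_log10_mass - 1.5), 0.1)
})

test_that("complete separation yields a finite penalized fit matching a grid oracle", {
  logm <- c(-2, -1.5, -1, -0.5, -0.2, 0.2, 0.5, 1, 1.5, 2)
  states <- as.integer(logm > 0)
  x <- enc_from_states(states, 10^logm)
  ft <- fit_transition(x$enc, x$md)
  expect_true(ft$separation)
  expect_true(is.finite(ft$beta1))
  expect_gt(ft$midpoint_log10_mass, -0.2)
  expect_lt(ft$midpoint_log10_mass, 0.2)

  grid <- firth_grid(logm, states)
  expect_equal(ft$midpoint_log10_mass,
               unname(-grid["beta0"] / grid["beta1"]), tolerance = 0.05)

  ids <- sprintf("s%03d", 1:10)
  mono_enc <- structure(list(state = setNames(rep(1L, 10), ids)),
                        class = "myo_encoding")
  expect_error(fit_transition(mono_enc, meta_for(ids, 10^logm)), "degenerate")
})

test_that("sites classify by the Bonferroni-adjusted p pair", {
  expect_identical(classify_site(1e-6, 0.5, 52), "mass_only")
  expect_identical(classify_site(0.5, 1e-6, 52), "clade_only")
  expect_identical(classify_site(1e-6, 1e-6, 52), "both")
  expect_identical(classify_site(0.02, 0.02, 52), "neither")
  expect_identical(classify_site(c(1e-6, 0.02), c(0.5, 0.02), 52),
                   c("mass_only", "neither"))
})

test_that("hypervariable flagging uses inclusive reference containment", {
  expect_true(flag_hypervariable(630))
  expect_false(flag_hypervariable(326))
  expect_true(flag_hypervariable(615))   # boundary inclusive
  expect_identical(flag_hypervariable(c(1, 36, 37, NA, 214)),
                   c(TRUE, TRUE, FALSE, FALSE, TRUE))
})

test_that("annotation overlap separates position and exact substitution matches", {
  sites <- data.frame(residue = c(44, 326), aa_to = c("D", "P"))
  ann <- data.frame(residue = c(44, 326, 500),
                    category = c("HCM", "HCM", "DCM"),
                    substitution = c("E44D", "A326P", "R500Q"))
  ov <- overlap_annotations(sites, ann)
  expect_identical(ov$n_position, 2L)
  expect_identical(ov$n_exact, 2L)

  ov2 <- overlap_annotations(data.frame(residue = 44, aa_to = "G"), ann)
  expect_identical(ov2$n_position, 1L)
  expect_identical(ov2$n_exact, 0L)

  ov3 <- overlap_annotations(data.frame(residue = 900, aa_to = "G"), ann)
  expect_identical(ov3$n_position, 0L)
  expect_identical(ov3$n_exact, 0L)
})

test_that("scanning a monomorphic alignment warns and returns no sites", {
  ids <- paste0("s", 1:8)
  a <- aln_cols(rep(list(rep("A", 8)), 5), ids = ids)
  md <- meta_for(ids, 1:8, clade = rep(c("E", "L"), 4))
  expect_warning(res <- scan_alignment(a, md), "no variable sites")
  expect_identical(nrow(res), 0L)
})
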