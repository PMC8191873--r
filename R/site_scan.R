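# Per-column site scan: conservation profiling, selection of variable sites,
# top-two amino-acid binary encoding, mass (Mann-Whitney) and clade (Fisher
# exact) association with Bonferroni control, and classification of each site
# as mass-associated, clade-associated, both, or neither.

#' Conservation profile of every alignment column
#'
#' For each column: the consensus (most frequent, ties alphabetical) amino
#' acid, its frequency as a fraction of all sequences, the second most
#' frequent amino acid, and the number of distinct amino acids. Gaps are
#' tallied separately and are never eligible as consensus; all-gap columns
#' are flagged and must be excluded downstream.
#'
#' @param alignment a `myo_alignment`.
#' @param columnmap optional output of [map_reference_coordinates()]; when
#'   omitted it is computed from the alignment's reference.
#' @return data.frame with one row per column: `column`, `label`,
#'   `ref_number`, `consensus`, `consensus_count`, `consensus_freq`,
#'   `second`, `second_count`, `n_distinct`, `n_gap`, `all_gap`.
#' @export
profile_sites <- function(alignment, columnmap = NULL) {
  if (alignment$length < 1L) fail("empty alignment")
  if (is.null(columnmap)) columnmap <- map_reference_coordinates(alignment)
  m <- alignment_matrix(alignment)
  nseq <- nrow(m)
  out <- lapply(seq_len(ncol(m)), function(k) {
    col <- m[, k]
    n_gap <- sum(col == GAP)
    aa <- col[col != GAP]
    if (!length(aa)) {
      return(data.frame(consensus = NA_character_, consensus_count = 0L,
                        consensus_freq = NA_real_, second = NA_character_,
                        second_count = 0L, n_distinct = 0L, n_gap = n_gap,
                        all_gap = TRUE, stringsAsFactors = FALSE))
    }
    tab <- table(aa)
    tab <- tab[order(-tab, names(tab))]  # count desc, alphabetical on ties
    data.frame(
      consensus = names(tab)[1L], consensus_count = as.integer(tab[1L]),
      consensus_freq = as.integer(tab[1L]) / nseq,
      second = if (length(tab) > 1L) names(tab)[2L] else NA_character_,
      second_count = if (length(tab) > 1L) as.integer(tab[2L]) else 0L,
      n_distinct = length(tab), n_gap = n_gap, all_gap = FALSE,
      stringsAsFactors = FALSE
    )
  })
  cbind(columnmap[, c("column", "label", "ref_number")],
        do.call(rbind, out))
}

#' Select variable sites for association testing
#'
#' Two rules: `"consensus_below"` keeps columns whose consensus frequency is
#' strictly below `threshold` (default 0.90); `"minor_ratio"` keeps columns
#' whose second amino-acid count is at least `threshold` (default 0.10) times
#' the consensus count. All-gap and monomorphic columns are never selected.
#'
#' @param profiles output of [profile_sites()].
#' @param rule selection rule.
#' @param threshold rule threshold (see above); defaults to 0.90 for
#'   `consensus_below` and 0.10 for `minor_ratio`.
#' @return the selected rows of `profiles`.
#' @export
select_sites <- function(profiles, rule = c("consensus_below", "minor_ratio"),
                         threshold = NULL) {
  rule <- match.arg(rule)
  eligible <- !profiles$all_gap & profiles$n_distinct >= 2L
  keep <- if (rule == "consensus_below") {
    if (is.null(threshold)) threshold <- 0.90
    eligible & profiles$consensus_freq < threshold
  } else {
    if (is.null(threshold)) threshold <- 0.10
    eligible & profiles$second_count >= threshold * profiles$consensus_count
  }
  profiles[keep, , drop = FALSE]
}

#' Binary (top-two amino acid) encoding of one site
#'
#' The two most frequent amino acids at the column are coded 0 and 1; ties
#' in frequency are broken alphabetically. State 0 is assigned to the amino
#' acid whose carrier species have the lower median body mass (ties again
#' alphabetical), so the small-mammal residue is always coded 0. Species
#' carrying any other amino acid, or a gap, are excluded.
#'
#' @param alignment a `myo_alignment`.
#' @param column alignment column index.
#' @param metadata species metadata data.frame (ids, `mass_kg`, `clade`).
#' @return object of class `myo_encoding`: `column`, `aa0`, `aa1`, `state`
#'   (named integer vector, NA = excluded), `n0`, `n1`, `excluded` ids.
#' @export
encode_site <- function(alignment, column, metadata) {
  m <- alignment_matrix(alignment)
  if (column < 1L || column > ncol(m)) fail("column out of range")
  col <- m[, column]
  aa <- col[col != GAP]
  tab <- table(aa)
  tab <- tab[order(-tab, names(tab))]
  if (length(tab) < 2L) fail("column ", column, " is monomorphic")
  top2 <- names(tab)[1:2]
  masses <- metadata$mass_kg[match(names(col), metadata$species_id)]
  if (anyNA(masses)) fail("metadata lacks species present in the alignment")
  med <- vapply(top2, function(a) stats::median(masses[col == a]), 0)
  ord <- order(med, top2)  # lower carrier median mass first, alphabetical tie
  aa0 <- top2[ord[1L]]; aa1 <- top2[ord[2L]]
  state <- ifelse(col == aa0, 0L, ifelse(col == aa1, 1L, NA_integer_))
  names(state) <- names(col)
  structure(list(column = column, aa0 = aa0, aa1 = aa1, state = state,
                 n0 = sum(state == 0L, na.rm = TRUE),
                 n1 = sum(state == 1L, na.rm = TRUE),
                 excluded = names(state)[is.na(state)]),
            class = "myo_encoding")
}

# Exact two-sided Mann-Whitney p by enumeration of group assignments.
# Two-sidedness: probability of a rank sum at least as far from its
# null expectation as observed (symmetric-distance definition; identical to
# doubling the smaller tail when the null distribution is symmetric).
mw_exact_p <- function(mass0, mass1) {
  n0 <- length(mass0); n1 <- length(mass1); n <- n0 + n1
  r <- rank(c(mass0, mass1))
  small <- if (n1 <= n0) seq.int(n0 + 1L, n) else seq_len(n0)
  k <- length(small)
  w_obs <- sum(r[small])
  cmb <- utils::combn(n, k)
  w_all <- colSums(matrix(r[cmb], nrow = k))
  e <- k * (n + 1) / 2
  mean(abs(w_all - e) >= abs(w_obs - e) - 1e-9)
}

# Normal approximation with tie correction and continuity correction.
mw_approx_p <- function(mass0, mass1) {
  n0 <- length(mass0); n1 <- length(mass1); n <- n0 + n1
  r <- rank(c(mass0, mass1))
  u <- sum(r[seq_len(n0)]) - n0 * (n0 + 1) / 2
  mu <- n0 * n1 / 2
  ties <- table(c(mass0, mass1))
  sigma2 <- n0 * n1 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Mass association of a binary-encoded site (Mann-Whitney U)
#'
#' Compares body masses between the species carrying the two amino-acid
#' states. The p-value is exact (full enumeration of group assignments) for
#' small problems (`n0 + n1 <= 12` or `min(n0, n1) <= 3`) and otherwise uses
#' the normal approximation with tie and continuity corrections.
#'
#' @param encoding a `myo_encoding` (from [encode_site()]).
#' @param metadata species metadata with `mass_kg`.
#' @return list with `p` (two-sided), `method` ("exact" or "normal"),
#'   `n0`, `n1`.
#' @export
mass_association <- function(encoding, metadata) {
  st <- encoding$state[!is.na(encoding$state)]
  masses <- metadata$mass_kg[match(names(st), metadata$species_id)]
  m0 <- masses[st == 0L]; m1 <- masses[st == 1L]
  if (!length(m0) || !length(m1))
    fail("all included species carry one amino acid: no mass comparison")
  exact <- (length(m0) + length(m1) <= 12L) || min(length(m0), length(m1)) <= 3L
  p <- if (exact) mw_exact_p(m0, m1) else mw_approx_p(m0, m1)
  list(p = p, method = if (exact) "exact" else "normal",
       n0 = length(m0), n1 = length(m1))
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Hypergeometric tail summation: with margins fixed, sums the probabilities
#' of all tables whose probability does not exceed that of the observed one.
#'
#' @param tab 2x2 integer matrix.
#' @return two-sided p-value.
#' @export
fisher_exact_p <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L) || any(tab < 0)) fail("need a non-negative 2x2 table")
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); c2 <- sum(tab[, 2L])
  a <- seq.int(max(0L, r1 - c2), min(r1, c1))
  pr <- stats::dhyper(a, c1, c2, r1)
  p_obs <- stats::dhyper(tab[1L, 1L], c1, c2, r1)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Clade association of a binary-encoded site (Fisher exact)
#'
#' Builds the 2x2 table of amino-acid state by clade over the two clades of
#' `clade_pair`; species outside the pair (or excluded at the site) do not
#' enter the table.
#'
#' @param encoding a `myo_encoding`.
#' @param metadata species metadata with `clade`.
#' @param clade_pair character vector of the two clade labels to compare.
#' @return list with `p` (two-sided), `table` (2x2), `clade_pair`.
#' @export
clade_association <- function(encoding, metadata, clade_pair) {
  if (length(clade_pair) != 2L) fail("clade_pair must name exactly 2 clades")
  st <- encoding$state[!is.na(encoding$state)]
  clade <- metadata$clade[match(names(st), metadata$species_id)]
  keep <- clade %in% clade_pair
  st <- st[keep]; clade <- clade[keep]
  for (cl in clade_pair)
    if (!any(clade == cl)) fail("clade '", cl, "' absent among included species")
  tab <- table(factor(st, levels = c(0L, 1L)),
               factor(clade, levels = clade_pair))
  list(p = fisher_exact_p(tab), table = tab, clade_pair = clade_pair)
}

#' Bonferroni-adjusted per-test significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m_tests number of tests in the family (>= 1).
#' @return `alpha / m_tests`.
#' @export
adjusted_threshold <- function(alpha, m_tests) {
  if (alpha <= 0 || alpha >= 1) fail("alpha must lie in (0, 1)")
  if (m_tests < 1) fail("m_tests must be >= 1")
  alpha / m_tests
}

# Penalized (Jeffreys-prior / Firth) logistic log-likelihood for a single
# covariate; used when maximum likelihood diverges under complete separation.
firth_logistic <- function(x, s) {
  xc <- x - mean(x)
  negpll <- function(b) {
    eta <- b[1L] + b[2L] * xc
    p <- stats::plogis(eta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    w <- p * (1 - p)
    det_i <- sum(w) * sum(w * xc^2) - sum(w * xc)^2
    -(sum(s * log(p) + (1 - s) * log(1 - p)) + 0.5 * log(max(det_i, 1e-300)))
  }
  fit <- stats::optim(c(0, 1), negpll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  b <- fit$par
  c(beta0 = b[1L] - b[2L] * mean(x), beta1 = b[2L])
}

#' Logistic transition of a site's amino-acid state with log10 body mass
#'
#' Fits `logit P(state = 1) = beta0 + beta1 * log10(mass_kg)` by maximum
#' likelihood; when complete (or quasi-complete) separation is detected the
#' fit switches to a Jeffreys-prior bias-reduction penalty (Firth), which
#' keeps the estimates finite, and sets a separation flag. The states are
#' oriented so that `beta1 > 0` (the large-mammal residue becomes more
#' probable with mass).
#'
#' @param encoding a `myo_encoding`.
#' @param metadata species metadata with `mass_kg`.
#' @return list: `beta0`, `beta1` (> 0, per log10 kg), `midpoint_log10_mass`
#'   (`-beta0/beta1`: log10 mass where both residues are equally likely),
#'   `transition_range_log10` (log10-mass span of the 10%-90% transition,
#'   `2 log(9) / beta1`), `separation` flag, `method` ("ml" or "firth").
#' @export
fit_transition <- function(encoding, metadata) {
  st <- encoding$state[!is.na(encoding$state)]
  x <- log10(metadata$mass_kg[match(names(st), metadata$species_id)])
  s <- as.numeric(st)
  if (length(unique(s)) < 2L)
    fail("degenerate site: all included species share one state")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(s ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  b <- stats::coef(fit)
  if (separation || any(!is.finite(b)) || abs(b[2L]) > 20) {
    separation <- TRUE
    b <- firth_logistic(x, s)
  }
  beta0 <- unname(b[1L]); beta1 <- unname(b[2L])
  if (beta1 < 0) { beta0 <- -beta0; beta1 <- -beta1 }
  list(beta0 = beta0, beta1 = beta1,
       midpoint_log10_mass = -beta0 / beta1,
       transition_range_log10 = 2 * log(9) / beta1,
       separation = separation,
       method = if (separation) "firth" else "ml")
}

#' Classify a site by its mass and clade association
#'
#' Applies the Bonferroni threshold `alpha / m_tests` to both p-values:
#' `mass_only` when only the mass test clears it, `clade_only` for the
#' mirror case, `both` or `neither` otherwise. Vectorised over sites.
#'
#' @param mass_p,clade_p two-sided p-values.
#' @param m_tests Bonferroni family size.
#' @param alpha family-wise level (default 0.05).
#' @return character vector of classifications.
#' @export
classify_site <- function(mass_p, clade_p, m_tests, alpha = 0.05) {
  thr <- adjusted_threshold(alpha, m_tests)
  ms <- mass_p <= thr
  cs <- clade_p <= thr
  ifelse(ms & !cs, "mass_only",
         ifelse(!ms & cs, "clade_only",
                ifelse(ms & cs, "both", "neither")))
}

#' Default hypervariable surface regions (reference numbering)
#'
#' N-terminus (1-36), Loop 1 (201-215) and Loop 2 (615-637): surface regions
#' with high background variability across the myosin family, where
#' mass-associated changes are less informative.
#'
#' @return data.frame with `name`, `start`, `end`, `role`.
#' @export
default_hypervariable_regions <- function() {
  data.frame(name = c("N-terminus", "Loop 1", "Loop 2"),
             start = c(1L, 201L, 615L), end = c(36L, 215L, 637L),
             role = "hypervariable", stringsAsFactors = FALSE)
}

#' Flag sites lying in hypervariable regions
#'
#' @param residues reference residue numbers (NA for alignment-only columns,
#'   which are never flagged).
#' @param regions region data.frame; rows with `role == "hypervariable"` are
#'   used (default: [default_hypervariable_regions()]). Containment is
#'   inclusive at both boundaries.
#' @return logical vector.
#' @export
flag_hypervariable <- function(residues, regions = default_hypervariable_regions()) {
  hv <- regions[regions$role == "hypervariable", , drop = FALSE]
  vapply(residues, function(r) {
    if (is.na(r)) return(FALSE)
    any(r >= hv$start & r <= hv$end)
  }, TRUE)
}

parse_substitution <- function(s) {
  m <- regmatches(s, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", s))[[1L]]
  if (length(m) != 4L) return(list(from = NA, residue = NA_integer_, to = NA))
  list(from = toupper(m[2L]), residue = as.integer(m[3L]), to = toupper(m[4L]))
}

#' Overlap between detected sites and an annotation table
#'
#' Reports position-level overlaps (same reference residue) and exact
#' substitution matches (same residue AND same replacement amino acid).
#'
#' @param sites data.frame with column `residue` and optionally `aa_to`
#'   (replacement amino acid observed across species).
#' @param annotations data.frame with `residue`, `category` and optionally
#'   `substitution` strings like "E44D".
#' @return list: `n_position`, `n_exact`, and a `matches` data.frame.
#' @export
overlap_annotations <- function(sites, annotations) {
  ann_to <- rep(NA_character_, nrow(annotations))
  if ("substitution" %in% names(annotations))
    ann_to <- vapply(annotations$substitution,
                     function(s) as.character(parse_substitution(s)$to), "")
  hit <- match(sites$residue, annotations$residue)
  pos <- !is.na(hit)
  exact <- pos & "aa_to" %in% names(sites) &
    !is.na(ann_to[hit]) & !is.na(sites$aa_to) & sites$aa_to == ann_to[hit]
  matches <- data.frame(
    residue = sites$residue[pos],
    category = annotations$category[hit[pos]],
    exact = exact[pos],
    stringsAsFactors = FALSE
  )
  list(n_position = sum(pos), n_exact = sum(exact), matches = matches)
}

#' Full site scan of an alignment
#'
#' Profiles every column, selects variable sites, encodes each as its two
#' most frequent amino acids, runs the mass (Mann-Whitney) and clade (Fisher
#' exact) tests with a Bonferroni family equal to the number of sites tested,
#' fits the logistic transition with log10 mass, and classifies every site.
#'
#' @param alignment a `myo_alignment`.
#' @param metadata species metadata data.frame.
#' @param rule,threshold site-selection rule (see [select_sites()]).
#' @param clade_pair the two clades for the Fisher test; defaults to the two
#'   most frequent clades among aligned species. Species of other clades are
#'   excluded from the 2x2 table but kept in the mass test.
#' @param alpha family-wise levels to flag (default 0.05 and 0.01).
#' @param regions region table for hypervariable flagging.
#' @param offset residue number of the reference's first column.
#' @return data.frame with one row per tested site carrying the encoding,
#'   test, transition and classification fields; attribute `m_tests`.
#' @export
scan_alignment <- function(alignment, metadata,
                           rule = "consensus_below", threshold = NULL,
                           clade_pair = NULL, alpha = c(0.05, 0.01),
                           regions = default_hypervariable_regions(),
                           offset = 1L) {
  colmap <- map_reference_coordinates(alignment, offset = offset)
  prof <- profile_sites(alignment, colmap)
  sel <- select_sites(prof, rule = rule, threshold = threshold)
  if (!nrow(sel)) {
    warning("no variable sites selected", call. = FALSE)
    return(structure(data.frame(), m_tests = 0L))
  }
  if (is.null(clade_pair)) {
    sp <- names(alignment$records)
    tab <- sort(table(metadata$clade[metadata$species_id %in% sp]),
                decreasing = TRUE)
    if (length(tab) < 2L) fail("need at least two clades for the clade test")
    clade_pair <- names(tab)[1:2]
  }
  m_tests <- nrow(sel)
  rows <- lapply(sel$column, function(k) {
    enc <- encode_site(alignment, k, metadata)
    mw <- mass_association(enc, metadata)
    # a clade can be entirely excluded by the top-two encoding; such a site
    # is untestable for clade association (clade_p = NA, classification NA)
    fe <- tryCatch(clade_association(enc, metadata, clade_pair),
                   error = function(e) list(p = NA_real_))
    tr <- tryCatch(fit_transition(enc, metadata),
                   error = function(e) list(beta0 = NA_real_, beta1 = NA_real_,
                                            midpoint_log10_mass = NA_real_,
                                            transition_range_log10 = NA_real_,
                                            separation = NA, method = NA_character_))
    data.frame(column = k, aa0 = enc$aa0, aa1 = enc$aa1,
               n0 = enc$n0, n1 = enc$n1,
               n_excluded = length(enc$excluded),
               mass_p = mw$p, mass_method = mw$method, clade_p = fe$p,
               beta0 = tr$beta0, beta1 = tr$beta1,
               midpoint_log10_mass = tr$midpoint_log10_mass,
               transition_range_log10 = tr$transition_range_log10,
               separation = tr$separation, transition_method = tr$method,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- cbind(sel[, c("label", "ref_number")], res)
  res$m_tests <- m_tests
  for (a in alpha) {
    thr <- adjusted_threshold(a, m_tests)
    res[[sprintf("mass_significant_%gpct", a * 100)]] <- res$mass_p <= thr
    res[[sprintf("clade_significant_%gpct", a * 100)]] <- res$clade_p <= thr
  }
  res$classification <- classify_site(res$mass_p, res$clade_p, m_tests,
                                      alpha = max(alpha))
  res$hypervariable <- flag_hypervariable(res$ref_number, regions)
  rownames(res) <- NULL
  structure(res, m_tests = m_tests, clade_pair = clade_pair)
}
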