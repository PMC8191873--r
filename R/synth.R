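# Synthetic study generator: clade-structured trees, body masses spanning
# ~6 orders of magnitude, and mostly-invariant protein alignments with
# planted site classes (conserved, neutral drift, clade markers, logistic
# mass-threshold sites), plus recovery scoring against the planted truth.
# Defaults echo the motivating study: 67 species (32 + 30 in two major
# clades plus 5 minor-clade species), 800 columns of which 632 are
# conserved, masses 6 g to 10,000 kg.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Configuration for the synthetic study generator
#'
#' @param n_species named integer vector: species per clade; the first two
#'   entries are the major clades (used for the clade-marker basal split and
#'   the default Fisher clade pair).
#' @param log10_mass_bounds length-2 numeric: log10(kg) bounds applied to
#'   every clade (default 6 g to 10,000 kg). Under `confounded = TRUE` the
#'   first major clade is capped at 140 kg while the second spans the full
#'   range, so the very largest species fall in one clade only.
#' @param alignment_length total columns.
#' @param n_conserved,n_drift,n_clade,n_mass site-class counts; must sum to
#'   `alignment_length`.
#' @param mass_midpoints log10(kg) transition midpoints of the mass sites
#'   (default evenly spaced in \[-1.5, 3\]).
#' @param steepness logistic steepness per log10(kg) (default 10: steep).
#' @param epsilon state-flip noise for clade and mass sites, in \[0, 0.5).
#' @param drift_rate expected substitutions per unit branch length at drift
#'   sites. The default 0.05 gives under one substitution per column on a
#'   height-1 tree of ~67 tips (total branch length ~13), so most drift
#'   columns stay nearly invariant, like the highly conserved minority of
#'   real columns, while a few dozen cross the 90%-consensus line.
#' @param confounded see `log10_mass_bounds`.
#' @param seed master RNG seed.
#' @return validated list of class `myo_simconfig`.
#' @export
sim_config <- function(n_species = c(Euarchontoglires = 32L, Laurasiatheria = 30L,
                                     Metatheria = 4L, Afrotheria = 1L),
                       log10_mass_bounds = c(log10(0.006), 4),
                       alignment_length = 800L,
                       n_conserved = 632L, n_drift = 144L,
                       n_clade = 12L, n_mass = 12L,
                       mass_midpoints = NULL, steepness = 10,
                       epsilon = 0.05, drift_rate = 0.05,
                       confounded = FALSE, seed = 1L) {
  if (n_conserved + n_drift + n_clade + n_mass != alignment_length)
    fail("site-class counts must sum to alignment_length")
  if (epsilon < 0 || epsilon >= 0.5) fail("epsilon must lie in [0, 0.5)")
  if (log10_mass_bounds[1L] >= log10_mass_bounds[2L])
    fail("log10_mass_bounds must be ordered")
  if (is.null(names(n_species)) || length(n_species) < 2L)
    fail("n_species must be named, with at least two clades")
  if (any(n_species[1:2] < 2L)) fail("major clades need >= 2 species")
  if (is.null(mass_midpoints))
    mass_midpoints <- seq(-1.5, 3, length.out = max(n_mass, 1L))
  if (length(mass_midpoints) != n_mass)
    fail("need one midpoint per mass site")
  structure(list(n_species = n_species, log10_mass_bounds = log10_mass_bounds,
                 alignment_length = alignment_length, n_conserved = n_conserved,
                 n_drift = n_drift, n_clade = n_clade, n_mass = n_mass,
                 mass_midpoints = mass_midpoints, steepness = steepness,
                 epsilon = epsilon, drift_rate = drift_rate,
                 confounded = confounded, seed = seed),
            class = "myo_simconfig")
}

scale_tree_height <- function(tree, h) {
  cur <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (h / cur)
  tree
}

# subtree newick without a stem branch; a single tip has height 0
clade_subtree_newick <- function(label_prefix, n, height) {
  tips <- sprintf("%s_%02d", label_prefix, seq_len(n))
  if (n == 1L) return(list(nwk = tips, height = 0))
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr <- scale_tree_height(tr, height)
  tr$tip.label <- tips
  list(nwk = sub(";$", "", ape::write.tree(tr)), height = height)
}

# subtree plus the stem branch that brings its tips to depth 1
hang_clade <- function(label_prefix, n, split_depth) {
  sub <- clade_subtree_newick(label_prefix, n,
                              height = max(1 - split_depth - 0.1, 0.05))
  stem <- 1 - split_depth - sub$height
  paste0(sub$nwk, ":", format(stem, digits = 12))
}

#' Simulate a clade-structured ultrametric species tree
#'
#' Each clade is an independent pure-birth subtree; clades are grafted at
#' nested basal splits (major pair deepest inside, minor clades outward) and
#' the whole tree is scaled to height 1.
#'
#' @param config a `myo_simconfig`.
#' @param seed RNG seed (default: the config's master seed).
#' @return rooted ultrametric `phylo`; tip labels are prefixed by clade and
#'   the tip-to-clade map is in `attr(tree, "clade_of_tip")`.
#' @export
simulate_tree <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_species[config$n_species > 0L]
  clades <- names(n)
  pre <- substr(clades, 1L, 3L)
  if (anyDuplicated(pre)) pre <- make.unique(pre, sep = "")
  # depths of the nested clade splits (tips at depth 1)
  k_minor <- length(n) - 2L
  split_depths <- if (k_minor > 0L) seq(0, 0.3, length.out = k_minor + 1L) else 0
  major_depth <- split_depths[length(split_depths)]
  nwk <- paste0(
    "(", hang_clade(pre[1L], n[1L], major_depth), ",",
    hang_clade(pre[2L], n[2L], major_depth), ")")
  depth_now <- major_depth
  if (k_minor > 0L) {
    for (i in seq_len(k_minor)) {
      d <- split_depths[length(split_depths) - i]
      nwk <- paste0("(", nwk, ":", format(depth_now - d, digits = 12), ",",
                    hang_clade(pre[2L + i], n[2L + i], d), ")")
      depth_now <- d
    }
  }
  tree <- ape::read.tree(text = paste0(nwk, ";"))
  clade_of_tip <- stats::setNames(
    clades[match(sub("_[0-9]+$", "", tree$tip.label), pre)], tree$tip.label)
  attr(tree, "clade_of_tip") <- clade_of_tip
  tree
}

#' Simulate species body masses
#'
#' `"uniform"` mode draws log10 mass independently and uniformly within the
#' configured bounds (per clade); `"brownian"` mode evolves log10 mass as
#' Brownian motion on the tree (for contrasts testing) and then maps it
#' affinely onto the bounds.
#'
#' @param tree output of [simulate_tree()].
#' @param config a `myo_simconfig`.
#' @param mode "uniform" or "brownian".
#' @param seed RNG seed.
#' @return metadata data.frame: `species_id`, `display_name`, `mass_kg`,
#'   `clade`.
#' @export
simulate_masses <- function(tree, config, mode = c("uniform", "brownian"),
                            seed = config$seed + 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  clade <- attr(tree, "clade_of_tip")[tree$tip.label]
  b <- config$log10_mass_bounds
  if (mode == "uniform") {
    lo <- rep(b[1L], length(clade)); hi <- rep(b[2L], length(clade))
    if (config$confounded) {
      major <- names(config$n_species)[1:2]
      hi[clade == major[1L]] <- min(b[2L], log10(140))
    }
    logm <- stats::runif(length(clade), lo, hi)
  } else {
    v <- ape::vcv(tree)
    z <- drop(t(chol(v)) %*% stats::rnorm(nrow(v)))
    names(z) <- rownames(v)
    z <- z[tree$tip.label]
    logm <- if (diff(range(z)) > 0)
      b[1L] + (z - min(z)) / diff(range(z)) * diff(b) else rep(mean(b), length(z))
  }
  data.frame(species_id = tree$tip.label, display_name = tree$tip.label,
             mass_kg = 10^logm, clade = unname(clade),
             stringsAsFactors = FALSE)
}

# drift column: substitutions placed by a Poisson process on branches
drift_column <- function(tree, rate) {
  root_aa <- sample(AA20, 1L)
  nnode <- length(tree$tip.label) + tree$Nnode
  aa <- rep(root_aa, nnode)
  edges <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]  # preorder-ish
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]; ch <- edges[e, 2L]
    len <- tree$edge.length[which(tree$edge[, 1L] == par &
                                    tree$edge[, 2L] == ch)]
    aa[ch] <- if (stats::rpois(1L, rate * len) > 0L) sample(AA20, 1L) else aa[par]
  }
  aa[seq_along(tree$tip.label)]
}

#' Simulate an alignment with planted site classes
#'
#' Conserved columns carry a single amino acid. Drift columns accumulate
#' neutral substitutions along the tree. Clade-marker columns carry one
#' amino acid in the first major clade and another elsewhere, flipped with
#' probability epsilon. Mass-threshold columns assign the large-mammal amino
#' acid with probability `plogis(steepness * (log10 mass - midpoint))`, then
#' flip with probability epsilon; they are generated independently of the
#' tree (pure mass-threshold model), so mass sites carry no clade signal by
#' construction.
#'
#' @param tree output of [simulate_tree()].
#' @param metadata output of [simulate_masses()].
#' @param config a `myo_simconfig`.
#' @param seed RNG seed.
#' @param reference_id identity/numbering reference species (default: the
#'   smallest-mass species, the natural mouse-like reference).
#' @return list: `alignment` (a `myo_alignment`), `truth` (data.frame:
#'   `column`, `class`, `aa0`, `aa1`, `midpoint`, `steepness`).
#' @export
simulate_alignment <- function(tree, metadata, config,
                               seed = config$seed + 2L, reference_id = NULL) {
  if (!setequal(tree$tip.label, metadata$species_id))
    fail("tree tips and metadata species differ")
  set.seed(seed)
  sp <- tree$tip.label
  n <- length(sp)
  L <- config$alignment_length
  classes <- sample(rep(c("conserved", "drift", "clade_marker", "mass_threshold"),
                        c(config$n_conserved, config$n_drift,
                          config$n_clade, config$n_mass)))
  truth <- data.frame(column = seq_len(L), class = classes,
                      aa0 = NA_character_, aa1 = NA_character_,
                      midpoint = NA_real_, steepness = NA_real_,
                      stringsAsFactors = FALSE)
  m <- matrix("", n, L, dimnames = list(sp, NULL))
  clade <- metadata$clade[match(sp, metadata$species_id)]
  logm <- log10(metadata$mass_kg[match(sp, metadata$species_id)])
  major1 <- names(config$n_species)[1L]
  mass_cols <- which(classes == "mass_threshold")
  midpoint_of <- stats::setNames(config$mass_midpoints, mass_cols)
  for (k in seq_len(L)) {
    cl <- classes[k]
    if (cl == "conserved") {
      aa <- sample(AA20, 1L)
      m[, k] <- aa
      truth$aa0[k] <- aa
    } else if (cl == "drift") {
      m[, k] <- drift_column(tree, config$drift_rate)
    } else {
      pair <- sample(AA20, 2L)
      state <- if (cl == "clade_marker") as.integer(clade != major1)
      else stats::rbinom(n, 1L, stats::plogis(
        config$steepness * (logm - midpoint_of[[as.character(k)]])))
      flip <- stats::runif(n) < config$epsilon
      state[flip] <- 1L - state[flip]
      m[, k] <- pair[state + 1L]
      truth$aa0[k] <- pair[1L]; truth$aa1[k] <- pair[2L]
      if (cl == "mass_threshold") {
        truth$midpoint[k] <- midpoint_of[[as.character(k)]]
        truth$steepness[k] <- config$steepness
      }
    }
  }
  if (is.null(reference_id))
    reference_id <- metadata$species_id[which.min(metadata$mass_kg)]
  seqs <- apply(m, 1L, paste, collapse = "")
  list(alignment = new_alignment(seqs, reference_id), truth = truth)
}

#' Score site-scan calls against the planted truth
#'
#' @param site_results output of [scan_alignment()].
#' @param truth truth data.frame from [simulate_alignment()].
#' @return list: `n_planted`, `n_called` (mass_only calls), `tp`,
#'   `false_positives` (columns), `sensitivity`, `precision` (NA when
#'   nothing was called), `midpoint_abs_err` (log10 units, per recovered
#'   planted site).
#' @export
evaluate_recovery <- function(site_results, truth) {
  planted <- truth$column[truth$class == "mass_threshold"]
  called <- if (nrow(site_results)) {
    site_results$column[which(site_results$classification == "mass_only")]
  } else integer()
  tp <- intersect(called, planted)
  fp <- setdiff(called, planted)
  err <- if (length(tp)) {
    est <- site_results$midpoint_log10_mass[match(tp, site_results$column)]
    abs(est - truth$midpoint[match(tp, truth$column)])
  } else numeric()
  list(n_planted = length(planted), n_called = length(called),
       tp = length(tp), false_positives = fp,
       sensitivity = if (length(planted)) length(tp) / length(planted) else NA_real_,
       precision = if (length(called)) length(tp) / length(called) else NA_real_,
       midpoint_abs_err = err)
}
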