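# Felsenstein's phylogenetically independent contrasts, implemented from the
# three defining rules (standardized tip-pair differences, variance-weighted
# ancestral values, parent-branch extension v_i*v_j/(v_i+v_j)), plus the
# contrasts-based correlation test between two tip traits. ape supplies tree
# input and bookkeeping only; the contrasts arithmetic is computed here.

#' Read and validate a rooted newick tree
#'
#' @param path newick file.
#' @param outgroup optional tip label used to root an unrooted input.
#' @return an `ape::phylo` tree, rooted and binary. Polytomies are resolved
#'   arbitrarily with zero-length branches (with a warning); unrooted input
#'   without an `outgroup` is an error, as are duplicate tips or missing
#'   branch lengths.
#' @export
read_newick <- function(path, outgroup = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) fail("could not parse newick in '", path, "'")
  if (anyDuplicated(tree$tip.label))
    fail("duplicate tip label: ",
         tree$tip.label[duplicated(tree$tip.label)][1L])
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    fail("tree lacks branch lengths")
  if (!ape::is.binary(tree)) {
    warning("polytomies resolved arbitrarily with zero-length branches",
            call. = FALSE)
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup)) fail("tree is unrooted; supply an outgroup")
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  }
  tree
}

#' Phylogenetically independent contrasts of one trait
#'
#' Post-order traversal: at each internal node with children i, j carrying
#' values x_i, x_j on (extended) branches v_i, v_j, the standardized
#' contrast is `(x_i - x_j) / sqrt(v_i + v_j)`, the ancestral value is the
#' variance-weighted mean, and the parent branch is extended by
#' `v_i v_j / (v_i + v_j)`. Children are ordered by their smallest
#' descendant tip label, so the contrast signs are deterministic.
#'
#' @param tree rooted binary `phylo` with branch lengths (polytomies are
#'   resolved as in [read_newick()]).
#' @param tip_values numeric vector named by tip label, one value per tip.
#' @param eps_frac zero-length branches entering a division are replaced by
#'   `eps_frac * tree height` (with a warning).
#' @return data.frame with `node`, `contrast` and `variance`
#'   (`v_i + v_j`), one row per internal node (`tips - 1` rows).
#' @export
contrasts <- function(tree, tip_values, eps_frac = 1e-8) {
  if (!inherits(tree, "phylo")) fail("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) fail("tree lacks branch lengths")
  if (!ape::is.binary(tree)) {
    warning("polytomies resolved arbitrarily with zero-length branches",
            call. = FALSE)
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (!ape::is.rooted(tree)) fail("tree must be rooted")
  ntip <- length(tree$tip.label)
  miss <- setdiff(tree$tip.label, names(tip_values))
  if (length(miss)) fail("missing tip value(s): ", paste(miss, collapse = ", "))
  height <- max(ape::node.depth.edgelength(tree))
  eps <- eps_frac * max(height, .Machine$double.eps)
  nnode <- ntip + tree$Nnode
  val <- numeric(nnode)
  val[seq_len(ntip)] <- as.numeric(tip_values[tree$tip.label])
  vext <- numeric(nnode)                      # accumulated branch extension
  blen <- numeric(nnode)
  blen[tree$edge[, 2L]] <- tree$edge.length
  kids <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1L]]] <- c(kids[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  mintip <- character(nnode)
  mintip[seq_len(ntip)] <- tree$tip.label
  inner <- unique(tree$edge[ape::postorder(tree), 1L])
  warned <- FALSE
  out <- matrix(0, length(inner), 3L,
                dimnames = list(NULL, c("node", "contrast", "variance")))
  for (k in seq_along(inner)) {
    nd <- inner[k]
    ch <- kids[[nd]]
    ch <- ch[order(mintip[ch])]
    mintip[nd] <- mintip[ch[1L]]
    v <- blen[ch] + vext[ch]
    if (any(v <= 0)) {
      if (!warned) {
        warning("zero-length branch in a contrast; using epsilon ", eps,
                call. = FALSE)
        warned <- TRUE
      }
      v <- pmax(v, eps)
    }
    out[k, ] <- c(nd, (val[ch[1L]] - val[ch[2L]]) / sqrt(sum(v)), sum(v))
    w <- 1 / v
    val[nd] <- sum(w * val[ch]) / sum(w)
    vext[nd] <- prod(v) / sum(v)
  }
  as.data.frame(out)
}

#' Contrasts-based correlation between two tip traits
#'
#' Computes independent contrasts of both traits on the same tree and
#' regresses the y-contrasts on the x-contrasts through the origin (the
#' standard PIC regression: contrasts have expectation zero). `r` is the
#' through-origin correlation and the p-value comes from its t statistic on
#' `tips - 2` degrees of freedom.
#'
#' @param tree rooted binary `phylo` with branch lengths.
#' @param x_values,y_values numeric vectors named by tip label.
#' @inheritParams contrasts
#' @return list: `slope`, `r`, `t`, `df`, `p`, `n_contrasts`.
#' @export
pic_correlation <- function(tree, x_values, y_values, eps_frac = 1e-8) {
  ntip <- length(tree$tip.label)
  if (ntip < 3L) fail("need at least 3 tips")
  cx <- contrasts(tree, x_values, eps_frac)$contrast
  cy <- contrasts(tree, y_values, eps_frac)$contrast
  sxx <- sum(cx^2); sxy <- sum(cx * cy); syy <- sum(cy^2)
  if (sxx == 0) fail("x contrasts are all zero")
  slope <- sxy / sxx
  r <- sxy / sqrt(sxx * syy)
  df <- ntip - 2L
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(slope = slope, r = r, t = tstat, df = df,
       p = 2 * stats::pt(-abs(tstat), df), n_contrasts = length(cx))
}
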