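# Independent oracles used to cross-check the package implementations.

# LAD regression as a linear program (via boot::simplex):
# minimise sum(u_i + v_i) s.t. y_i = b0 + b1 x_i + u_i - v_i, u, v >= 0,
# with the free coefficients split into positive parts.
lad_lp <- function(x, y) {
  n <- length(x)
  A3 <- cbind(1, x, -1, -x, diag(n), -diag(n))
  r <- boot::simplex(a = c(0, 0, 0, 0, rep(1, 2 * n)),
                     A3 = A3, b3 = y, maxi = FALSE)
  c(intercept = unname(r$soln[1] - r$soln[3]),
    slope = unname(r$soln[2] - r$soln[4]),
    objective = unname(r$value))
}

# Exact two-sided Mann-Whitney by enumeration of group assignments, computing
# the U statistic directly from pairwise mass comparisons (a different route
# than the rank-sum used by the implementation).
mw_brute_p <- function(m0, m1) {
  vals <- c(m0, m1)
  n <- length(vals); n1 <- length(m1)
  u_of <- function(g1) {
    a <- vals[setdiff(seq_len(n), g1)]
    b <- vals[g1]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq.int(length(m0) + 1L, n))
  cmb <- utils::combn(n, n1)
  u_all <- apply(cmb, 2L, u_of)
  e <- length(m0) * n1 / 2
  mean(abs(u_all - e) >= abs(u_obs - e) - 1e-9)
}

# Two-sided Fisher exact by explicit enumeration over the free cell, with
# table probabilities computed from binomial coefficients.
fisher_brute_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); ntot <- sum(tab)
  a_range <- max(0, r1 - (ntot - c1)):min(r1, c1)
  pr <- vapply(a_range, function(a)
    choose(c1, a) * choose(ntot - c1, r1 - a) / choose(ntot, r1), 0)
  p_obs <- pr[a_range == tab[1, 1]]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Grid-search maximiser of the Jeffreys-penalized logistic likelihood.
firth_grid <- function(x, s, b0 = seq(-6, 6, 0.01), b1 = seq(0.05, 25, 0.05)) {
  pll <- function(a, b) {
    p <- stats::plogis(a + b * x)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    w <- p * (1 - p)
    sum(s * log(p) + (1 - s) * log(1 - p)) +
      0.5 * log(sum(w) * sum(w * x^2) - sum(w * x)^2)
  }
  g <- expand.grid(b0 = b0, b1 = b1)
  v <- mapply(pll, g$b0, g$b1)
  i <- which.max(v)
  c(beta0 = g$b0[i], beta1 = g$b1[i])
}

# small deterministic alignment builder
aln_from <- function(..., .ref) {
  new_alignment(c(...), reference_id = .ref)
}
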