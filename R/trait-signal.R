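# Phylogenetic clustering of a binary trait via the D statistic: the sum of
# sister-clade disparities, rescaled between two null expectations so that
# D = 1 matches random label shuffles and D = 0 matches a Brownian-threshold
# (phylogenetically clumped) trait of the same prevalence. Values outside
# [0, 1] are possible and are not clamped.

# coerce/validate a trait vector against a tree's tips; returns named 0/1
check_trait <- function(phy, trait, require_polymorphic = TRUE) {
  labs <- phy$tip.label
  if (is.null(names(trait))) {
    if (length(trait) != length(labs)) {
      stop("unnamed trait vector must have one entry per tip")
    }
    names(trait) <- labs
  }
  missing <- setdiff(labs, names(trait))
  if (length(missing) > 0L) {
    stop("trait is missing tips: ", paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (and %d more)", length(missing) - 5L))
  }
  trait <- trait[labs]
  if (!all(trait %in% c(0, 1))) stop("trait states must be 0/1")
  trait <- as.numeric(trait)
  names(trait) <- labs
  if (require_polymorphic && (sum(trait) == 0 || sum(trait) == length(trait))) {
    stop("D undefined: trait is monomorphic on this tip set")
  }
  trait
}

# Vectorized sister-clade disparity sums: X is an ntip x r matrix of 0/1
# columns; nodal values are daughter means computed bottom-up; returns the r
# disparity sums. Topology-only (branch lengths never enter).
disparity_sums <- function(st, X) {
  if (!st$binary) stop("sister-clade disparities require a binary tree")
  r <- ncol(X)
  V <- matrix(0, st$N, r)
  V[seq_len(st$ntip), ] <- X
  d <- numeric(r)
  for (v in st$postorder) {
    k <- st$children[[v]]
    a <- V[k[1L], ]
    b <- V[k[2L], ]
    d <- d + abs(a - b)
    V[v, ] <- (a + b) / 2
  }
  d
}

#' Sum of sister-clade disparities for a binary trait
#'
#' Nodal values are estimated bottom-up as the mean of the two daughter
#' values (tips carry their 0/1 state); the statistic is the sum over
#' internal nodes of the absolute difference between the two daughter values.
#' Small values indicate phylogenetic clumping. Branch lengths never enter.
#'
#' @param phy A binary `phylo`.
#' @param trait Named 0/1 vector over the tips (names = tip labels), or an
#'   unnamed vector in tip order.
#' @return The disparity sum (unitless).
#' @export
sister_clade_disparity_sum <- function(phy, trait) {
  st <- tree_struct(phy)
  x <- check_trait(phy, trait)
  disparity_sums(st, matrix(x, ncol = 1L))
}

# Brownian liabilities at the tips: rate 1, root value 0, variance
# proportional to branch length (My). Returns ntip x r matrix.
bm_tip_liabilities <- function(st, r) {
  L <- matrix(0, st$N, r)
  e <- st$edge
  sd_e <- sqrt(pmax(st$phy$edge.length, 0))
  for (i in st$preorder_edges) { # parents before children
    L[e[i, 2L], ] <- L[e[i, 1L], ] + stats::rnorm(r, 0, sd_e[i])
  }
  L[seq_len(st$ntip), , drop = FALSE]
}

#' Simulate a clumped binary trait under the Brownian threshold model
#'
#' A continuous liability evolves by Brownian motion along the tree (rate 1,
#' root value 0, variance proportional to branch length in My); the `n_ones`
#' tips with the largest liabilities receive state 1. Rank thresholding
#' preserves the prevalence exactly, matching the prevalence-conditioned
#' nulls used by [phylo_d()].
#'
#' @param phy An ultrametric `phylo`.
#' @param n_ones Number of tips to set to 1 (`1 <= n_ones <= n - 1`).
#' @param seed Optional integer seed.
#' @return Named 0/1 vector over the tips.
#' @export
simulate_bm_threshold <- function(phy, n_ones, seed = NULL) {
  st <- tree_struct(phy)
  n <- st$ntip
  if (n_ones < 1L || n_ones > n - 1L) {
    stop("n_ones must be between 1 and n - 1")
  }
  with_seed(seed, {
    liab <- bm_tip_liabilities(st, 1L)[, 1L]
    x <- numeric(n)
    x[order(liab, decreasing = TRUE)[seq_len(n_ones)]] <- 1
    names(x) <- st$tip_labels
    x
  })
}

# internal: r BM-threshold 0/1 columns at fixed n_ones
bm_threshold_matrix <- function(st, n_ones, r) {
  liab <- bm_tip_liabilities(st, r)
  X <- matrix(0, st$ntip, r)
  for (j in seq_len(r)) {
    X[order(liab[, j], decreasing = TRUE)[seq_len(n_ones)], j] <- 1
  }
  X
}

#' D statistic for phylogenetic clustering of a binary trait
#'
#' Computes the observed sister-clade disparity sum and rescales it between
#' two prevalence-preserving nulls:
#' `D = (d_obs - mean_d_brownian) / (mean_d_random - mean_d_brownian)`,
#' where the random null shuffles tip labels and the Brownian null draws
#' threshold traits ([simulate_bm_threshold()]) at the same prevalence,
#' `reps` replicates each. `D = 1` is indistinguishable from random, `D = 0`
#' from Brownian clumping; values beyond `[0, 1]` occur and are reported
#' as-is. One-tailed Monte-Carlo p-values use the `(1 + b)/(reps + 1)`
#' convention: `p_random` tests departure from random toward clumping
#' (observed disparity in the lower tail of the shuffle null), `p_brownian`
#' departure from clumped toward random (upper tail of the Brownian null).
#'
#' @param phy A binary ultrametric `phylo`.
#' @param trait Named 0/1 vector over the tips; both states must be present.
#' @param reps Replicates per null (default 1000).
#' @param seed Optional integer seed.
#' @return A list of class `"phylo_d"`: `d_obs`, `mean_d_random`,
#'   `mean_d_brownian`, `D`, `p_random`, `p_brownian`, `ns_vs_random`
#'   (`p_random > 0.01`), `ns_vs_clumped` (`p_brownian > 0.01`),
#'   `prevalence`, `reps`, `seed`.
#' @export
phylo_d <- function(phy, trait, reps = 1000, seed = NULL) {
  if (reps < 1L) stop("reps must be a positive integer")
  st <- tree_struct(phy)
  x <- check_trait(phy, trait)
  n <- st$ntip
  if (n < 4L) stop("D needs at least 4 tips")
  d_obs <- disparity_sums(st, matrix(x, ncol = 1L))
  with_seed(seed, {
    Xs <- vapply(seq_len(reps), function(i) sample(x), numeric(n))
    d_rand <- disparity_sums(st, Xs)
    d_bm <- disparity_sums(st, bm_threshold_matrix(st, sum(x), reps))
    m_rand <- mean(d_rand)
    m_bm <- mean(d_bm)
    if (abs(m_rand - m_bm) < 1e-12) {
      stop("degenerate D denominator: random and Brownian null means coincide")
    }
    p_random <- (1 + sum(d_rand <= d_obs)) / (reps + 1)
    p_brownian <- (1 + sum(d_bm >= d_obs)) / (reps + 1)
    res <- list(d_obs = d_obs,
                mean_d_random = m_rand,
                mean_d_brownian = m_bm,
                D = (d_obs - m_bm) / (m_rand - m_bm),
                p_random = p_random,
                p_brownian = p_brownian,
                ns_vs_random = p_random > 0.01,
                ns_vs_clumped = p_brownian > 0.01,
                prevalence = mean(x),
                reps = reps,
                seed = seed)
    class(res) <- "phylo_d"
    res
  })
}

#' @export
print.phylo_d <- function(x, ...) {
  cat("Phylogenetic signal of a binary trait (D statistic)\n")
  cat(sprintf("  prevalence : %.3f\n", x$prevalence))
  cat(sprintf("  d observed : %.4f (random null mean %.4f, Brownian %.4f)\n",
              x$d_obs, x$mean_d_random, x$mean_d_brownian))
  cat(sprintf("  D          : %.4f  (0 = clumped, 1 = random)\n", x$D))
  cat(sprintf("  P vs random : %.4g%s\n", x$p_random,
              if (x$ns_vs_random) "  (not distinguishable from random)" else ""))
  cat(sprintf("  P vs clumped: %.4g%s\n", x$p_brownian,
              if (x$ns_vs_clumped) "  (not distinguishable from clumped)" else ""))
  invisible(x)
}
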