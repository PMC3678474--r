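# Tree-shape statistics and their Yule-model nulls. The gamma statistic
# summarizes the temporal spread of splits (standard normal under the Yule
# model; positive when divergences concentrate near the present), and the
# Colless index summarizes topological imbalance (0 for a fully balanced
# tree, (n-1)(n-2)/2 for a caterpillar).

#' Lineage-through-time intervals of an ultrametric tree
#'
#' Computes `g[k]`, the duration (My) during which exactly `k` lineages
#' coexist, for `k = 2..n`, from the sorted internal-node ages: the interval
#' with `k` lineages ends when the `k`-th split occurs, and `g[n]` runs from
#' the last split to the present. Ties in node ages (simultaneous splits)
#' yield zero-length intervals, which are legal.
#'
#' @param phy A binary ultrametric `phylo` with `n >= 3` tips.
#' @return A list with `n` (tip count), `g` (named numeric, indices `2..n`),
#'   and `total` = sum over k of `k * g[k]` (total lineage-time, My).
#' @export
lineage_intervals <- function(phy) {
  validate_timetree(phy)
  if (!is_binary_tree(phy)) stop("tree must be binary")
  n <- n_tips(phy)
  if (n < 3L) stop("lineage intervals need at least 3 tips")
  ages <- node_ages(phy)
  internal <- sort(ages[(n + 1L):(n + phy$Nnode)], decreasing = TRUE)
  bounds <- c(internal, 0)            # a_1 (root) >= a_2 >= ... >= a_{n-1} >= 0
  g <- bounds[-length(bounds)] - bounds[-1L]
  names(g) <- as.character(2:n)
  list(n = n, g = g, total = sum((2:n) * g))
}

#' Gamma statistic of tree-shape (Pybus & Harvey)
#'
#' Standard normal under the Yule (pure-birth) model. Negative gamma means
#' edges near the tips are generally longer than those near the root (early
#' splits); positive gamma means divergences concentrate near the present.
#' Invariant under rescaling all ages by a positive constant.
#'
#' @param phy A binary ultrametric `phylo`, `n >= 3`.
#' @return The gamma value (unitless).
#' @export
gamma_statistic <- function(phy) {
  li <- lineage_intervals(phy)
  n <- li$n
  g <- li$g
  total <- li$total
  cum <- cumsum((2:n) * g)       # cum[i-1] = sum_{k=2}^{i} k g[k]
  inner <- mean(cum[seq_len(n - 2L)])   # i = 2 .. n-1
  (inner - total / 2) / (total * sqrt(1 / (12 * (n - 2))))
}

#' Colless imbalance index
#'
#' Sum over internal nodes of the absolute difference in descendant-tip
#' counts between the node's two daughter clades. Topology-only: ignores
#' branch lengths and child order.
#'
#' @param phy A binary `phylo`.
#' @return Non-negative integer.
#' @export
colless_index <- function(phy) {
  st <- tree_struct(phy)
  if (!st$binary) stop("Colless index requires a binary tree")
  cnt <- integer(st$N)
  cnt[seq_len(st$ntip)] <- 1L
  total <- 0L
  for (v in st$postorder) {
    k <- st$children[[v]]
    total <- total + abs(cnt[k[1L]] - cnt[k[2L]])
    cnt[v] <- cnt[k[1L]] + cnt[k[2L]]
  }
  total
}

#' Simulate a Yule (pure-birth) tree conditioned on n tips
#'
#' Starts with 2 lineages at the root; while `k` lineages exist, waits an
#' Exponential(rate = k) time (unit speciation rate) and splits a uniformly
#' chosen lineage, until `n` lineages exist; a final Exponential(n) interval
#' separates the last split from the present, so the complete internode
#' vector `g[2..n]` has the independent-exponential law under which gamma is
#' asymptotically standard normal. Tips sit at age 0.
#'
#' @param n Number of tips (`>= 2`).
#' @param seed Optional integer seed (deterministic output given it).
#' @return An ultrametric binary `phylo` with tips `t1..tn`.
#' @export
simulate_yule <- function(n, seed = NULL) {
  stopifnot(n >= 2L)
  with_seed(seed, {
    top <- yule_topology(n, kappa = 1)
    ages <- yule_node_ages(n, top$order, root_age = NULL, age_power = 1)
    build_phylo(top$children, ages$ages, top$tip_labels, root = 1L)
  })
}

# Shared topology machinery for the Yule simulator and the biased generator.
# kappa > 1 biases the choice of splitting tip toward deep tips: tip i gets
# weight kappa^(r_i/m), where r_i is the rank of its depth among the m active
# tips. The exponent is bounded in (0, 1], so kappa is a mild, interpretable
# dial (the deepest tip is at most kappa times as likely to speciate as the
# shallowest) rather than a degenerate caterpillar switch.
# Returns children lists (ids), the internal-node creation order, and labels.
yule_topology <- function(n, kappa = 1) {
  N <- 2L * n - 1L
  children <- vector("list", N)
  for (i in seq_len(N)) children[[i]] <- integer(0)
  depth <- integer(N)
  children[[1L]] <- c(2L, 3L)
  depth[2L] <- 1L; depth[3L] <- 1L
  active <- c(2L, 3L)
  order <- integer(n - 1L)
  order[1L] <- 1L
  nextid <- 4L
  if (n > 2L) {
    for (s in 2:(n - 1L)) {
      if (kappa == 1) {
        i <- active[sample.int(length(active), 1L)]
      } else {
        r <- rank(depth[active], ties.method = "average") / length(active)
        i <- active[sample.int(length(active), 1L, prob = kappa^r)]
      }
      a <- nextid; b <- nextid + 1L; nextid <- nextid + 2L
      children[[i]] <- c(a, b)
      depth[a] <- depth[i] + 1L
      depth[b] <- depth[i] + 1L
      order[s] <- i
      active <- c(active[active != i], a, b)
    }
  }
  tips <- which(lengths(children) == 0L)
  labels <- character(N)
  labels[tips] <- paste0("t", seq_along(tips))
  list(children = children, order = order, tip_labels = labels,
       tips = tips, depth = depth)
}

# Draw Yule waiting times for a topology's split order and turn them into
# node ages. If root_age is given, split times are rescaled so the root sits
# at exactly that age; age_power > 1 then pushes internal ages toward the
# present via a -> A * (a/A)^beta (monotone, fixes root and present).
yule_node_ages <- function(n, order, root_age = NULL, age_power = 1) {
  waits <- stats::rexp(n - 1L, rate = 2:n)    # g[2], ..., g[n]
  split_times <- c(0, cumsum(waits[-(n - 1L)])) # time of split s from root
  total <- sum(waits)
  N <- 2L * n - 1L
  ages <- numeric(N)                          # tips at 0
  rel <- (total - split_times) / total        # in (0, 1], root = 1
  A <- if (is.null(root_age)) total else root_age
  ages[order] <- A * rel^age_power
  list(ages = ages, root_age = A)
}

# Colless index of a random Yule topology, drawn without building the tree:
# under the Yule model the left-clade size of an n-clade root is uniform on
# 1..n-1 and the two daughter clades are independent Yule trees.
r_colless_yule <- function(n) {
  total <- 0
  stack <- n
  while (length(stack) > 0L) {
    m <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (m >= 2L) {
      a <- sample.int(m - 1L, 1L)
      total <- total + abs(m - 2L * a)
      if (a > 1L) stack <- c(stack, a)
      if (m - a > 1L) stack <- c(stack, m - a)
    }
  }
  total
}

#' Test tree imbalance against the Yule null
#'
#' Compares the observed Colless index with its distribution over `reps`
#' random Yule topologies of the same tip count (Colless ignores ages, so the
#' null need not be rescaled to the observed root age). The one-tailed upper
#' p-value uses the `(1 + b) / (reps + 1)` Monte-Carlo convention and never
#' returns 0.
#'
#' @param phy A binary `phylo`, `n >= 4`.
#' @param reps Number of Yule null trees (default 1000).
#' @param seed Optional integer seed.
#' @return A list of class `"shape_stats"`: `n`, `gamma`, `colless`,
#'   `colless_p`, `yule_reps`, `seed`.
#' @export
colless_yule_test <- function(phy, reps = 1000, seed = NULL) {
  if (reps < 1L) stop("reps must be a positive integer")
  n <- n_tips(phy)
  if (n < 4L) stop("imbalance test needs at least 4 tips")
  obs <- colless_index(phy)
  nulls <- with_seed(seed, vapply(seq_len(reps), function(i) r_colless_yule(n),
                                  numeric(1)))
  res <- list(n = n,
              gamma = gamma_statistic(phy),
              colless = obs,
              colless_p = (1 + sum(nulls >= obs)) / (reps + 1),
              yule_reps = reps,
              seed = seed)
  class(res) <- "shape_stats"
  res
}

#' @export
print.shape_stats <- function(x, ...) {
  cat(sprintf("Tree shape (n = %d tips)\n", x$n))
  cat(sprintf("  gamma   : %.4f\n", x$gamma))
  cat(sprintf("  Colless : %d (max %d)\n", x$colless,
              ((x$n - 1L) * (x$n - 2L)) %/% 2L))
  cat(sprintf("  P(Colless >= obs | Yule), %d reps: %.4g\n",
              x$yule_reps, x$colless_p))
  invisible(x)
}
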