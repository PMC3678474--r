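# Faith's phylogenetic diversity, the random-extinction null, and the
# percent difference in projected PD between a threat scenario and random
# extinction of the same number of species.

# Vectorized survivor PD: S is an ntip x r 0/1 survivor indicator matrix.
# An edge contributes iff its subtree contains at least one survivor, which
# implements the rooted convention (path to the ORIGINAL root included).
survivor_pd <- function(st, S) {
  r <- ncol(S)
  C <- matrix(0, st$N, r)
  C[seq_len(st$ntip), ] <- S
  for (v in st$postorder) {
    k <- st$children[[v]]
    acc <- C[k[1L], ]
    for (j in k[-1L]) acc <- acc + C[j, ]
    C[v, ] <- acc
  }
  nonroot <- setdiff(seq_len(st$N), st$root)
  as.numeric(st$elen[nonroot] %*% (C[nonroot, , drop = FALSE] > 0))
}

#' Faith's phylogenetic diversity of a survivor set
#'
#' Sum of edge lengths (My) in the minimal subtree connecting the survivors
#' to the original root (rooted convention: the root path is included, so
#' deep stem edges count as long as any descendant survives). With all tips
#' surviving this equals the total branch length of the tree.
#'
#' @param phy A validated `phylo`.
#' @param survivors Non-empty character vector of surviving tip labels.
#' @return PD in My.
#' @export
faith_pd <- function(phy, survivors) {
  survivors <- unique(as.character(survivors))
  if (length(survivors) == 0L) stop("survivor set is empty")
  unknown <- setdiff(survivors, phy$tip.label)
  if (length(unknown) > 0L) {
    stop("unknown tip labels: ", paste(unknown, collapse = ", "))
  }
  st <- tree_struct(phy)
  S <- matrix(as.numeric(st$tip_labels %in% survivors), ncol = 1L)
  survivor_pd(st, S)
}

#' Random-extinction null distribution of survivor PD
#'
#' Each replicate removes `n_doomed` tips uniformly at random without
#' replacement and records the survivors' rooted PD.
#'
#' When the number of distinct removal sets `choose(n, n_doomed)` does not
#' exceed `reps`, the null is enumerated exhaustively instead of sampled, so
#' small-tree results are exact and deterministic; set `exhaustive` to force
#' either behaviour.
#'
#' @param phy A validated `phylo`.
#' @param n_doomed Number of tips to remove per replicate
#'   (`0 < n_doomed < n`).
#' @param reps Number of replicates (default 1000).
#' @param seed Optional integer seed.
#' @param exhaustive `NULL` (auto, see above), `TRUE` or `FALSE`.
#' @return List with `null_mean`, `null_sd` (My), `values`, and
#'   `exhaustive` (logical).
#' @export
random_extinction_null <- function(phy, n_doomed, reps = 1000, seed = NULL,
                                   exhaustive = NULL) {
  st <- tree_struct(phy)
  n <- st$ntip
  if (n_doomed <= 0L || n_doomed >= n) {
    stop("n_doomed must satisfy 0 < n_doomed < n_tips")
  }
  if (reps < 1L) stop("reps must be a positive integer")
  n_sets <- choose(n, n_doomed)
  if (is.null(exhaustive)) exhaustive <- n_sets <= reps
  if (exhaustive && n_sets > 1e6) stop("too many removal sets to enumerate")
  if (exhaustive) {
    doom <- utils::combn(n, n_doomed)
    S <- matrix(1, n, ncol(doom))
    for (j in seq_len(ncol(doom))) S[doom[, j], j] <- 0
    vals <- survivor_pd(st, S)
  } else {
    vals <- with_seed(seed, {
      S <- matrix(1, n, reps)
      for (j in seq_len(reps)) S[sample.int(n, n_doomed), j] <- 0
      survivor_pd(st, S)
    })
  }
  list(null_mean = mean(vals), null_sd = stats::sd(vals), values = vals,
       exhaustive = exhaustive)
}

#' Percent difference in projected PD under a threat scenario
#'
#' Assumes every species in `doomed` goes extinct, and compares the
#' survivors' PD with the expectation under random extinction of the same
#' number of species:
#' `%dE(PD) = 100 * (null_mean - pd_survivors_observed) / null_mean`.
#' Positive values mean the scenario destroys more PD than random extinction
#' of equally many species; negative values mean it is gentler than random.
#'
#' @param phy A validated `phylo`.
#' @param doomed Character vector of doomed tip labels (proper non-empty
#'   subset; at least 2 survivors).
#' @param reps Null replicates (default 1000).
#' @param seed Optional integer seed.
#' @return A list of class `"pd_loss"`: `pd_total`,
#'   `pd_survivors_observed`, `null_mean`, `null_sd` (all My),
#'   `percent_delta_epd` (%), `n_doomed`, `reps`, `seed`.
#' @export
percent_delta_epd <- function(phy, doomed, reps = 1000, seed = NULL) {
  doomed <- unique(as.character(doomed))
  unknown <- setdiff(doomed, phy$tip.label)
  if (length(unknown) > 0L) {
    stop("unknown tip labels: ", paste(unknown, collapse = ", "))
  }
  survivors <- setdiff(phy$tip.label, doomed)
  if (length(doomed) == 0L) stop("doomed set is empty")
  if (length(survivors) < 2L) stop("need at least 2 survivors")
  st <- tree_struct(phy)
  pd_total <- sum(phy$edge.length)
  pd_obs <- survivor_pd(st, matrix(as.numeric(st$tip_labels %in% survivors),
                                   ncol = 1L))
  nul <- random_extinction_null(phy, length(doomed), reps = reps, seed = seed)
  res <- list(pd_total = pd_total,
              pd_survivors_observed = pd_obs,
              null_mean = nul$null_mean,
              null_sd = nul$null_sd,
              percent_delta_epd = 100 * (nul$null_mean - pd_obs) / nul$null_mean,
              n_doomed = length(doomed),
              reps = reps,
              seed = seed)
  class(res) <- "pd_loss"
  res
}

#' @export
print.pd_loss <- function(x, ...) {
  cat("Projected PD loss under a threat scenario\n")
  cat(sprintf("  total PD            : %.2f My\n", x$pd_total))
  cat(sprintf("  survivor PD         : %.2f My (%d species doomed)\n",
              x$pd_survivors_observed, x$n_doomed))
  cat(sprintf("  random-null survivor: %.2f +/- %.2f My (%d reps)\n",
              x$null_mean, x$null_sd, x$reps))
  cat(sprintf("  %%dE(PD)             : %.3f%%  (positive = worse than random)\n",
              x$percent_delta_epd))
  invisible(x)
}
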