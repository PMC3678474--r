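# Internal plumbing shared by all modules: seeded evaluation, seed derivation,
# tree structure caches, and a preorder phylo builder used by the simulators.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the global RNG stream as-is".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from a single master seed; per-tree and
#' per-category streams are derived deterministically so that, e.g., category
#' order can be permuted without changing any individual result. The mix is a
#' multiplicative integer hash kept below 2^31 (R integers are 32-bit).
#'
#' @param master Integer master seed.
#' @param ... Integer indices (e.g. tree index, category index, stage tag).
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- as.double(master) %% 2147483647
  for (i in idx) {
    # 48271 is a classical Lehmer multiplier; exact in doubles below 2^53
    h <- (h * 48271 + as.double(i) + 1) %% 2147483647
  }
  as.integer(h)
}

# stable polynomial hash of a string, for category-name-keyed seed streams
name_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

n_tips <- function(phy) length(phy$tip.label)

root_node <- function(phy) n_tips(phy) + 1L

# children[[v]] = integer vector of v's children (empty for tips)
children_of <- function(phy) {
  N <- n_tips(phy) + phy$Nnode
  ch <- vector("list", N)
  for (v in seq_len(N)) ch[[v]] <- integer(0)
  sp <- split(phy$edge[, 2], phy$edge[, 1])
  ch[as.integer(names(sp))] <- lapply(sp, as.integer)
  ch
}

# topological depth (edge count from root) for every node; makes no
# assumption about edge-row ordering
topo_depths <- function(phy, ch = children_of(phy)) {
  N <- n_tips(phy) + phy$Nnode
  d <- integer(N)
  stk <- root_node(phy)
  while (length(stk) > 0L) {
    v <- stk[length(stk)]
    stk <- stk[-length(stk)]
    kids <- ch[[v]]
    if (length(kids) > 0L) {
      d[kids] <- d[v] + 1L
      stk <- c(stk, kids)
    }
  }
  d
}

# Precomputed traversal structure reused across many replicate evaluations
# (trait disparity sums, survivor PD, Brownian liabilities).
tree_struct <- function(phy) {
  nt <- n_tips(phy)
  N <- nt + phy$Nnode
  ch <- children_of(phy)
  dep <- topo_depths(phy, ch)
  e <- phy$edge
  internal <- (nt + 1L):N
  ord <- internal[order(dep[internal], decreasing = TRUE)] # children first
  elen <- numeric(N)
  elen[e[, 2]] <- phy$edge.length
  binary <- all(lengths(ch[internal]) == 2L)
  preorder_edges <- order(dep[e[, 2]]) # parent rows before child rows
  list(phy = phy, ntip = nt, nnode = phy$Nnode, N = N, root = nt + 1L,
       children = ch, postorder = ord, edge = e, elen = elen,
       preorder_edges = preorder_edges,
       binary = binary, tip_labels = phy$tip.label)
}

# Build an ape "phylo" from an id-indexed children list and node ages.
# Nodes with no children are tips; edges are emitted in preorder (cladewise).
build_phylo <- function(children, ages, tip_labels, root = 1L) {
  N <- length(ages)
  deg <- lengths(children)
  is_tip <- deg == 0L
  nt <- sum(is_tip)
  nn <- N - nt
  stopifnot(nt >= 2L, length(tip_labels) == N || length(tip_labels) == nt)
  if (length(tip_labels) == nt) {
    lab_full <- character(N)
    lab_full[is_tip] <- tip_labels
    tip_labels <- lab_full
  }
  newid <- integer(N)
  edge <- matrix(0L, N - 1L, 2L)
  elen <- numeric(N - 1L)
  labs <- character(nt)
  # iterative preorder DFS; stack of (node, parent-old-id)
  stk_n <- integer(N); stk_p <- integer(N); top <- 1L
  stk_n[1L] <- root; stk_p[1L] <- 0L
  tipc <- 0L; intc <- 0L; ec <- 0L
  while (top > 0L) {
    v <- stk_n[top]; p <- stk_p[top]; top <- top - 1L
    if (is_tip[v]) {
      tipc <- tipc + 1L
      newid[v] <- tipc
      labs[tipc] <- tip_labels[v]
    } else {
      intc <- intc + 1L
      newid[v] <- nt + intc
    }
    if (p > 0L) {
      ec <- ec + 1L
      edge[ec, 1L] <- newid[p]
      edge[ec, 2L] <- newid[v]
      elen[ec] <- ages[p] - ages[v]
    }
    kids <- children[[v]]
    for (k in rev(kids)) { # reversed so first child is popped first
      top <- top + 1L
      stk_n[top] <- k
      stk_p[top] <- v
    }
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = labs, Nnode = nn),
                   class = "phylo", order = "cladewise")
  phy
}

# inverse of build_phylo: children list + ages in phylo numbering
phylo_to_children <- function(phy) {
  list(children = children_of(phy), ages = node_ages(phy),
       root = root_node(phy))
}

is_binary_tree <- function(phy) {
  ch <- children_of(phy)
  internal <- (n_tips(phy) + 1L):(n_tips(phy) + phy$Nnode)
  all(lengths(ch[internal]) == 2L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
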