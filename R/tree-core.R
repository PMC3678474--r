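# Tree data model and plumbing: Newick I/O, validation of ultrametric time
# trees, pruning to tip subsets, random polytomy resolution, and extraction of
# the two root-daughter clades. Trees are ape "phylo" objects throughout;
# branch lengths are interpreted as durations in millions of years (My), so
# every node carries an implied age before present.

#' Node ages of an ultrametric time tree
#'
#' Ages are reconstructed from root-to-node path lengths: the root age is the
#' maximum root-to-tip distance and every other node's age is root age minus
#' its depth. On an exactly ultrametric tree all tip ages are 0.
#'
#' @param phy A rooted `phylo` with branch lengths (My).
#' @return Numeric vector of ages (My before present), indexed by node id
#'   (tips `1..n`, then internal nodes).
#' @export
node_ages <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  depth <- ape::node.depth.edgelength(phy)
  max(depth[seq_len(n_tips(phy))]) - depth
}

#' Validate a time tree
#'
#' Checks the invariants assumed by every downstream computation: at least two
#' tips with unique non-empty labels, non-negative branch lengths, and
#' contemporaneous tips (ultrametric within an absolute tolerance, default
#' 1e-6 My, reflecting the limited decimal precision of posterior tree files).
#'
#' @param phy A `phylo` object.
#' @param tol Absolute ultrametricity tolerance in My.
#' @return `phy`, invisibly, if valid; otherwise an error naming the worst
#'   offending tip.
#' @export
validate_timetree <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object")
  nt <- n_tips(phy)
  if (nt < 2L) stop("time tree must have at least 2 tips (got ", nt, ")")
  labs <- phy$tip.label
  if (any(!nzchar(labs))) stop("empty tip labels are not allowed")
  if (anyDuplicated(labs)) {
    stop("duplicated tip labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < -1e-12)) stop("negative branch lengths present")
  ages <- node_ages(phy)
  tip_ages <- abs(ages[seq_len(nt)])
  if (max(tip_ages) > tol) {
    worst <- which.max(tip_ages)
    stop(sprintf(
      "tree is not ultrametric: tip '%s' sits %.3g My off the present (tolerance %g)",
      labs[worst], tip_ages[worst], tol))
  }
  if (max(ages) <= 0) stop("root age must be positive")
  invisible(phy)
}

#' Parse a Newick string into a validated time tree
#'
#' @param text A single Newick string (rooted, branch lengths on all non-root
#'   edges, ages in My).
#' @param tol Ultrametricity tolerance passed to [validate_timetree()].
#' @return A validated `phylo`.
#' @export
parse_newick <- function(text, tol = 1e-6) {
  stopifnot(is.character(text), length(text) == 1L)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed Newick string")
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L) stop("expected a single Newick tree, got ", length(phy))
    phy <- phy[[1L]]
  }
  validate_timetree(phy, tol = tol)
  phy
}

#' Serialize a time tree to Newick
#'
#' @param phy A `phylo`.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string that re-parses to an equal tree.
#' @export
write_newick <- function(phy, digits = 12) {
  stopifnot(inherits(phy, "phylo"))
  ape::write.tree(phy, digits = digits)
}

#' Read a sample of time trees (one Newick per line)
#'
#' All member trees must share an identical tip-label set (a posterior sample
#' over a fixed taxon set). Lines that are empty or whitespace are skipped.
#' Files starting with `#NEXUS` are read as a NEXUS trees block instead
#' (translate tables are applied and stripped).
#'
#' @param file Path to a Newick file (one tree per line) or a NEXUS file
#'   with a trees block.
#' @param tol Ultrametricity tolerance per tree.
#' @return A `multiPhylo` list of validated trees.
#' @export
read_tree_sample <- function(file, tol = 1e-6) {
  first <- readLines(file, n = 1L)
  if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) {
    nex <- ape::read.nexus(file)
    if (inherits(nex, "phylo")) nex <- list(nex)
    trees <- lapply(nex, validate_timetree, tol = tol)
  } else {
    lines <- readLines(file)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("no trees found in ", file)
    trees <- lapply(lines, parse_newick, tol = tol)
  }
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      stop("tree ", i, " has a different tip set from tree 1")
    }
  }
  structure(trees, class = "multiPhylo")
}

#' Write a sample of time trees, one Newick per line
#'
#' @param trees A `multiPhylo` or list of `phylo`.
#' @param file Output path.
#' @export
write_tree_sample <- function(trees, file) {
  writeLines(vapply(trees, write_newick, character(1)), file)
  invisible(file)
}

#' Prune a time tree to a subset of tips
#'
#' Returns the subtree induced by `keep`: unary internal nodes are suppressed
#' (their two incident edges summed), kept-node ages are unchanged, and the
#' result is rooted at the most recent common ancestor of `keep` with no stem
#' edge above it. This is the standard rooted-PD convention for subtrees.
#'
#' @param phy A validated `phylo`.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The induced `phylo` subtree.
#' @export
prune_to <- function(phy, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, phy$tip.label)
  if (length(unknown) > 0L) {
    stop("unknown tip labels: ", paste(unknown, collapse = ", "))
  }
  if (length(keep) < 2L) stop("need at least 2 tips to prune to")
  if (length(keep) == n_tips(phy)) return(phy)
  out <- ape::keep.tip(phy, keep)
  out$root.edge <- NULL # MRCA-rooted: no stem edge above the new root
  out
}

#' Randomly resolve polytomies of a time tree
#'
#' Each multifurcation is resolved by uniformly random sequential pairing of
#' its children; every new internal node's age is drawn uniformly between the
#' polytomy's age and the older of the two paired children, so ultrametricity
#' and non-negative branch lengths are preserved and no zero-length edges are
#' introduced. Already-binary trees are returned unchanged.
#'
#' @param phy A (possibly multifurcating) validated `phylo`.
#' @param seed Optional integer seed; the result is deterministic given it.
#' @return A binary `phylo` with the same tip set, root age and pre-existing
#'   node ages.
#' @export
resolve_polytomies <- function(phy, seed = NULL) {
  if (is_binary_tree(phy)) return(phy)
  with_seed(seed, {
    st <- phylo_to_children(phy)
    ch <- st$children
    ages <- st$ages
    nt <- n_tips(phy)
    labs <- character(length(ages))
    labs[seq_len(nt)] <- phy$tip.label
    poly <- which(lengths(ch) > 2L)
    for (v in poly) {
      kids <- ch[[v]]
      while (length(kids) > 2L) {
        pick <- sample.int(length(kids), 2L)
        pair <- kids[pick]
        newage <- stats::runif(1L, min = max(ages[pair]), max = ages[v])
        ages <- c(ages, newage)
        labs <- c(labs, "")
        newid <- length(ages)
        ch[[newid]] <- pair
        kids <- c(kids[-pick], newid)
      }
      ch[[v]] <- kids
    }
    out <- build_phylo(ch, ages, labs, root = st$root)
    validate_timetree(out)
    out
  })
}

#' Tip sets of the two root-daughter clades
#'
#' For a tree whose root is binary, returns the two sets of tip labels
#' subtended by the root's children (e.g. the "complex" and "robust" clades of
#' the scleractinian root). Their union is the full tip set and they are
#' disjoint.
#'
#' @param phy A `phylo` with a binary root.
#' @return A list of two character vectors, in root-child order.
#' @export
root_daughter_clades <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  ch <- children_of(phy)
  kids <- ch[[root_node(phy)]]
  if (length(kids) != 2L) {
    stop("root is multifurcating; resolve polytomies first ",
         "(see resolve_polytomies())")
  }
  lapply(kids, function(k) clade_tips(phy, ch, k))
}

# tip labels below node v (v itself if a tip); iterative DFS
clade_tips <- function(phy, ch, v) {
  nt <- n_tips(phy)
  out <- character(0)
  stk <- v
  while (length(stk) > 0L) {
    x <- stk[length(stk)]
    stk <- stk[-length(stk)]
    if (x <= nt) out <- c(out, phy$tip.label[x]) else stk <- c(stk, ch[[x]])
  }
  out
}
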