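# Small fixture trees and independent brute-force oracles. The oracles are
# deliberately naive (path enumeration, recursion, exhaustive combinations)
# and share no code with the package internals they check.

bal4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")

caterpillar5 <- function() {
  parse_newick("((((A:1,B:1):1,C:2):1,D:3):1,E:4);")
}

balanced_tree <- function(depth) {
  # fully balanced 2^depth-tip tree with unit edges at every level
  lab <- function(k) paste0("x", k)
  build <- function(ids, lvl) {
    if (length(ids) == 1L) return(paste0(lab(ids), ":", lvl))
    half <- length(ids) / 2
    paste0("(", build(ids[1:half], 1), ",",
           build(ids[(half + 1):length(ids)], 1), "):",
           if (lvl == 0) "" else lvl)
  }
  n <- 2^depth
  txt <- paste0("(", build(1:(n / 2), 1), ",", build((n / 2 + 1):n, 1), ");")
  parse_newick(txt)
}

caterpillar_tree <- function(n) {
  # pectinate n-tip ultrametric tree, splits at ages 1..n-1
  txt <- paste0("(A1:1,A2:1)")
  for (k in 3:n) txt <- paste0("(", txt, ":1,A", k, ":", k - 1, ")")
  parse_newick(paste0(txt, ";"))
}

# PD by explicit path enumeration: union of edges on survivor-to-root paths
oracle_pd <- function(phy, survivors) {
  nt <- length(phy$tip.label)
  parent <- integer(nt + phy$Nnode)
  elen <- numeric(nt + phy$Nnode)
  for (i in seq_len(nrow(phy$edge))) {
    parent[phy$edge[i, 2]] <- phy$edge[i, 1]
    elen[phy$edge[i, 2]] <- phy$edge.length[i]
  }
  used <- logical(nt + phy$Nnode)
  for (s in match(survivors, phy$tip.label)) {
    v <- s
    while (parent[v] != 0L) {
      used[v] <- TRUE
      v <- parent[v]
    }
  }
  sum(elen[used])
}

# recursive sister-clade disparity oracle (exhaustive node walk)
oracle_disparity <- function(phy, trait) {
  nt <- length(phy$tip.label)
  kids <- vector("list", nt + phy$Nnode)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2])
  }
  total <- 0
  value <- function(v) {
    if (v <= nt) return(trait[[phy$tip.label[v]]])
    ab <- vapply(kids[[v]], value, numeric(1))
    total <<- total + abs(ab[1] - ab[2])
    mean(ab)
  }
  value(nt + 1L)
  total
}

# exhaustive random-extinction null by enumerating all removal sets
oracle_extinction_null <- function(phy, n_doomed) {
  sets <- utils::combn(phy$tip.label, n_doomed, simplify = FALSE)
  vals <- vapply(sets, function(d) oracle_pd(phy, setdiff(phy$tip.label, d)),
                 numeric(1))
  list(mean = mean(vals), values = vals)
}

# random 0/1 trait with both states, named by tip
random_trait <- function(phy, k = NULL) {
  n <- length(phy$tip.label)
  if (is.null(k)) k <- sample(seq_len(n - 1L), 1L)
  x <- numeric(n)
  x[sample.int(n, k)] <- 1
  names(x) <- phy$tip.label
  x
}
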