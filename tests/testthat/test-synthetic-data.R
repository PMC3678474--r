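test_that("synth_spec validates its parameters", {
  expect_s3_class(coral_preset(), "synth_spec")
  expect_error(synth_spec(n_tips = 100, clade_split = 0), "clade_split")
  expect_error(synth_spec(n_tips = 10,
                          categories = data.frame(name = "a", prevalence = 0.01,
                                                  clustering_weight = 1)))
  expect_error(synth_spec(n_tips = 4, clade_split = 0.9,
                          categories = data.frame(name = "a", prevalence = 0.5,
                                                  clustering_weight = 1)),
               "clade sizes")
})

test_that("generated trees have the prescribed size, root age and split", {
  spec <- coral_preset(n_tips = 200, seed = 4)
  tr <- generate_tree(spec)
  validate_timetree(tr)
  expect_equal(length(tr$tip.label), 200)
  expect_equal(max(node_ages(tr)), spec$root_age, tolerance = 1e-9)
  expect_setequal(lengths(root_daughter_clades(tr)), c(110L, 90L))
  expect_identical(write_newick(generate_tree(spec)), write_newick(tr))
  expect_true(pdthreat:::is_binary_tree(tr))
})

test_that("with neutral dials each clade reduces to a plain Yule clock", {
  spec <- coral_preset(n_tips = 120, n_trees = 1, seed = 6,
                       age_power = 1, imbalance_bias = 1)
  g <- vapply(1:60, function(i) {
    tr <- generate_tree(spec, seed = 700 + i)
    cl <- root_daughter_clades(tr)
    gamma_statistic(prune_to(tr, cl[[1]])) # gamma is scale-invariant
  }, numeric(1))
  expect_lt(abs(mean(g)), 0.45) # ~3 SE band around the Yule expectation of 0
  expect_gt(sd(g), 0.6)
  expect_lt(sd(g), 1.4)
})

test_that("the tippiness dial drives gamma strongly positive", {
  spec <- coral_preset(n_tips = 400, n_trees = 1, seed = 8, age_power = 3)
  g <- vapply(1:12, function(i) gamma_statistic(generate_tree(spec, seed = i)),
              numeric(1))
  expect_gt(mean(g), 5)
})

test_that("the imbalance dial raises Colless monotonically", {
  mean_colless <- vapply(c(1, 1.5, 2), function(k) {
    spec <- coral_preset(n_tips = 200, n_trees = 1, seed = 10,
                         imbalance_bias = k)
    mean(vapply(1:40, function(i) {
      colless_index(generate_tree(spec, seed = 3000 + i))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_colless) > 0))
})

test_that("tree samples share topology and differ only in node ages", {
  spec <- coral_preset(n_tips = 80, n_trees = 5, seed = 12)
  trees <- generate_tree_sample(spec)
  expect_length(trees, 5)
  for (tr in trees) validate_timetree(tr)
  topo <- lapply(trees, function(tr) {
    t2 <- tr
    t2$edge.length <- NULL
    ape::write.tree(t2)
  })
  expect_length(unique(unlist(topo)), 1L)
  ages <- vapply(trees, function(tr) sort(node_ages(tr), decreasing = TRUE)[2],
                 numeric(1))
  expect_gt(length(unique(ages)), 1L)
})

test_that("threat tables hit exact carrier counts with graded clustering", {
  spec <- coral_preset(n_tips = 200, n_trees = 1, seed = 14)
  tr <- generate_tree(spec)
  tab <- generate_threat_table(tr, spec)
  expect_equal(names(tab), c("species", spec$categories$name))
  expect_setequal(tab$species, tr$tip.label)
  for (j in seq_len(nrow(spec$categories))) {
    col <- tab[[spec$categories$name[j]]]
    expect_true(all(col %in% 0:1))
    expect_equal(sum(col), round(spec$categories$prevalence[j] * 200))
  }
  expect_equal(sum(tab$nt_plus), 116) # round(0.5799 * 200)

  # carrier counts of 0 or n are rejected
  bad <- coral_preset(n_tips = 200, n_trees = 1, seed = 14,
                      categories = data.frame(name = "near_all",
                                              prevalence = 0.998,
                                              clustering_weight = 0.5))
  expect_error(generate_threat_table(tr, bad), "out of range")
})

test_that("clustering weight anchors D at its two calibration points", {
  spec0 <- coral_preset(n_tips = 200, n_trees = 1, seed = 16,
                        categories = data.frame(name = "c0", prevalence = 0.3,
                                                clustering_weight = 0))
  spec1 <- coral_preset(n_tips = 200, n_trees = 1, seed = 16,
                        categories = data.frame(name = "c1", prevalence = 0.3,
                                                clustering_weight = 1))
  tr <- generate_tree(spec0)
  d_of <- function(spec, i) {
    tab <- generate_threat_table(tr, spec, seed = i)
    x <- tab[[2]]
    names(x) <- tab$species
    phylo_d(tr, x, reps = 200, seed = i)$D
  }
  d0 <- vapply(1:40, function(i) d_of(spec0, i), numeric(1))
  d1 <- vapply(1:40, function(i) d_of(spec1, i), numeric(1))
  expect_gt(mean(d0), 0.85)
  expect_lt(mean(d0), 1.15)
  expect_gt(mean(d1), -0.2)
  expect_lt(mean(d1), 0.25)
  # and the control is monotone across the grid
  spec5 <- coral_preset(n_tips = 200, n_trees = 1, seed = 16,
                        categories = data.frame(name = "c5", prevalence = 0.3,
                                                clustering_weight = 0.5))
  d5 <- vapply(1:40, function(i) d_of(spec5, i), numeric(1))
  expect_lt(mean(d1), mean(d5))
  expect_lt(mean(d5), mean(d0))
})

test_that("write_fixture emits byte-stable files that round-trip", {
  spec <- coral_preset(n_tips = 60, n_trees = 10, seed = 18)
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  p1 <- write_fixture(spec, d1)
  p2 <- write_fixture(spec, d2)
  expect_true(all(file.exists(p1)))
  expect_identical(readLines(p1[["trees"]]), readLines(p2[["trees"]]))
  expect_identical(readLines(p1[["threats"]]), readLines(p2[["threats"]]))

  trees <- read_tree_sample(p1[["trees"]])
  expect_length(trees, 10)
  tab <- read_threat_table(p1[["threats"]])
  expect_equal(nrow(tab), 60)
  meta <- jsonlite::read_json(p1[["spec"]])
  expect_equal(meta$n_tips, 60)
  expect_equal(length(meta$categories), 8)
})
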