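make_fixture <- function(n_tips = 120, n_trees = 3, seed = 5) {
  spec <- coral_preset(n_tips = n_tips, n_trees = n_trees, seed = seed)
  trees <- generate_tree_sample(spec)
  list(spec = spec, trees = trees,
       table = generate_threat_table(trees[[1]], spec))
}

test_that("run_category aggregates per-tree D and PD loss", {
  fx <- make_fixture()
  x <- fx$table$bleaching
  names(x) <- fx$table$species
  res <- run_category(fx$trees, x, reps = 100, seed = 2, category = "bleaching")
  expect_equal(res$percent_species, 100 * mean(x))
  expect_equal(res$n_trees, 3)
  expect_equal(nrow(res$per_tree), 3)
  expect_gte(res$D_sd, 0)

  # identical trees: d_obs identical, aggregate spread is Monte-Carlo only
  same <- structure(rep(list(fx$trees[[1]]), 4), class = "multiPhylo")
  res2 <- run_category(same, x, reps = 200, seed = 3)
  expect_equal(length(unique(res2$per_tree$d_obs)), 1L)
  expect_lt(res2$D_sd, 0.1)
})

test_that("threat_pd builds a category table in input order", {
  fx <- make_fixture()
  fit <- threat_pd(fx$trees, fx$table, reps = 100, seed = 7)
  expect_s3_class(fit, "threat_pd")
  expect_equal(fit$table$category, names(fx$table)[-1])
  expect_equal(nrow(fit$table), 8)
  expect_true(all(fit$table$percent_species > 0 & fit$table$percent_species < 100))
  expect_true(all(fit$table$D_sd >= 0, na.rm = TRUE))
  expect_equal(nrow(fit$per_tree), 8 * 3)

  # permuting category columns permutes rows only (name-keyed seed streams)
  perm <- fx$table[, c("species", rev(names(fx$table)[-1]))]
  fit2 <- threat_pd(fx$trees, perm, reps = 100, seed = 7)
  reord <- fit2$table[match(fit$table$category, fit2$table$category), ]
  rownames(reord) <- NULL
  expect_equal(reord, fit$table)

  # full determinism under a fixed master seed
  fit3 <- threat_pd(fx$trees, fx$table, reps = 100, seed = 7)
  expect_equal(fit3$table, fit$table)
})

test_that("monomorphic categories yield flagged undefined rows", {
  fx <- make_fixture(n_tips = 60, n_trees = 1)
  tab <- fx$table
  tab$all_on <- 1L
  fit <- threat_pd(fx$trees, tab, reps = 50, seed = 1)
  row <- fit$table[fit$table$category == "all_on", ]
  expect_true(is.na(row$D_mean))
  expect_match(row$note, "monomorphic")
  expect_equal(sum(nzchar(fit$table$note)), 1)
})

test_that("threat tables are validated", {
  fx <- make_fixture(n_tips = 60, n_trees = 1)
  bad <- fx$table
  bad$bleaching[1] <- 2L
  expect_error(threat_pd(fx$trees, bad, reps = 10), "outside \\{0, 1\\}")
  short <- fx$table[-(1:5), ]
  expect_error(threat_pd(fx$trees, short, reps = 10), "missing tips")
  # species assessed but absent from the trees are dropped with a logged count
  extra <- rbind(fx$table, fx$table[1, ])
  extra$species[nrow(extra)] <- "sp_not_on_tree"
  expect_message(threat_pd(fx$trees, extra, reps = 10, seed = 1),
                 "1 species .* absent from the trees")
})

test_that("regress recovers exact lines and rejects degenerate input", {
  tab <- data.frame(category = letters[1:8],
                    percent_species = seq(10, 80, by = 10),
                    D_mean = seq(0.1, 0.8, by = 0.1),
                    pdelta_mean = 2 - 5 * seq(0.1, 0.8, by = 0.1))
  r <- regress(tab, "D", "on_means")
  expect_equal(r$slope, -5, tolerance = 1e-10)
  expect_equal(r$intercept, 2, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  expect_lt(r$p_value, 1e-10)

  # prevalence predictor is the fraction, not the percentage
  tab$pdelta_mean <- 1 + 3 * tab$percent_species / 100
  rp <- regress(tab, "prevalence", "on_means")
  expect_equal(rp$slope, 3, tolerance = 1e-10)

  tab$D_mean <- 0.5
  expect_error(regress(tab, "D"), "constant predictor")
  expect_error(regress(tab[1:2, ], "prevalence"), "at least 3")
})

test_that("per-tree regression mode reports across-tree spread", {
  fx <- make_fixture()
  fit <- threat_pd(fx$trees, fx$table, reps = 100, seed = 11)
  r <- regress(fit, "D", "per_tree")
  expect_equal(r$n_trees, 3)
  expect_length(r$slope_ci95, 2)
  expect_lte(r$slope_ci95[1], r$slope)
  expect_gte(r$slope_ci95[2], r$slope)
})

test_that("clade-restricted runs recompute prevalence within the clade", {
  fx <- make_fixture(n_tips = 200, n_trees = 2)
  clades <- root_daughter_clades(fx$trees[[1]])
  expect_setequal(lengths(clades), c(110L, 90L))

  # a trait with known clade composition: 20 carriers in clade 1, 10 in clade 2
  tab <- data.frame(species = fx$table$species)
  x <- integer(200)
  names(x) <- tab$species
  x[clades[[1]][1:20]] <- 1L
  x[clades[[2]][1:10]] <- 1L
  tab$mixed <- x[tab$species]
  tab$only1 <- as.integer(tab$species %in% clades[[1]][21:40])

  fit1 <- threat_pd(fx$trees, tab, reps = 50, seed = 2, clade = "first")
  expect_equal(fit1$table$percent_species[1], 100 * 20 / 110, tolerance = 1e-9)
  fit2 <- threat_pd(fx$trees, tab, reps = 50, seed = 2, clade = "second")
  expect_equal(fit2$table$percent_species[1], 100 * 10 / 90, tolerance = 1e-9)
  # trait confined to clade 1 is undefined within clade 2
  expect_true(is.na(fit2$table$D_mean[2]))
  expect_match(fit2$table$note[2], "monomorphic")
})

test_that("summary, coef and plot methods work on a fitted object", {
  fx <- make_fixture(n_tips = 100, n_trees = 2)
  fit <- threat_pd(fx$trees, fx$table, reps = 80, seed = 3)
  out <- capture.output(s <- summary(fit))
  expect_true(any(grepl("OLS", out)))
  cf <- coef(fit)
  expect_named(cf, c("intercept", "slope"))
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("bundled coral threat summary loads and filters", {
  tab <- coral_threat_summary()
  expect_equal(nrow(tab), 32)
  expect_setequal(unique(tab$tree_set),
                  c("scleractinia", "mtdna", "complex_clade", "robust_clade"))
  scl <- coral_threat_summary("scleractinia")
  expect_equal(nrow(scl), 8)
  expect_true(all(scl$percent_species > 0 & scl$percent_species < 100))
})
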