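test_that("cohort means are per-gene arithmetic means, order-invariant", {
  m <- matrix(c(2, 1, 4, 3), 2, 2, dimnames = list(c("NQO1", "CAT"), c("a", "b")))
  expect_equal(cohort_means(m), c(NQO1 = 3, CAT = 2))
  expect_equal(cohort_means(m[, c(2, 1)]), cohort_means(m))
  expect_equal(unname(cohort_means(matrix(7, 1, 5,
    dimnames = list("NQO1", NULL)))), 7)
  expect_error(cohort_means(m[, 0, drop = FALSE]), "at least one cell")
})

test_that("rate multipliers are expression ratios with an epsilon floor", {
  expect_equal(rate_multiplier(3, 3), 1)
  expect_equal(rate_multiplier(4.5, 3), 1.5)
  expect_equal(rate_multiplier(0, 3, eps = 1e-3), 1e-3)
  expect_error(rate_multiplier(1, 0), "> 0")
})

test_that("additive multipliers pool gene pairs", {
  expect_equal(additive_multiplier(c(2, 2), c(2, 2)), 1)
  expect_equal(additive_multiplier(c(4, 0), c(2, 2)), 1)  # split irrelevant
  expect_equal(additive_multiplier(c(3, 3), c(2, 2)), 1.5)
  expect_error(additive_multiplier(c(1, 1), c(0, 0)), "> 0")
})

test_that("a cohort-average profile yields the identity specification", {
  mapping <- read_mapping_config()
  genes <- mapped_genes(mapping)
  means <- setNames(runif(length(genes), 1, 10), genes)
  spec <- build_cell_model(means, means, mapping)
  expect_true(all(abs(spec$multipliers - 1) < 1e-12))
  expect_true(all(abs(spec$abundance_scale - 1) < 1e-12))
  cell <- apply_cell_spec(default_net(), spec, rest_state(), mapping)
  expect_equal(cell$network$params, default_net()$params)
  expect_equal(cell$state, rest_state())
})

test_that("a single-gene shift maps locally to its rate constant", {
  mapping <- read_mapping_config()
  genes <- mapped_genes(mapping)
  means <- setNames(rep(5, length(genes)), genes)
  expr <- means; expr["NQO1"] <- 10
  spec <- build_cell_model(expr, means, mapping)
  expect_equal(unname(spec$multipliers["k29"]), 2)
  others <- setdiff(names(spec$multipliers), "k29")
  expect_true(all(abs(spec$multipliers[others] - 1) < 1e-12))
  expect_true(all(abs(spec$abundance_scale - 1) < 1e-12))
})

test_that("applying then inverting a spec recovers the base constants", {
  mapping <- read_mapping_config()
  genes <- mapped_genes(mapping)
  set.seed(2)
  means <- setNames(runif(length(genes), 1, 10), genes)
  expr <- means * exp(rnorm(length(genes), 0, 0.5))
  names(expr) <- genes
  spec <- build_cell_model(expr, means, mapping)
  cell <- apply_cell_spec(default_net(), spec, rest_state(), mapping)
  recovered <- cell$network$params
  recovered[names(spec$multipliers)] <-
    recovered[names(spec$multipliers)] / spec$multipliers
  expect_equal(recovered, default_net()$params)
})

test_that("specs are deterministic and scale linearly in expression", {
  mapping <- read_mapping_config()
  genes <- mapped_genes(mapping)
  means <- setNames(rep(4, length(genes)), genes)
  expr <- means; expr["SOD1"] <- 6
  s1 <- build_cell_model(expr, means, mapping)
  s2 <- build_cell_model(expr, means, mapping)
  expect_identical(s1$multipliers, s2$multipliers)
  # scaling one gene's expression by alpha scales exactly its multiplier
  alpha <- 3
  expr2 <- expr; expr2["SOD1"] <- expr["SOD1"] * alpha
  s3 <- build_cell_model(expr2, means, mapping)
  expect_equal(unname(s3$multipliers["k32"]),
               unname(alpha * s1$multipliers["k32"]))
  same <- setdiff(names(s1$multipliers), "k32")
  expect_equal(s3$multipliers[same], s1$multipliers[same])
})

test_that("missing mapped genes are reported by name", {
  mapping <- read_mapping_config()
  genes <- mapped_genes(mapping)
  means <- setNames(rep(4, length(genes)), genes)
  expect_error(build_cell_model(means[-match("GSR", genes)], means, mapping),
               "GSR")
})

test_that("pooled abundance genes weight by equilibrium protein, not raw RNA", {
  mapping <- read_mapping_config()
  genes <- mapped_genes(mapping)
  means <- setNames(rep(5, length(genes)), genes)
  expr <- means
  # move expression between PRX1 and PRX2; equal protein weights would keep
  # the pool scale at 1 only if their constants matched
  expr["PRX1"] <- 10; expr["PRX2"] <- 0
  spec <- build_cell_model(expr, means, mapping)
  tab <- read_rate_constants()
  w1 <- with(tab[tab$gene == "PRX1", ], k_sp / k_dp)
  w2 <- with(tab[tab$gene == "PRX2", ], k_sp / k_dp)
  expect_equal(unname(spec$abundance_scale["PRX"]),
               (10 * w1) / (5 * w1 + 5 * w2))
})

test_that("protein concentrations build a cells x genes molar block", {
  co <- small_cohort()
  pr <- protein_concentrations(co$matrix)
  expect_equal(rownames(pr), colnames(co$matrix))
  expect_setequal(colnames(pr), mapped_genes(read_mapping_config()))
  expect_true(all(pr >= 0))
  # equilibrium gene: doubling expression doubles concentration
  m2 <- co$matrix; m2["NQO1", ] <- 2 * m2["NQO1", ]
  pr2 <- protein_concentrations(m2)
  expect_equal(pr2[, "NQO1"], 2 * pr[, "NQO1"])
})
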