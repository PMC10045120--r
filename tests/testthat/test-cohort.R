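test_that("Welch's t matches the closed-form oracle", {
  # hand oracle: a = [1,2,3], b = [2,3,4]; s1^2 = s2^2 = 1, n = 3
  # t = (2-3)/sqrt(2/3) = -1.224745; df = (2/3)^2 / (2 * (1/3)^2/2) = 4
  wt <- welch_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(wt$t, -1.224745, tolerance = 1e-6)
  expect_equal(wt$df, 4)
  expect_equal(wt$p, 0.2878641, tolerance = 1e-6)
})

test_that("identical varying groups give t = 0, p = 1", {
  wt <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(wt$t, 0)
  expect_equal(wt$p, 1)
})

test_that("equal-n Welch equals the pooled Student t statistic", {
  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(12); b <- rnorm(12, 0.5)
    wt <- welch_test(a, b)
    pooled <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(wt$t, unname(pooled$statistic), tolerance = 1e-12)
  }
})

test_that("degenerate groups are rejected by name", {
  expect_error(welch_test(c(1), c(1, 2, 3)), "group a")
  expect_error(welch_test(c(1, 2, 3), c(2, 2, 2)), "group b")
})

test_that("null p-values are uniform under repeated sampling", {
  set.seed(123)
  p <- replicate(200, welch_test(rnorm(20), rnorm(20))$p)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("whiskers follow the interquartile-range rule", {
  v <- c(1, 2, 3, 4, 100)
  bs <- boxplot_stats(v)
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  expect_equal(unname(bs["whisker_hi"]), q[2] + 1.5 * (q[2] - q[1]))
  expect_equal(unname(bs["whisker_lo"]), q[1] - 1.5 * (q[2] - q[1]))
  expect_equal(unname(bs["mean"]), mean(v))
})

test_that("identical average cells give identical endpoint rows", {
  genes <- redox_genes()
  m <- matrix(default_base_means(genes), length(genes), 3,
              dimnames = list(genes, c("c1", "c2", "c3")))
  ann <- data.frame(cell_id = c("c1", "c2", "c3"), patient_id = "P1",
                    malignant = c(0L, 1L, 1L))
  ep <- run_cohort(m, ann, default_net(), base_state = rest_state())
  expect_equal(ep$h2o2[2], ep$h2o2[1])
  expect_equal(ep$h2o2[3], ep$h2o2[1])
  expect_identical(ep$status, rep("stable", 3))
  # all multipliers are 1, so this equals the average-cell simulation
  base <- endpoint_summary(dosed_traj())
  expect_equal(ep$h2o2[1], base[["h2o2"]], tolerance = 1e-6)
})

test_that("endpoint H2O2 is ordered in the NQO1 multiplier", {
  genes <- redox_genes()
  mu <- default_base_means(genes)
  m <- matrix(mu, length(genes), 3, dimnames = list(genes, c("lo", "md", "hi")))
  m["NQO1", "lo"] <- 0          # epsilon-floored multiplier
  m["NQO1", "hi"] <- 5 * mu["NQO1"]
  # means computed from these three cells shift, so fix the reference by
  # building specs against the average profile directly
  means <- setNames(mu[mapped_genes(read_mapping_config())],
                    mapped_genes(read_mapping_config()))
  h <- sapply(c("lo", "md", "hi"), function(cid) {
    expr <- setNames(m[names(means), cid], names(means))
    spec <- build_cell_model(expr, means)
    cell <- apply_cell_spec(default_net(), spec, rest_state())
    st <- cell$state; st["blap_ext"] <- default_dose
    endpoint_summary(simulate_network(cell$network, st))[["h2o2"]]
  })
  expect_lt(h[["lo"]], h[["md"]])
  expect_lt(h[["md"]], h[["hi"]])
})

test_that("an undosed cohort stays at the drug-free baseline", {
  genes <- redox_genes()
  m <- matrix(default_base_means(genes), length(genes), 2,
              dimnames = list(genes, c("c1", "c2")))
  ann <- data.frame(cell_id = c("c1", "c2"), patient_id = "P1",
                    malignant = c(0L, 1L))
  ep <- run_cohort(m, ann, default_net(), dose = 0, base_state = rest_state())
  base_h2o2 <- rest_state()[["H2O2"]]
  expect_true(all(abs(ep$h2o2 - base_h2o2) / base_h2o2 < 0.01))
})

test_that("the cohort pipeline is deterministic and order-insensitive", {
  co <- small_cohort()
  ep1 <- small_endpoints()
  perm <- sample(nrow(co$annotations))
  ep2 <- suppressMessages(run_cohort(co$matrix, co$annotations[perm, ],
                                     default_net(), base_state = rest_state()))
  expect_equal(ep1, ep2)
})

test_that("patient report compares classes per patient with Welch", {
  ep <- small_endpoints()
  rep <- patient_report(ep)
  expect_true(all(c("t", "df", "p", "significant") %in% names(rep$comparisons)))
  expect_true(all(rep$comparisons$p >= 0 & rep$comparisons$p <= 1))
  expect_true(all(rep$comparisons$df > 0))
  expect_setequal(unique(rep$boxplot$malignant), c(0, 1))
  # manual check for one patient on the log scale
  pat <- rep$comparisons$patient_id[1]
  sub <- ep[ep$patient_id == pat & ep$status == "stable", ]
  wt <- welch_test(log10(sub$h2o2[sub$malignant == 1]),
                   log10(sub$h2o2[sub$malignant == 0]))
  expect_equal(rep$comparisons$t[1], wt$t)
})

test_that("single-class patients are excluded with a warning", {
  ep <- small_endpoints()
  ep$malignant[ep$patient_id == "P01"] <- 1L
  expect_warning(rep <- patient_report(ep), "P01")
  expect_false("P01" %in% rep$comparisons$patient_id)
})

test_that("an implanted class shift is detected with near-certain power", {
  set.seed(99)
  n <- 100
  base <- rnorm(n, 0, 1)
  shifted <- rnorm(n, 2, 1)  # +2 SD implant
  wt <- welch_test(shifted, base)
  expect_lt(wt$p, 0.05)
  expect_gt(wt$t, 0)
})
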