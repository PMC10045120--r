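test_that("the nine drug reactions carry their printed rate terms", {
  net <- default_net()
  k <- net$params
  st <- initial_state(net)
  st[c("blap_ext", "blapQ", "blapHQ", "blapSQ", "blapHQ_SG")] <-
    c(5e-6, 2e-6, 3e-6, 1e-6, 4e-7)
  st["O2s"] <- 1e-8
  r <- evaluate_rates(net, st)
  A <- net$geometry$membrane_area_factor
  expect_equal(r[["blap_permeation"]],
               k[["k34"]] * A * (st[["blap_ext"]] - st[["blapQ"]]))
  expect_equal(r[["blap_reduction"]], k[["k29"]] * st[["blapQ"]] * st[["NADPH"]])
  expect_equal(r[["blap_semioxidation"]], k[["k30"]] * st[["blapHQ"]] * st[["O2"]])
  expect_equal(r[["blap_oxidation"]], k[["k31"]] * st[["blapSQ"]] * st[["O2"]])
  expect_equal(r[["superoxide_dismutase"]], k[["k32"]] * st[["O2s"]]^2)
  expect_equal(r[["blap_semireduction"]], k[["k33"]] * st[["blapQ"]] * st[["NADPH"]])
  expect_equal(r[["blap_semiquinone_semireduction"]],
               k[["k33"]] * st[["blapSQ"]] * st[["NADPH"]])
  expect_equal(r[["blap_glutathionylation"]],
               k[["k35"]] * st[["blapHQ"]] * st[["GSH"]])
  expect_equal(r[["glutathionylated_blap_permeation"]],
               k[["k36"]] * A * st[["blapHQ_SG"]])
})

test_that("rate-law templates evaluate by substitution", {
  # dismutation k [S]^2: k32 = 2, [S] = 3 -> 18
  net <- build_network(toy_config(
    species = list(toy_species("S", 3), toy_species("P", 0)),
    parameters = list(k32 = 2),
    reactions = list(toy_reaction("dismutation", "second_order_self", "k32",
                                  list("S"), list(S = -2, P = 1)))))
  expect_equal(unname(evaluate_rates(net, c(S = 3, P = 0))), 18)

  # zero-gradient permeation: equal concentrations -> rate 0
  net2 <- build_network(toy_config(
    species = list(toy_species("X_out", 5e-6, "extracellular"),
                   toy_species("X_in", 5e-6)),
    parameters = list(k34 = 1),
    reactions = list(toy_reaction("perm", "gradient_permeation", "k34",
                                  list("X_out", "X_in"),
                                  list(X_out = -1, X_in = 1)))))
  expect_equal(unname(evaluate_rates(net2, c(X_out = 5e-6, X_in = 5e-6))), 0)

  # bimolecular substitution: k = 0.1, [Q] = 2, [NADPH] = 10 -> 2
  net3 <- build_network(toy_config(
    species = list(toy_species("Q", 2), toy_species("NADPH", 10),
                   toy_species("HQ", 0), toy_species("NADP", 0)),
    parameters = list(k29 = 0.1),
    reactions = list(toy_reaction("red", "mass_action", "k29",
                                  list("Q", "NADPH"),
                                  list(Q = -1, NADPH = -1, HQ = 1, NADP = 1)))))
  expect_equal(unname(evaluate_rates(net3, c(Q = 2, NADPH = 10, HQ = 0, NADP = 0))), 2)
})

test_that("configuration validation rejects broken inputs by name", {
  cfg <- read_model_config()
  cfg$parameters$k32 <- NULL
  expect_error(build_network(cfg), "k32")

  cfg2 <- read_model_config()
  cfg2$reactions[[2]]$stoichiometry$GHOST <- 1
  expect_error(build_network(cfg2), "GHOST")

  cfg3 <- read_model_config()
  cfg3$compartments$volume_cytosol <- 0
  expect_error(build_network(cfg3), "volume_cytosol")
})

test_that("drug moiety is conserved reaction by reaction and in bulk", {
  net <- default_net()
  moi <- net$moieties$blap
  # symbolic audit: signed moiety sum of every reaction's stoichiometry is 0
  for (rx in net$reactions) {
    st <- unlist(rx$stoichiometry)
    touched <- intersect(names(st), names(moi))
    expect_equal(sum(st[touched] * unlist(moi)[touched]), 0,
                 info = rx$name)
  }
  # volume-weighted: w' S_eff = 0, so d(total drug amount)/dt = 0 at any state
  w <- numeric(nrow(net$species))
  w[net$compiled$idx[names(moi)]] <- unlist(moi)
  w <- w * net$compiled$vol
  # permeation columns mix amounts scaled by 1/volume (~1e12), so allow
  # floating-point cancellation error
  expect_lt(max(abs(t(w) %*% net$compiled$S)), 1e-10)
})

test_that("derivatives compose stoichiometry with rates and honor clamps", {
  net <- default_net()
  f <- assemble_derivatives(net)
  st <- rest_state()  # no drug anywhere
  d <- f(st)
  drug <- c("blap_ext", "blapQ", "blapHQ", "blapSQ", "blapHQ_SG", "blapHQ_SG_ext")
  expect_true(all(abs(d[drug]) == 0))
  expect_identical(unname(d["O2"]), 0)  # clamped
  # manual composition check on one species: H2O2 balance
  r <- evaluate_rates(net, st)
  man <- r[["mitochondrial_h2o2_source"]] - r[["prx_oxidation"]] -
    r[["prx_hyperoxidation"]] - r[["gpx_h2o2_reduction"]] -
    2 * r[["catalase_h2o2_decomposition"]] - r[["protein_thiol_oxidation"]] +
    r[["superoxide_dismutase"]] +
    r[["h2o2_permeation"]] / net$geometry$volume_cytosol
  expect_equal(unname(d["H2O2"]), man)
})

test_that("one-reaction decay matches the closed-form exponential", {
  net <- decay_network(k = 0.1, A0 = 1)
  tr <- simulate_network(net, c(A = 1, B = 0),
                         solver_settings(list(end_time = 60)), n_out = 61)
  expect_identical(tr$status, "stable")
  expect_equal(tr$conc[, "A"], exp(-0.1 * tr$times), tolerance = 1e-6)
  expect_equal(tr$conc[, "B"], 1 - exp(-0.1 * tr$times), tolerance = 1e-6)
})

test_that("default solver settings are 2 h, max step 1 s, abstol 1e-8", {
  s <- solver_settings()
  expect_equal(s$end_time, 7200)
  expect_equal(s$max_step, 1)
  expect_equal(s$atol, 1e-8)
  expect_identical(default_net()$solver$end_time, 7200)
})

test_that("a pathological parameter set flags unstable without crashing", {
  net <- default_net()
  net$params[["k29"]] <- net$params[["k29"]] * 1e12
  net$params[["k_nadph"]] <- 1e12
  net$compiled <- redoxcell:::compile_network(net)
  tr <- simulate_network(net, dosed_state())
  expect_s3_class(tr, "redox_trajectory")
  expect_true(tr$status %in% c("stable", "unstable"))
  net$params[["k29"]] <- net$params[["k29"]] * 1e12  # 1e24: must break
  net$compiled <- redoxcell:::compile_network(net)
  tr2 <- simulate_network(net, dosed_state())
  expect_identical(tr2$status, "unstable")
})

test_that("trajectory export is tidy and round-trips through CSV", {
  tr <- simulate_network(decay_network(), c(A = 1, B = 0),
                         solver_settings(list(end_time = 10)), n_out = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- trajectory_to_tidy(tr, cell_id = "c1", path = path)
  expect_named(df, c("time", "species", "concentration", "cell_id"))
  expect_equal(nrow(df), 5 * 2)
  back <- utils::read.csv(path)
  expect_equal(back$concentration, df$concentration)
})
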