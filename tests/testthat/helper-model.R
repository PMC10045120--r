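# Shared fixtures, memoized so the expensive objects (default network,
# pre-equilibrated resting state, dosed baseline trajectory) are computed
# once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

default_net <- function() memo("net", build_network(read_model_config()))

rest_state <- function() memo("rest", equilibrate_network(default_net()))

default_dose <- 5e-6

dosed_state <- function() {
  st <- rest_state()
  st["blap_ext"] <- default_dose
  st
}

dosed_traj <- function() memo("dosed",
  simulate_network(default_net(), dosed_state()))

# Minimal-network builder for toy models.
toy_config <- function(species, parameters, reactions,
                       vol_ext = 1e-3, vol_cyt = 1e-3, solver = NULL) {
  list(
    compartments = list(volume_extracellular = vol_ext,
                        volume_cytosol = vol_cyt,
                        membrane_area_factor = 1),
    species = species, parameters = parameters, reactions = reactions,
    solver = solver)
}

toy_species <- function(name, initial, compartment = "cytosol",
                        clamped = FALSE) {
  list(name = name, compartment = compartment, initial = initial,
       clamped = clamped)
}

toy_reaction <- function(name, template, k, species, stoichiometry) {
  list(name = name, template = template, k = k, species = species,
       stoichiometry = stoichiometry)
}

# A -> B first-order decay, closed form A0 * exp(-k t).
decay_network <- function(k = 0.1, A0 = 1) {
  build_network(toy_config(
    species = list(toy_species("A", A0), toy_species("B", 0)),
    parameters = list(k_decay = k),
    reactions = list(toy_reaction("decay", "mass_action", "k_decay",
                                  list("A"), list(A = -1, B = 1)))))
}

# Small synthetic cohort reused across pipeline tests.
small_cohort <- function() memo("small_cohort",
  generate_cohort(cohort_design(n_patients = 2, cells_per_class = 6,
                                seed = 11)))

small_endpoints <- function() memo("small_endpoints",
  run_cohort(small_cohort()$matrix, small_cohort()$annotations,
             default_net(), base_state = rest_state()))
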