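# shared builders for small test mechanisms

two_state_scheme <- function(kf = 2, kr = 1) {
  list(scheme = kinetic_scheme("ab", c("A", "B"),
                               transitions = data.frame(from = "A", to = "B",
                                                        kf = "kf", kr = "kr")),
       params = parameter_set(kf = kf, kr = kr))
}

irreversible_ab <- function(k = 1) {
  list(scheme = kinetic_scheme("ab_irrev", c("A", "B"),
                               transitions = data.frame(from = "A", to = "B",
                                                        kf = "k")),
       params = parameter_set(k = k))
}

# one-step tight-binding scheme E + L <-> EL
one_step_binding <- function(kon = 10, koff = 100) {
  list(scheme = kinetic_scheme("bind1", c("E", "EL"), ligands = "L",
                               transitions = data.frame(from = "E", to = "EL",
                                                        kf = "kon", kr = "koff",
                                                        ligand_f = "L")),
       params = parameter_set(kon = list(value = kon, units = "/uM/s"),
                              koff = koff))
}

# small quench fit problem on the sequential mechanism, noiseless by default
fig2_problem <- function(seedA = 11, seedB = 12, sigma = 0) {
  nm <- function(s) noise_model("gaussian-relative", sigma, s)
  exA <- generate_quench_dataset(
    generator_config("fig2_sequential", start = "ED27", noise = nm(seedA)))
  exB <- generate_quench_dataset(
    generator_config("fig2_sequential", start = "ED28", noise = nm(seedB)))
  fit_problem(list(exA, exB), paper_fixture("fig2_sequential")$params)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
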