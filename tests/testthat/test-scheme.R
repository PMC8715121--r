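test_that("scheme construction validates states, ligands and endpoints", {
  expect_error(kinetic_scheme("x", c("A", "A"),
                              transitions = data.frame(from = "A", to = "A",
                                                       kf = "k")),
               "unique")
  expect_error(kinetic_scheme("x", c("A", "B"),
                              transitions = data.frame(from = "A", to = "C",
                                                       kf = "k")),
               "endpoint")
  expect_error(kinetic_scheme("x", c("A", "B"),
                              transitions = data.frame(from = "A", to = "B",
                                                       kf = "k",
                                                       ligand_f = "L")),
               "undeclared ligand")
})

test_that("parameter sets enforce positivity, units and coverage", {
  expect_error(parameter_set(k = -1), "positive")
  expect_error(parameter_set(k = list(value = 1, units = "/h")), "units")
  ## unit conversion on load
  ps <- parameter_set(k = list(value = 1.5, units = "/mM/s"))
  expect_equal(param_values(ps)[["k"]], 1.5e-3)
  ## a bimolecular transition demands /uM/s units
  ts <- one_step_binding()
  bad <- parameter_set(kon = 10, koff = 100)  # kon declared /s
  expect_error(rate_matrix(ts$scheme, bad, c(L = 1)), "units")
  fx <- paper_fixture("fig3_binding")
  dropped <- fx$params[fx$params$name != "kB2", ]
  class(dropped) <- class(fx$params)
  expect_error(rate_matrix(fx$scheme, dropped, c(dTTP = 1)),
               "missing parameter: kB2")
})

test_that("fixture catalog round-trips the published rate constants", {
  expect_error(paper_fixture("fig9"), "fig1_minimal")
  ## literal copies of the printed tables (uM, s units)
  tab3 <- c(kA1 = 10, kmA1 = 77000, kA2 = 0.68,
            kB1 = 10, kmB1 = 4600, kB2 = 0.20)
  expect_identical(param_values(paper_fixture("fig2_sequential")$params)[names(tab3)],
                   tab3)
  tab4 <- c(kB1 = 10, kmB1 = 15000, kB2 = 310, kmB2 = 6.8)
  expect_identical(param_values(paper_fixture("fig3_binding")$params)[names(tab4)],
                   tab4)
  tab5 <- c(k4 = 10, km4 = 26000, k5 = 500, km5 = 140, k6 = 45, km6 = 6.6,
            k7 = 0.102, k8 = 0.22, k9 = 0.007, km9 = 14, k10 = 0.90,
            k11 = 0.12)
  expect_identical(param_values(paper_fixture("fig5_extension")$params)[names(tab5)],
                   tab5)
  tab6a <- c(k12 = 0.055, km12 = 340, k3 = 0.53)
  expect_identical(param_values(paper_fixture("fig7_misincorporation",
                                              "one_step")$params)[names(tab6a)],
                   tab6a)
  tab6b <- c(k1 = 100, km1 = 930000, k2 = 170, km2 = 340, k3 = 1.6)
  expect_identical(param_values(paper_fixture("fig7_misincorporation",
                                              "two_step")$params)[names(tab6b)],
                   tab6b)
})

test_that("rate matrix columns sum to zero and empty schemes give zero derivatives", {
  for (nm in c("fig2_sequential", "fig3_binding", "fig5_extension")) {
    fx <- paper_fixture(nm)
    M <- rate_matrix(fx$scheme, fx$params, c(dTTP = 777))
    expect_lt(max(abs(colSums(M))), 1e-10)
  }
  empty <- kinetic_scheme("none", c("A", "B"),
                          transitions = data.frame(from = character(),
                                                   to = character(),
                                                   kf = character()))
  f <- build_rate_equations(empty, parameter_set(unused = 1))
  expect_equal(f(c(A = 3, B = 5)), c(A = 0, B = 0))
})

test_that("derivatives vanish at detailed-balance and linear-solve equilibria", {
  ts <- two_state_scheme(kf = 2, kr = 1)
  f <- build_rate_equations(ts$scheme, ts$params)
  expect_equal(max(abs(f(c(A = 1, B = 2)))), 0)  # B/A = kf/kr
  ## brute-force null space of the rate matrix as an independent oracle
  fx <- paper_fixture("fig3_binding")
  M <- rate_matrix(fx$scheme, fx$params, c(dTTP = 3000))
  ns <- svd(M)$v[, 3L]
  ns <- ns / sum(ns) * 0.2
  g <- build_rate_equations(fx$scheme, fx$params, c(dTTP = 3000))
  expect_lt(max(abs(g(stats::setNames(ns, fx$scheme$states)))),
            1e-9 * max(abs(M)) * 0.2)
})

test_that("conservation totals cover pools and explicit-ligand bookkeeping", {
  fx <- paper_fixture("fig3_binding")
  tot <- conservation_totals(fx$scheme, c(ED = 0.2))
  expect_equal(unname(tot[["pool.ED"]]), 0.2)
  ## mirrors the trap experiment premix: 1 uM complex + 5 uM nucleotide
  tot2 <- conservation_totals(fx$scheme, c(ED = 1, dTTP = 5),
                              mode = "explicit")
  expect_equal(unname(tot2[["dTTP"]]), 5)
  expect_error(conservation_totals(fx$scheme, c(ED = -1)), "non-negative")
  ## totals preserved along any simulated trajectory
  tc <- integrate_scheme(fx$scheme, fx$params, c(ED = 1, dTTP = 5),
                         times = seq(0, 0.5, length.out = 21),
                         mode = "explicit", method = "lsoda")
  st <- ligand_stoichiometry(fx$scheme)
  lig_tot <- as.matrix(tc[, fx$scheme$states]) %*% st[, "dTTP"] + tc$dTTP
  expect_rel_equal(lig_tot, rep(5, nrow(tc)), 1e-6)
  pool <- rowSums(tc[, fx$scheme$states])
  expect_rel_equal(pool, rep(1, nrow(tc)), 1e-6)
})

test_that("pseudo-first-order and explicit modes agree when ligand is in excess", {
  fx <- paper_fixture("fig3_binding")
  times <- seq(0, 0.1, length.out = 41)
  ## ligand 100x the enzyme pool
  tc_p <- integrate_scheme(fx$scheme, fx$params, c(ED = 0.2),
                           ligand_concs = c(dTTP = 20), times = times)
  tc_e <- integrate_scheme(fx$scheme, fx$params, c(ED = 0.2, dTTP = 20),
                           times = times, mode = "explicit", method = "lsoda")
  for (s in fx$scheme$states)
    expect_lt(max(abs(tc_p[[s]] - tc_e[[s]])) / 0.2, 1e-3)
})
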