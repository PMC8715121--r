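test_that("King-Altman reduction matches textbook closed forms", {
  ## E + S <-> ES -> E + P: kcat = k2, Km = (km1 + k2)/k1
  sc <- kinetic_scheme("mm", c("E", "ES", "P"), ligands = "S",
                       transitions = data.frame(
                         from = c("E", "ES"), to = c("ES", "P"),
                         kf = c("k1", "k2"), kr = c("km1", NA),
                         ligand_f = c("S", NA), ligand_r = NA))
  ps <- parameter_set(k1 = list(value = 5, units = "/uM/s"),
                      km1 = 80, k2 = 12)
  ss <- king_altman(sc, ps, "S")
  expect_equal(ss$kcat, 12, tolerance = 1e-9)
  expect_equal(ss$Km, (80 + 12) / 5, tolerance = 1e-9)
})

test_that("King-Altman agrees with closed forms across random three-step draws", {
  ## independent oracle: the exact steady-state expressions for
  ## E+S <-> ES <-> FS -> P:
  ##   kcat = k2 k3/(k2 + km2 + k3), Km = (km1 km2 + km1 k3 + k2 k3)/(k1 (k2+km2+k3))
  fx <- paper_fixture("fig7_misincorporation", "two_step")
  set.seed(7)
  for (i in 1:50) {
    v <- param_values(fx$params) * exp(stats::runif(5, -2, 2))
    p <- set_param_values(fx$params, v)
    ss <- king_altman(fx$scheme, p, "dTTP")
    kcat_o <- v[["k2"]] * v[["k3"]] / (v[["k2"]] + v[["km2"]] + v[["k3"]])
    Km_o <- (v[["km1"]] * v[["km2"]] + v[["km1"]] * v[["k3"]] +
               v[["k2"]] * v[["k3"]]) /
      (v[["k1"]] * (v[["k2"]] + v[["km2"]] + v[["k3"]]))
    expect_rel_equal(ss$kcat, kcat_o, 1e-6)
    expect_rel_equal(ss$Km, Km_o, 1e-6)
  }
})

test_that("the published misincorporation constants give the published kinetics", {
  one <- paper_fixture("fig7_misincorporation", "one_step")
  ss1 <- king_altman(one$scheme, one$params, "dTTP")
  expect_equal(ss1$Km / 1000, 6.2, tolerance = 0.005)   # mM
  two <- paper_fixture("fig7_misincorporation", "two_step")
  ss2 <- king_altman(two$scheme, two$params, "dTTP")
  expect_equal(round(ss2$kcat, 2), 0.53)
  expect_equal(ss2$Km / 1000, 6.2, tolerance = 0.005)
  ## kcat/Km = K1 K2 k3 in the rapid-equilibrium regime
  expect_equal(ss2$kcat_over_Km_M, (100 / 930000) * 0.5 * 1.6 * 1e6,
               tolerance = 0.005)
  expect_equal(ss2$kcat_over_Km_M, 86, tolerance = 0.01)
  expect_equal(ss2$kcat_over_Km, ss2$kcat / ss2$Km, tolerance = 1e-10)
})

test_that("rapid-equilibrium approximations and their limits", {
  re <- rapid_equilibrium_approx(100, 930000, 170, 340, 1.6)
  expect_equal(re$kcat, 0.5 * 1.6 / 1.5, tolerance = 1e-12)
  expect_true(re$rapid_equilibrium)
  ## agreement with the full reduction in the km2 >> k3 regime
  two <- paper_fixture("fig7_misincorporation", "two_step")
  ss <- king_altman(two$scheme, two$params, "dTTP")
  expect_rel_equal(re$kcat, ss$kcat, 0.01)
  expect_rel_equal(re$Km, ss$Km, 0.01)
  ## convergence tightens as km2/k3 grows
  p4 <- set_param_values(two$params, c(km2 = 340 * 100))  # ratio 2.1e4
  re4 <- rapid_equilibrium_approx(100, 930000, 170, 34000, 1.6)
  ss4 <- king_altman(two$scheme, p4, "dTTP")
  expect_rel_equal(re4$kcat, ss4$kcat, 1e-4)
  ## K2 -> infinity: kcat -> k3, Km -> 0
  reK <- rapid_equilibrium_approx(100, 930000, 1e9, 1, 1.6)
  expect_equal(reK$kcat, 1.6, tolerance = 1e-6)
  expect_lt(reK$Km, 1e-3)
  ## inverting Km for the ground-state Kd: 6.2 mM, K2 = 0.5 -> 9.3 mM
  expect_equal(ground_state_Kd_from_Km(6200, 0.5), 9300)
})

test_that("discrimination indices reproduce the published screen", {
  expect_equal(discrimination_index(1.65e7, 143), 115400, tolerance = 0.005)
  expect_equal(discrimination_index(1.37e7, 1.4), 9.8e6, tolerance = 0.005)
  expect_equal(discrimination_index(1.56e7, 265), 59000, tolerance = 0.005)
  expect_equal(discrimination_index(5, 5), 1)
  expect_identical(discrimination_index(5, 0), Inf)
  ## invariant under common unit rescaling
  expect_equal(discrimination_index(1.65e-2, 143e-9),
               discrimination_index(1.65e7, 143), tolerance = 1e-12)
  dt <- discrimination_table()
  expect_true(all(dt$D[dt$is_correct] == 1))
  ## computed D within the printed rounding for every mismatch row
  m <- !dt$is_correct
  expect_rel_equal(dt$D[m], dt$discrimination_printed[m], 0.01)
  ## median over the 12 printed values: midpoint of the central pair
  printed <- dt
  printed$D <- printed$discrimination_printed
  s <- discrimination_summary(printed)
  expect_equal(s$median, 127500)
  expect_equal(s$n, 12L)
  expect_equal(s$min, 59000)
  one_row <- printed[printed$template == "T" & printed$dntp == "dGTP", ]
  s1 <- discrimination_summary(one_row)
  expect_equal(s1$median, s1$min)
  expect_equal(s1$median, s1$max)
  expect_error(discrimination_summary(printed[printed$is_correct, ]),
               "no mismatch")
})

test_that("free-energy barriers follow transition-state theory arithmetic", {
  k_ref <- 0.01 * 1.380649e-23 * 293 / 6.62607015e-34
  sc <- kinetic_scheme("one", c("A", "B"),
                       transitions = data.frame(from = "A", to = "B",
                                                kf = "k", kr = "km"))
  ## k = kappa kB T / h: barrier exactly 0
  pr0 <- free_energy_profile(sc, parameter_set(k = k_ref, km = 1),
                             ligand_concs = NULL)
  expect_equal(pr0$profile$level[pr0$profile$kind == "barrier"], 0,
               tolerance = 1e-9)
  ## k = 170 /s at 293 K: 11.47 kcal/mol
  pr1 <- free_energy_profile(sc, parameter_set(k = 170, km = 1),
                             ligand_concs = NULL)
  expect_equal(pr1$profile$level[pr1$profile$kind == "barrier"][1L],
               11.47, tolerance = 1e-3)
  expect_equal(highest_barrier(pr1), "A.B", ignore_attr = TRUE)
})

test_that("highest barrier is chemistry for a mismatch, conformational change for correct", {
  two <- paper_fixture("fig7_misincorporation", "two_step")
  prm <- free_energy_profile(two$scheme, two$params, c(dTTP = 175))
  expect_equal(as.character(highest_barrier(prm)), "FDT.EP")
  crs <- correct_reference_scheme()
  prc <- free_energy_profile(crs$scheme, crs$params, c(dNTP = 175))
  expect_equal(as.character(highest_barrier(prc)), "EDN.FDN")
  ## barrier ordering invariant: every reversible step's transition state
  ## sits above both adjacent states
  p <- prm$profile
  for (i in which(p$kind == "barrier")) {
    before <- p$level[i - 1L]
    after <- p$level[i + 1L]
    expect_gte(p$level[i], before - 1e-9)
    if (!is.na(after)) expect_gte(p$level[i], after - 1e-9)
  }
})

test_that("rescaling kappa shifts all barriers equally and keeps their order", {
  two <- paper_fixture("fig7_misincorporation", "two_step")
  a <- free_energy_profile(two$scheme, two$params, c(dTTP = 175), kappa = 0.01)
  b <- free_energy_profile(two$scheme, two$params, c(dTTP = 175), kappa = 1)
  ba <- a$profile$level[a$profile$kind == "barrier"]
  bb <- b$profile$level[b$profile$kind == "barrier"]
  shifts <- bb - ba
  expect_lt(max(shifts) - min(shifts), 1e-9)
  expect_identical(as.character(highest_barrier(a)),
                   as.character(highest_barrier(b)))
})
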