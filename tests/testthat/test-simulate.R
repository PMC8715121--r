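test_that("integration matches closed forms and the matrix-exponential oracle", {
  ab <- irreversible_ab(k = 1)
  tc <- integrate_scheme(ab$scheme, ab$params, c(A = 1), times = c(0, 1))
  expect_equal(tc$A[2L], exp(-1), tolerance = 1e-9)
  ## slowest relaxation of the binding scheme at 3 mM: rapid-equilibrium
  ## approximation kB2*S/(S + 1/KB1) + kmB2
  fx <- paper_fixture("fig3_binding")
  M <- rate_matrix(fx$scheme, fx$params, c(dTTP = 3000))
  lam <- sort(abs(Re(eigen(M)$values)))
  expect_equal(lam[2L], 310 * 3000 / (3000 + 1500) + 6.8, tolerance = 0.01)
  ## full product plateau equals the DNA total (conservation + terminal sink)
  f2 <- paper_fixture("fig2_sequential")
  tc2 <- integrate_scheme(f2$scheme, f2$params, c(ED27 = 0.075),
                          c(dTTP = 3000), times = c(0, 300))
  expect_equal(tc2$ED29[2L], 0.075, tolerance = 1e-4)
})

test_that("lsoda agrees with the matrix exponential across random parameter draws", {
  set.seed(42)
  fx <- paper_fixture("fig3_binding")
  times <- seq(0, 0.05, length.out = 21)
  for (i in 1:25) {
    vals <- param_values(fx$params) * exp(stats::runif(4, -1.5, 1.5))
    p <- set_param_values(fx$params, vals)
    a <- integrate_scheme(fx$scheme, p, c(ED = 0.2), c(dTTP = 1000),
                          times = times, method = "expm")
    b <- integrate_scheme(fx$scheme, p, c(ED = 0.2), c(dTTP = 1000),
                          times = times, method = "lsoda")
    expect_lt(max(abs(as.matrix(a[, -1]) - as.matrix(b[, -1]))) / 0.2, 1e-6)
  }
})

test_that("inner-filter factor is continuous at 0, decreasing, and matches arithmetic", {
  expect_equal(inner_filter_factor(0), 1)
  expect_equal(inner_filter_factor(1e-9), 1, tolerance = 1e-6)
  expect_equal(inner_filter_factor(1), (1 - 0.1) / log(10), tolerance = 1e-12)
  expect_equal(inner_filter_factor(1), 0.3908, tolerance = 1e-3)
  x <- 10^seq(-6, 2, length.out = 50)
  expect_true(all(diff(inner_filter_factor(x)) < 0))
  expect_error(inner_filter_factor(-0.1), "non-negative")
})

test_that("observable projection is linear in state factors", {
  ts <- two_state_scheme(1, 1)
  tc <- integrate_scheme(ts$scheme, ts$params, c(A = 1),
                         times = seq(0, 10, length.out = 11))
  ## all factors equal, q = 0: constant at A1 x pool
  sig <- project_observable(tc, observable_spec(A1 = 2))
  expect_equal(sig, rep(2, 11), tolerance = 1e-8)
  ## equal populations with b = (1, 2) give 1.5 x pool
  eq <- tc[nrow(tc), ]
  expect_equal(eq$A, eq$B, tolerance = 1e-6)
  sig2 <- project_observable(tc, observable_spec(A1 = 1,
                                                 state_factors = c(B = 2)))
  expect_equal(sig2[11L], 1.5, tolerance = 1e-5)
  expect_error(observable_spec(q = -1), "non-negative")
})

test_that("titration applies cumulative dilution and matches the quadratic root", {
  fx <- paper_fixture("fig3_binding")
  tt <- simulate_titration(fx$scheme, fx$params, c(ED = 0.1), 280, "dTTP",
                           rep(0.5, 41), 7500)
  expect_equal(tt$dilution[nrow(tt)], 280 / 300.5, tolerance = 1e-12)
  ## zero titrant: cell equilibrium is the initial state
  expect_equal(tt$ED[1L], 0.1)
  expect_equal(tt$EDT[1L] + tt$FDT[1L], 0)
  ## one-step binding: bound fraction equals the tight-binding quadratic
  os <- one_step_binding(kon = 10, koff = 100)   # Kd = 10 uM
  t1 <- simulate_titration(os$scheme, os$params, c(E = 1), 280, "L",
                           rep(2.05, 10), 1000)
  Kd <- 10
  for (i in seq_len(nrow(t1))) {
    Et <- 1 * t1$dilution[i]
    Lt <- t1$titrant_total[i]
    bound <- ((Et + Lt + Kd) - sqrt((Et + Lt + Kd)^2 - 4 * Et * Lt)) / 2
    expect_equal(t1$EL[i], bound, tolerance = 1e-8)
  }
})

test_that("trap decay reproduces the partitioning rate and its limits", {
  fx <- paper_fixture("fig3_binding")
  times <- seq(0, 1.2, length.out = 150)
  tc <- simulate_trap(fx$scheme, fx$params, c(ED = 1, dTTP = 5), "dTTP",
                      times)
  b <- attr(tc, "bound")
  expect_true(all(diff(b) < 0))
  f <- fit_exponentials(times, -b, 1)   # decay as rising exponential
  ## partitioning oracle: kmB2 kmB1/(kmB1 + kB2)
  expect_equal(f$rates[1L], 6.8 * 15000 / 15310, tolerance = 0.02)
  expect_equal(f$rates[1L], 6.6, tolerance = 0.05)
  ## no ternary complex at t = 0: flat zero bound signal
  tc0 <- simulate_trap(fx$scheme, fx$params, c(ED = 1), "dTTP", times)
  expect_equal(max(abs(attr(tc0, "bound"))), 0)
  ## limit kmB1/kB2 -> infinity: decay rate -> kmB2
  p <- set_param_values(fx$params, c(kmB1 = 310 * 1e4))
  tcL <- simulate_trap(fx$scheme, p, c(ED = 1, dTTP = 500), "dTTP",
                       seq(0, 1.2, length.out = 150))
  fL <- fit_exponentials(seq(0, 1.2, length.out = 150),
                         -attr(tcL, "bound"), 1)
  expect_equal(fL$rates[1L], 6.8, tolerance = 0.01)
  expect_error(simulate_trap(fx$scheme, fx$params, c(ED = 1), "ATP", times),
               "unknown ligand")
})

test_that("flux partition matches the pool-weighted oracle and its properties", {
  fx <- paper_fixture("fig5_extension")
  br <- list(unactivated = "k7", activated = "k10")
  init <- c(ED = 0.075)
  fr <- flux_partition(fx$scheme, fx$params, init, c(dTTP = 3000), br, 200)
  expect_true(fr[["activated"]] > 0.60)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  ## quasi-equilibrium pool estimate: FDT:GDT:GDTp = 1 : k6/km6 : k9 S/km9
  gdt <- 45 / 6.6; gdtp <- 0.007 * 3000 / 14
  oracle <- gdtp * 0.90 / (gdtp * 0.90 + gdt * 0.102)
  expect_equal(fr[["activated"]], oracle, tolerance = 0.05)
  ## t_end invariance beyond completion
  fr2 <- flux_partition(fx$scheme, fx$params, init, c(dTTP = 3000), br, 400)
  expect_lt(abs(fr2[["activated"]] - fr[["activated"]]), 0.005)
  ## no activation branch when k9 is off
  p0 <- set_param_values(fx$params, c(k9 = 1e-300))
  fr0 <- flux_partition(fx$scheme, p0, init, c(dTTP = 3000), br, 200)
  expect_equal(unname(fr0[["activated"]]), 0, tolerance = 1e-12)
  ## monotone in nucleotide concentration
  shares <- vapply(c(100, 250, 1000, 3000), function(S)
    flux_partition(fx$scheme, fx$params, init, c(dTTP = S), br,
                   6000 / (1 + S / 100))[["activated"]], numeric(1))
  expect_true(all(diff(shares) > 0))
  ## undefined fractions when nothing reacts
  expect_error(flux_partition(fx$scheme, fx$params, c(EP = 0.075),
                              c(dTTP = 3000), br, 10),
               "no product")
})
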