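test_that("chi-square matches its definition and scaling identity", {
  pr <- fig2_problem(sigma = 0)   # noiseless data
  ## data generated exactly by the parameters: chi-square is zero
  expect_lt(chi_square(pr), 1e-12)
  ## displacing one parameter raises it
  expect_gt(chi_square(pr, c(kB2 = 0.4)), 1)
  ## multiplying every sigma by sqrt(2) halves chi-square
  pr2 <- pr
  pr2$sigma <- lapply(pr$sigma, function(s) s * sqrt(2))
  x <- chi_square(pr, c(kB2 = 0.4))
  expect_equal(chi_square(pr2, c(kB2 = 0.4)), x / 2, tolerance = 1e-12)
  ## objective invariant to experiment ordering
  pr3 <- pr
  pr3$experiments <- rev(pr$experiments)
  pr3$sigma <- rev(pr$sigma)
  expect_equal(chi_square(pr3, c(kB2 = 0.4)), x, tolerance = 1e-12)
})

test_that("noiseless global refit recovers the generating constants to <1%", {
  pr <- fig2_problem(sigma = 0)
  truth <- param_values(pr$params, pr$free)
  fit <- kinfit(pr, start = truth * 2)
  expect_true(fit$converged)
  expect_rel_equal(fit$estimates[names(truth)], truth, 0.01)
  ## the printed constants themselves: 1/K'A1 7.7 mM, k'A2 0.68 /s,
  ## 1/K'B1 460 uM, k'B2 0.20 /s
  expect_equal(fit$estimates[["kmA1"]] / 10, 7700, tolerance = 0.01)
  expect_equal(fit$estimates[["kA2"]], 0.68, tolerance = 0.01)
  expect_equal(fit$estimates[["kmB1"]] / 10, 460, tolerance = 0.01)
  expect_equal(fit$estimates[["kB2"]], 0.20, tolerance = 0.01)
})

test_that("locking everything returns the start unchanged with its chi-square", {
  pr <- fig2_problem(sigma = 0.03)
  pr$float <- character(); pr$free <- character()
  fit <- kinfit(pr)
  expect_identical(fit$estimates, numeric(0))
  expect_equal(fit$chi2, chi_square(pr), tolerance = 1e-12)
})

test_that("per-trace scaling recovers multipliers; analytic equals fitted mode", {
  ex <- generate_stopped_flow_dataset(
    generator_config("fig3_binding", seed = 5,
                     noise = noise_model("gaussian-absolute", 0, 5)))
  ## scale one trace by 1.3
  ex$traces[[3L]]$data <- 1.3 * ex$traces[[3L]]$data
  params <- paper_fixture("fig3_binding")$params
  pr0 <- fit_problem(list(ex), params)
  pr_an <- apply_per_trace_scaling(pr0, 1, "analytic")
  ## with analytic profiling the mismatch vanishes at the true constants
  expect_lt(chi_square(pr_an), 1e-12)
  expect_gt(chi_square(pr0), 1)
  ## fitted multipliers reproduce the analytic ones
  pr_fit <- apply_per_trace_scaling(pr0, 1, "fit")
  fit <- kinfit(pr_fit)
  sc <- fit$estimates[grep("^scale\\.", names(fit$estimates))]
  expect_equal(unname(sc[3L]), 1.3, tolerance = 1e-4)
  expect_equal(unname(sc[-3L]), rep(1, length(sc) - 1L), tolerance = 1e-4)
  ## nesting: allowing scaling can only decrease chi-square
  ex_noisy <- generate_stopped_flow_dataset(
    generator_config("fig3_binding", seed = 6,
                     noise = noise_model("gaussian-absolute", 0.01, 6)))
  prA <- fit_problem(list(ex_noisy), params)
  prB <- apply_per_trace_scaling(prA, 1, "analytic")
  expect_lte(chi_square(prB), chi_square(prA))
  expect_error(apply_per_trace_scaling(pr0, 1, "bogus"))
})

test_that("linked parameters come out exactly equal", {
  ## same mechanism measured in two experiments; ground-state off-rate and
  ## isomerization linked across them through duplicated parameter names
  exA <- generate_stopped_flow_dataset(
    generator_config("fig3_binding", seed = 7,
                     noise = noise_model("gaussian-absolute", 0.005, 7)))
  ## second copy of the scheme with renamed parameters
  fx <- paper_fixture("fig3_binding")
  sc2 <- fx$scheme
  sc2$name <- "fig3_copy"
  sc2$transitions$kf <- c("kB1.b", "kB2.b")
  sc2$transitions$kr <- c("kmB1.b", "kmB2.b")
  exB <- exA
  exB$scheme <- sc2
  both <- parameter_set(
    kB1 = list(value = 10, units = "/uM/s", locked = TRUE),
    kmB1 = 12000, kB2 = 250, kmB2 = 5,
    kB1.b = list(value = 10, units = "/uM/s", locked = TRUE),
    kmB1.b = 12000, kB2.b = 250, kmB2.b = 5)
  pr <- fit_problem(list(exA, exB), both,
                    links = list(c("kmB1", "kmB1.b"), c("kB2", "kB2.b"),
                                 c("kmB2", "kmB2.b")))
  fit <- kinfit(pr)
  v <- param_values(fit$params)
  expect_identical(v[["kmB1"]], v[["kmB1.b"]])
  expect_identical(v[["kB2"]], v[["kB2.b"]])
  expect_equal(v[["kB2"]], 310, tolerance = 0.05)
})

test_that("kinfit methods behave like a standard model object", {
  pr <- fig2_problem(sigma = 0.03)
  fit <- kinfit(pr)
  expect_s3_class(fit, "kinfit")
  expect_named(coef(fit), pr$free)
  expect_equal(deviance(fit), fit$chi2)
  expect_equal(length(residuals(fit)), fit$n_points)
  expect_output(print(fit), "chi-square")
  expect_output(print(summary(fit)), "per-experiment")
  pred <- predict(fit, 1)
  expect_equal(length(pred), length(pr$experiments[[1L]]$traces))
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  sims2 <- simulate(fit, nsim = 2, seed = 3)
  expect_identical(sims, sims2)
  ## plotting runs without error
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit, 1))
})
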