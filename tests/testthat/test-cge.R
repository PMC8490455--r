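test_that("the unshocked model replicates the benchmark SAM flows", {
  eco <- small_economy(n_regions = 3, trade = 0.25, seed = 7)
  params <- calibrateCGE(eco)
  sol <- solveCGE(params)
  expect_lt(max(abs(sol$X - eco$X) / eco$X), 1e-8)
  expect_lt(max(abs(sol$L - eco$L_pay) / eco$L_pay), 1e-8)
  expect_lt(max(abs(sol$p - 1)), 1e-8)
  expect_equal(sol$gdp$gdp_real, sol$gdp$gdp_benchmark, tolerance = 1e-10)
})

test_that("within-country import elasticities carry the 20% border markup", {
  eco <- generateToyEconomy(toyEconomyConfig(n_regions = 4, n_countries = 2,
                                             trade_openness = 0.2,
                                             seed = 8))
  params <- calibrateCGE(eco, list(sigma_va = 1, sigma_arm = 2,
                                   sigma_imp = 4))
  # regions 1-2 share a country; 3-4 share the other
  expect_equal(params$sigma_imp[1, 2] / params$sigma_imp[1, 3], 1.2)
  expect_equal(params$sigma_imp[1, 2], 4 * 1.2)
  expect_equal(params$sigma_imp[1, 3], 4)
})

test_that("Cobb-Douglas calibration uses SAM value-added shares", {
  eco <- small_economy(seed = 9)
  params <- calibrateCGE(eco, list(sigma_va = 1, sigma_arm = 2,
                                   sigma_imp = 4))
  expect_equal(params$thL,
               eco$L_pay / (eco$L_pay + eco$K_pay), tolerance = 1e-12)
  # CRESH sourcing over several import partners needs sigma_imp > 1
  eco3 <- small_economy(n_regions = 3, seed = 9)
  expect_error(calibrateCGE(eco3, list(sigma_imp = 0.8)), "sigma_imp")
})

test_that("productivity shocks scale psi and compose multiplicatively", {
  eco <- small_economy(seed = 10)
  params <- calibrateCGE(eco)
  t1 <- data.frame(region = "R01", sector = "AGR", tau = 0.1)
  p1 <- applyShock(params, t1)
  expect_equal(p1$psi["R01", "AGR"], 0.9)
  expect_true(all(p1$psi[p1$psi != 0.9] == 1))
  p2 <- applyShock(p1, data.frame(region = "R01", sector = "AGR",
                                  tau = 0.2))
  expect_equal(p2$psi["R01", "AGR"], 0.9 * 0.8)
  expect_error(applyShock(params, data.frame(region = "R01",
                                             sector = "AGR", tau = 1)),
               "tau")
  p0 <- applyShock(params, data.frame(region = "R01", sector = "AGR",
                                      tau = 0))
  expect_identical(p0$psi, params$psi)
})

test_that("a uniform shock to a no-intermediates Cobb-Douglas economy matches the closed form", {
  eco <- generateToyEconomy(toyEconomyConfig(n_regions = 1,
                                             io_density = 0,
                                             trade_openness = 0, seed = 11))
  params <- calibrateCGE(eco, list(sigma_va = 1, sigma_arm = 2,
                                   sigma_imp = 4))
  bench <- solveCGE(params)
  tau <- 0.15
  shock <- data.frame(region = "R01", sector = eco$sectors$sector,
                      tau = tau)
  sol <- solveCGE(applyShock(params, shock))
  # with fixed factors and Cobb-Douglas demand, each sector's real value
  # added scales by (1 - tau)^theta_L
  thL <- eco$L_pay / (eco$L_pay + eco$K_pay)
  expect_equal(as.vector(sol$VAq / bench$VAq),
               as.vector((1 - tau)^thL), tolerance = 1e-7)
  gdp_expected <- sum(bench$VAq * (1 - tau)^thL) / sum(bench$VAq) - 1
  expect_equal(sol$gdp$gdp_real / bench$gdp$gdp_real - 1, gdp_expected,
               tolerance = 1e-7)
})

test_that("shocks do not transmit between autarkic regions", {
  eco <- generateToyEconomy(toyEconomyConfig(n_regions = 2,
                                             trade_openness = 0,
                                             seed = 12))
  params <- calibrateCGE(eco)
  bench <- solveCGE(params)
  sol <- solveCGE(applyShock(params, data.frame(region = "R01",
                                                sector = "AGR",
                                                tau = 0.2)))
  imp <- impactReport(sol, bench)
  expect_lt(imp$regional$gdp_pct[imp$regional$region == "R01"], -0.1)
  expect_equal(imp$regional$gdp_pct[imp$regional$region == "R02"], 0,
               tolerance = 1e-6)
})

test_that("Walras' law holds at the solution and the system is homogeneous", {
  eco <- small_economy(n_regions = 2, trade = 0.3, seed = 13)
  params <- calibrateCGE(eco)
  sol <- solveCGE(applyShock(params, data.frame(region = "R01",
                                                sector = "AGR",
                                                tau = 0.1)))
  expect_lt(abs(sol$diagnostics$walras), 1e-7)
  # scaling every price by a common factor leaves real quantities unchanged
  z <- log(c(t(sol$p), sol$w, sol$rk))
  sys0 <- heatshock:::cge_system(params, z)
  sys1 <- heatshock:::cge_system(params, z + log(3))
  expect_equal(sys1$X, sys0$X, tolerance = 1e-9)
  expect_equal(sys1$Ld, sys0$Ld, tolerance = 1e-9)
})

test_that("aggregate GDP losses grow with the shock size", {
  eco <- small_economy(n_regions = 2, trade = 0.2, seed = 14)
  params <- calibrateCGE(eco)
  bench <- solveCGE(params)
  losses <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(tau) {
    if (tau == 0) return(0)
    sol <- solveCGE(applyShock(params, data.frame(region = "R01",
                                                  sector = "AGR",
                                                  tau = tau)))
    sum(bench$VAq) - sum(sol$VAq)
  }, numeric(1))
  expect_true(all(diff(losses) > 0))
})

test_that("more elastic trade buffers the shocked region's GDP loss", {
  eco <- generateToyEconomy(toyEconomyConfig(n_regions = 2,
                                             trade_openness = 0.3,
                                             seed = 15))
  shock <- data.frame(region = "R01", sector = "AGR", tau = 0.25)
  loss_at <- function(sa, si) {
    params <- calibrateCGE(eco, list(sigma_va = 1, sigma_arm = sa,
                                     sigma_imp = si))
    bench <- solveCGE(params)
    sol <- solveCGE(applyShock(params, shock))
    r <- impactReport(sol, bench)$regional
    -r$gdp_pct[r$region == "R01"]
  }
  rigid <- loss_at(1.5, 2)
  fluid <- loss_at(4, 8)
  expect_lte(fluid, rigid)
})

test_that("sectoral contributions decompose the regional GVA change exactly", {
  eco <- small_economy(n_regions = 2, trade = 0.2, io = 0.4, seed = 16)
  params <- calibrateCGE(eco)
  bench <- solveCGE(params)
  sol <- solveCGE(applyShock(params, data.frame(region = "R01",
                                                sector = "AGR",
                                                tau = 0.2)))
  imp <- impactReport(sol, bench)
  agg <- aggregate(contribution_pp ~ region, imp$sectoral, sum)
  expect_lt(max(abs(agg$contribution_pp -
                      imp$regional$gdp_pct[match(agg$region,
                                                 imp$regional$region)])),
            1e-10)
  # identical solutions give all-zero changes
  imp0 <- impactReport(bench, bench)
  expect_true(all(imp0$regional$gdp_pct == 0))
  expect_true(all(imp0$sectoral$contribution_pp == 0))
})

test_that("an outdoor shock propagates to indoor sectors through intermediate use", {
  eco <- small_economy(n_regions = 1, trade = 0, io = 0.5, seed = 17)
  params <- calibrateCGE(eco)
  bench <- solveCGE(params)
  sol <- solveCGE(applyShock(params, data.frame(region = "R01",
                                                sector = "AGR",
                                                tau = 0.3)))
  imp <- impactReport(sol, bench)
  indoor <- imp$sectoral[imp$sectoral$sector != "AGR", ]
  expect_true(all(indoor$contribution_pp < 0))
})
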