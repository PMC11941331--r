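make_theory_ar1 <- function(p1 = 3, p2 = 6, rho = 0.5,
                            d1 = rep(1, p1) / sqrt(p1),
                            delta = rep(0.3, p2)) {
  sg <- make_ar1_covariance(p1 + p2, rho)
  i1 <- seq_len(p1); i2 <- p1 + seq_len(p2)
  theory_inputs(sg[i1, i1], sg[i1, i2], sg[i2, i2], d1, delta)
}

test_that("Schur complements match hand computations and stay PSD", {
  # independent blocks: conditioning changes nothing
  out0 <- conditional_covariances(diag(2), matrix(0, 2, 3), diag(3))
  expect_equal(out0$sigma_s1_given_s2, diag(2))
  # 2x2 AR(1): 1 - rho^2 = 0.75
  out <- conditional_covariances(matrix(1), matrix(0.5), matrix(1))
  expect_equal(out$sigma_s1_given_s2, matrix(0.75))
  expect_equal(out$sigma_s2_given_s1, matrix(0.75))
  # PSD on a larger random-ish block
  sg <- make_ar1_covariance(8, 0.7)
  outl <- conditional_covariances(sg[1:3, 1:3], sg[1:3, 4:8], sg[4:8, 4:8])
  expect_gt(min(eigen(outl$sigma_s1_given_s2)$values), -1e-10)
  expect_gt(min(eigen(outl$sigma_s2_given_s1)$values), -1e-10)
  expect_error(conditional_covariances(diag(2), matrix(0, 2, 2),
                                       matrix(0, 2, 2)), "singular")
})

test_that("the non-central chi-square CDF behaves like a CDF", {
  # central chi-square with 2 df is Exp(1/2): median at 2 log 2
  expect_equal(noncentral_chisq_cdf(2 * log(2), 2, 0), 0.5)
  expect_equal(noncentral_chisq_cdf(0, 5, 3), 0)
  xs <- seq(0, 30, length.out = 50)
  vals <- noncentral_chisq_cdf(xs, 4, 2.5)
  expect_true(all(diff(vals) >= 0))
  # Monte Carlo agreement at several quantiles
  set.seed(10)
  draws <- rchisq(1e6, df = 4, ncp = 2.5)
  for (x in c(1, 3, 6, 10, 15)) {
    mc <- mean(draws <= x)
    se <- sqrt(mc * (1 - mc) / 1e6)
    expect_lt(abs(noncentral_chisq_cdf(x, 4, 2.5) - mc), 3 * se + 1e-12)
  }
  expect_error(noncentral_chisq_cdf(-1, 2, 0), "nonnegative")
})

test_that("chi-square inverse moments match closed forms to 1e-8", {
  for (nu in c(5, 6, 8, 12, 30)) {
    expect_lt(abs(chisq_inverse_moment(nu, 0, 1) - 1 / (nu - 2)), 1e-8)
    expect_lt(abs(chisq_inverse_moment(nu, 0, 2) - 1 / ((nu - 2) * (nu - 4))),
              1e-8)
  }
  expect_error(chisq_inverse_moment(2, 0, 1), "diverges")
  expect_error(chisq_inverse_moment(4, 0, 2), "diverges")
})

test_that("non-central inverse moments match a Monte Carlo oracle", {
  set.seed(77)
  draws <- rchisq(1e6, df = 6, ncp = 3)
  inv1 <- 1 / draws
  mc <- mean(inv1); se <- sd(inv1) / 1000
  expect_lt(abs(chisq_inverse_moment(6, 3, 1) - mc), 3 * se)
  # second order
  draws8 <- rchisq(1e6, df = 8, ncp = 2)
  inv2 <- 1 / draws8^2
  mc2 <- mean(inv2); se2 <- sd(inv2) / 1000
  expect_lt(abs(chisq_inverse_moment(8, 2, 2) - mc2), 3 * se2)
  # truncated version against the same draws
  tr <- (1 / draws) * (draws < 4)
  mct <- mean(tr); set <- sd(tr) / 1000
  expect_lt(abs(chisq_inverse_moment(6, 3, 1, upper = 4) - mct), 3 * set)
})

test_that("truncated and tail moments add up to the full moment", {
  for (t in c(2, 5, 10)) {
    full <- chisq_inverse_moment(7, 1.5, 1)
    low <- chisq_inverse_moment(7, 1.5, 1, upper = t)
    # tail by quadrature oracle
    tail <- integrate(function(x) dchisq(x, 7, ncp = 1.5) / x, t, Inf,
                      rel.tol = 1e-10)$value
    expect_equal(low + tail, full, tolerance = 1e-8)
  }
  # moments are nonincreasing in the non-centrality
  ms <- vapply(c(0, 1, 3, 8), function(ncp) chisq_inverse_moment(9, ncp, 1),
               numeric(1))
  expect_true(all(diff(ms) < 0))
})

test_that("the non-centrality functional is a ratio of quadratic forms", {
  # scalar blocks: Delta = (sigma12 delta / sigma11)^2 / s2^2 with
  # s2^2 = d2^2 / sigma_{2|1}; hand-substitute
  s11 <- 2; s12 <- 0.6; s22 <- 1.5; d1 <- 0.9; dl <- 1.3
  ti <- theory_inputs(matrix(s11), matrix(s12), matrix(s22), d1, dl)
  d2 <- s12 * d1 / s11
  cond <- s22 - s12^2 / s11
  expect_equal(delta_ncp(ti), (d2 * dl)^2 / (d2^2 / cond))

  ti0 <- make_theory_ar1(delta = rep(0, 6))
  expect_equal(delta_ncp(ti0), 0)
  # quadratic homogeneity in delta
  tia <- make_theory_ar1(delta = rep(0.2, 6))
  tib <- make_theory_ar1(delta = rep(0.6, 6))
  expect_equal(delta_ncp(tib), 9 * delta_ncp(tia), tolerance = 1e-10)
})

test_that("asymptotic bias values follow the printed structure", {
  ti <- make_theory_ar1()
  adb <- adb_values(ti)
  expect_equal(adb[["wr"]], 0)
  # zero weak signals: no bias anywhere
  adb0 <- adb_values(make_theory_ar1(delta = rep(0, 6)))
  expect_equal(unname(adb0), rep(0, 4))
  # large non-centrality: shrinkage bias vanishes
  tibig <- make_theory_ar1(delta = rep(40, 6))
  adbig <- adb_values(tibig)
  expect_lt(abs(adbig[["se"]]), abs(adbig[["re"]]) * 1e-2)
})

test_that("asymptotic risks reproduce the dominance orderings", {
  ti <- make_theory_ar1()
  adr <- adr_values(ti)
  expect_equal(adr[["wr"]], 1)
  expect_true(all(adr >= 0))
  expect_lte(adr[["pse"]], adr[["se"]] + 1e-12)
  expect_lte(adr[["se"]], adr[["wr"]] + 1e-12)

  # RE risk formula: c + (1 - c) Delta
  expect_equal(adr[["re"]], ti$c + (1 - ti$c) * delta_ncp(ti))

  # delta = 0, several weak dimensions: RE < PSE <= WR
  for (p2 in c(6, 10, 20)) {
    adr0 <- adr_values(make_theory_ar1(p2 = p2, delta = rep(0, p2)))
    expect_lt(adr0[["re"]], adr0[["pse"]])
    expect_lte(adr0[["pse"]], adr0[["wr"]] + 1e-12)
  }
  expect_error(adr_values(make_theory_ar1(p2 = 4, delta = rep(0, 4))), "p2")
})

test_that("the dominance map holds ordering (i) on the unit ball and is even in delta", {
  base <- make_theory_ar1(delta = rep(1, 6) / sqrt(6)) # ||delta|| = 1
  dm <- dominance_map(base, seq(0, 1, length.out = 20))
  expect_true(all(dm$ord_pse_se_wr))
  expect_true(all(dm$adr_wr == 1))
  # symmetry: Delta depends on delta delta'
  neg <- make_theory_ar1(delta = -rep(1, 6) / sqrt(6))
  expect_equal(adr_values(neg), adr_values(base))
})

test_that("Monte Carlo normalized risk matches the theory for WR and RE", {
  # small design, known information, local alternatives; moderate replicate
  # count keeps the runtime down while 3 MC SEs give a meaningful band
  wr <- mc_normalized_risk(n = 2000, replicates = 300, seed = 31)
  expect_lt(abs(wr$risk - wr$theory), 3 * wr$mc_se)
  re <- mc_normalized_risk(n = 2000, replicates = 300, seed = 31,
                           estimator = "re")
  expect_lt(abs(re$risk - re$theory), 3 * re$mc_se)
  # the restricted theory risk is below 1 in this near-null design
  expect_lt(re$theory, 1)
})
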