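stats_row <- function(p, n_pairs = 1e5, axon_total = 1e5 * 100) {
  data.frame(pathway = "A:B", pre_mtype = "A", post_mtype = "B",
             s_m_struc = 1 / p, p = p, n_pairs_apposed = n_pairs,
             total_axon_length_um = axon_total)
}

test_that("geometric fit is the reciprocal mean with strict input checks", {
  expect_equal(fit_geometric(rep(1L, 10)), 1)
  expect_equal(fit_geometric(c(1, 2, 3, 4)), 0.4)
  # a structural mean of 3.79 appositions per connection
  expect_equal(fit_geometric(rep(3.79, 5)), 0.2638522, tolerance = 1e-6)
  expect_error(fit_geometric(integer(0)), "empty")
  expect_error(fit_geometric(c(1, 0, 2)), ">= 1")
})

test_that("constraint prediction applies the two structural fits and floors", {
  ee <- predict_constraints(stats_row(1 / 2.01), "EE")
  expect_equal(ee$s_m, 3.015)
  expect_equal(ee$s_sd, 0.9648)
  expect_equal(ee$b_d, 0.2)

  other <- predict_constraints(stats_row(1 / 3.05), "other")
  expect_equal(other$s_m, 9 * sqrt(2.05) - 2, tolerance = 1e-12)
  expect_equal(other$s_m, 10.88604, tolerance = 1e-5)

  # raw square-root fit would give -2 at s_m_struc = 1: floored to 1
  floor_case <- predict_constraints(stats_row(1), "other")
  expect_equal(floor_case$s_m, 1.0)
  expect_gt(floor_case$s_sd, 0.5)

  bad <- stats_row(0.5); bad$s_m_struc <- 0.9
  expect_error(predict_constraints(bad, "EE"), ">= 1")

  # per-m-type biological bouton densities override the fallback
  bd_tab <- data.frame(m_type = "A", bio = 0.15)
  expect_equal(predict_constraints(stats_row(0.5), "EE",
                                   b_d_table = bd_tab)$b_d, 0.15)
})

test_that("parameter derivation reproduces the closed forms", {
  # representative thick-tufted pyramidal pathway: structural mean 3.79,
  # predicted S_m = 5.685 and S_sd = 0.32 * S_m = 1.8192
  st <- stats_row(0.26385)
  cons <- data.frame(s_m = 5.685, s_sd = 1.8192, b_d = 0.2)
  par <- derive_parameters(st, cons)
  expect_equal(par$p_prime, 0.4311832, tolerance = 1e-6)
  expect_equal(par$f1, 0.4728261, tolerance = 1e-6)
  expect_equal(par$mu2, 4.3658)
  expect_false(par$f1_clamped)

  # if the target SD equals the structural SD regime (p' = p), f1 = 1 exactly
  st2 <- stats_row(0.4)
  cons2 <- data.frame(s_m = 4, s_sd = 1 / 0.4 - 0.5, b_d = 0.2)
  expect_equal(derive_parameters(st2, cons2)$f1, 1)

  # S_m = S_sd collapses the sigmoid offset to 0.5
  cons3 <- data.frame(s_m = 1.8, s_sd = 1.8, b_d = 0.2)
  expect_equal(derive_parameters(st, cons3)$mu2, 0.5)

  expect_error(derive_parameters(st, data.frame(s_m = 3, s_sd = 0.4,
                                                b_d = 0.2)), "0.5")
})

test_that("a clamped f1 re-solves mu2 to preserve the S_m priority", {
  # an already narrow input (p = 0.9) cannot be thinned to a wider target:
  # f1 clamps at 1 and mu2 absorbs the S_m constraint
  st <- stats_row(0.9)
  cons <- data.frame(s_m = 4, s_sd = 2, b_d = 0.2)
  par <- derive_parameters(st, cons)
  expect_true(par$f1_clamped)
  expect_equal(par$f1, 1)
  es <- expected_survival(0.9, 1, par$mu2)
  expect_equal(es$mean_synapses, 4, tolerance = 1e-3)
})

test_that("expected_survival limits and reserve bookkeeping are exact", {
  # no pruning limit: everything survives and the mean is the geometric mean
  es <- expected_survival(p = 0.25, f1 = 1, mu2 = 1e-3)
  expect_equal(es$survival_fraction, 1, tolerance = 1e-9)
  expect_equal(es$mean_synapses, 4, tolerance = 1e-6)

  es0 <- expected_survival(p = 0.25, f1 = 0, mu2 = 4)
  expect_equal(es0$survival_fraction, 0)
  expect_equal(es0$b2, 0)

  # b2 is the surviving synapse count over the presynaptic axon length
  es2 <- expected_survival(p = 0.25, f1 = 1, mu2 = 1e-3,
                           n_connections = 1000, total_axon_length = 2e4)
  expect_equal(es2$b2, 1000 * 4 / 2e4, tolerance = 1e-6)

  # a3 = b_d / b2, clamped with a flag, and the reserve-rule warning trips
  # whenever fewer than half of the viable connections stay in reserve
  st <- stats_row(0.25, n_pairs = 1000, axon_total = 2e4)
  cons <- data.frame(s_m = 5, s_sd = 1.6, b_d = 0.5)
  par <- derive_parameters(st, cons)
  expect_true(par$a3_clamped)
  expect_equal(par$a3, 1)
  expect_true(par$reserve_rule_warning)
  cons$b_d <- 0.005
  par2 <- derive_parameters(st, cons)
  expect_false(par2$a3_clamped)
  expect_false(par2$reserve_rule_warning)
  expect_equal(par2$a3, 0.005 / par2$b2, tolerance = 1e-9)
})

test_that("analytic survival matches Monte-Carlo within sampling error", {
  set.seed(404)
  for (i in 1:5) {
    p <- runif(1, 0.15, 0.5)
    f1 <- runif(1, 0.3, 0.9)
    mu2 <- runif(1, 2, 6)
    es <- expected_survival(p, f1, mu2)
    n <- 2e5
    k <- rgeom(n, p) + 1L
    j <- rbinom(n, k, f1)
    keep <- j >= 1 & runif(n) < sigmoid_acceptance(j, mu2)
    se_frac <- sqrt(es$survival_fraction * (1 - es$survival_fraction) / n)
    expect_lt(abs(mean(keep) - es$survival_fraction), 4 * se_frac)
    se_mean <- sd(j[keep]) / sqrt(sum(keep))
    expect_lt(abs(mean(j[keep]) - es$mean_synapses), 4 * se_mean)
  }
})

test_that("the axon-length/bouton-density budget closes on toy circuits", {
  # constructed so S_m * Chat_p * Chat_d = A_l * B_d exactly
  pw <- data.frame(pre_mtype = "A", post_mtype = "B", s_m = 5, c_p_hat = 0.1,
                   c_d_hat = 100, known = TRUE, n_appositions = 10)
  pre <- data.frame(m_type = "A", a_l = 250, b_d = 0.2)
  res <- check_budget(pw, pre)
  expect_equal(res$residuals$residual, 0)

  # doubling the target density doubles the budget: residual +100 %
  pw2 <- pw; pw2$c_d_hat <- 200
  expect_equal(check_budget(pw2, pre)$residuals$residual, 1)

  # a known pathway consuming half the budget leaves the other half for the
  # unknown pathway under the Peters'-rule split
  pw3 <- rbind(pw, data.frame(pre_mtype = "A", post_mtype = "C",
                              s_m = NA, c_p_hat = NA, c_d_hat = NA,
                              known = FALSE, n_appositions = 30))
  pw3$s_m[1] <- 2.5  # known product = 25 = half of 50
  res3 <- check_budget(pw3[, names(pw)], pre)
  expect_equal(res3$unknown_allocation$allocated_product, 25)

  # two unknown pathways split proportionally to apposition counts
  pw4 <- rbind(pw3, data.frame(pre_mtype = "A", post_mtype = "D",
                               s_m = NA, c_p_hat = NA, c_d_hat = NA,
                               known = FALSE, n_appositions = 10))
  res4 <- check_budget(pw4, pre)
  expect_equal(res4$unknown_allocation$allocated_product, c(18.75, 6.25))

  expect_error(check_budget(pw, data.frame(m_type = "A", a_l = NA,
                                           b_d = 0.2)), "missing")
})
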