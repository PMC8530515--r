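test_that("stop-codon degeneracy correction", {
  expect_equal(stop_codon_delta(0, 0.7), 0)
  expect_equal(stop_codon_delta(0.5, 0.5), 0.5)
  expect_equal(stop_codon_delta(0.1, 0.3), 0.06)
  expect_error(stop_codon_delta(0.8, 0.3), "<= 1")
  expect_error(stop_codon_delta(-0.1, 0.3), "fractions")
})

test_that("termination time is the sum of two inverse binding waits", {
  p <- tlf_params_default()
  s <- toy_specs(kon = c(RFI = 4e4, RF4 = 4e4),
                 len = c(RFI = 362, RF4 = 185))
  lv <- c(RFI = 1e-3, RF4 = 1e-3)
  expect_equal(as.numeric(tau_termination(lv, s, p)), 0.05)
  # homogeneity of degree -1
  expect_equal(as.numeric(tau_termination(2 * lv, s, p)), 0.025)
  # release-only limit when recycling is instantaneous
  lv2 <- c(RFI = 1e-3, RF4 = 1e9)
  expect_equal(as.numeric(tau_termination(lv2, s, p)), 1 / (4e4 * 1e-3),
               tolerance = 1e-9)
  # vanishing factor yields an explicit divergent time, not an error
  expect_identical(as.numeric(tau_termination(c(RFI = 0, RF4 = 1e-3), s, p)),
                   Inf)
  # catalytic mode adds 1/kcat per step and sequesters factor mass
  s2 <- toy_specs(kon = c(RFI = 4e4, RF4 = 4e4),
                  len = c(RFI = 362, RF4 = 185),
                  kcat = c(RFI = 2, RF4 = 2))
  t_cat <- tau_termination(lv, s2, p, mode = "catalytic", lambda = 1e-4)
  expect_gt(as.numeric(t_cat), 0.05 + 2 * (1 / 2) - 1e-9)
})

test_that("per-codon elongation time carries the codon-specificity rescale", {
  p <- tlf_params_default()
  s <- toy_specs(kon = c(`EF-Tu` = 4e4, `EF-G` = 4e4),
                 len = c(`EF-Tu` = 394, `EF-G` = 704))
  expect_equal(tau_codon(2e-2, 1e-2, s, p), 1 / 40 + 1 / 400)
  # no coarse-graining: n_aa = 1 removes the rescale
  p1 <- global_params(n_aa = 1)
  expect_equal(tau_codon(2e-2, 1e-2, s, p1), 1 / 800 + 1 / 400)
  # strictly decreasing in both factor levels
  expect_gt(tau_codon(1e-2, 1e-2, s, p), tau_codon(2e-2, 1e-2, s, p))
  expect_gt(tau_codon(2e-2, 5e-3, s, p), tau_codon(2e-2, 1e-2, s, p))
})

test_that("initiation time is additive over its waiting sub-steps", {
  p <- tlf_params_default()
  s <- tlf_specs_default()
  bracket <- 1 + (890 + 180) / p$len_ribo
  kon <- function(nm) s$kon[s$name == nm]
  # construct levels so that each of the four binding sub-steps waits 0.25 s
  lv <- c(IF1 = bracket / (kon("IF1") * 0.25),
          IF2 = 0.75 / (kon("IF2") * 0.25),
          IF3 = 0.75 / (kon("IF3") * 0.25),
          `50S` = 1 / (kon("50S") * 0.25))
  expect_equal(as.numeric(tau_initiation(lv, s, p)), 1.0, tolerance = 1e-12)
  # disabling a sub-step removes exactly its term
  lv2 <- lv; lv2[["IF3"]] <- Inf
  expect_equal(as.numeric(tau_initiation(lv2, s, p)), 0.75,
               tolerance = 1e-12)
  # degenerate limit: a single active binding step
  lv3 <- c(IF1 = lv[["IF1"]], IF2 = Inf, IF3 = Inf, `50S` = Inf)
  expect_equal(as.numeric(tau_initiation(lv3, s, p)), 0.25,
               tolerance = 1e-12)
})

test_that("growth law links active ribosomes, cycle time and rescaling factor", {
  p <- tlf_params_default()
  lv <- c(dummy = p$phi_tl - p$phi_ribo_inactive - 0.2)  # phi_act = 0.2
  cyc <- structure(list(tau_tl = 60), class = "tlf_cycle")
  expect_equal(growth_rate(lv, cyc, p), 9.13242e-5, tolerance = 1e-5)
  cyc2 <- structure(list(tau_tl = 30), class = "tlf_cycle")
  expect_equal(growth_rate(lv, cyc2, p), 2 * growth_rate(lv, cyc, p))
  expect_equal(p$len_ribo / p$avg_len, 36.5)
  expect_error(growth_rate(c(dummy = 0.5), cyc, p), "allocation infeasible")
})

test_that("steady-state ribosome occupancies equalize step fluxes", {
  p <- tlf_params_default()
  s <- tlf_specs_default()
  lv <- tlf_levels_default()
  cyc <- cycle_times(lv, s, p, phi_TC = lv[["EF-Tu"]])
  expect_equal(cyc$tau_tl, cyc$tau_ini + cyc$tau_el + cyc$tau_ter,
               tolerance = 1e-12)
  expect_equal(cyc$tau_el, p$avg_len * cyc$tau_aa, tolerance = 1e-12)
  phi_act <- p$phi_tl - p$phi_ribo_inactive - sum(lv)
  occ <- ribosome_occupancies(cyc, phi_act)
  expect_equal(sum(occ), phi_act, tolerance = 1e-12)
  lam <- growth_rate(lv, cyc, p)
  flux <- occ / c(cyc$tau_ini, cyc$tau_el, cyc$tau_ter)
  expect_rel(unname(flux),
             rep(lam * p$len_ribo / p$avg_len, 3), 1e-10)
  # symmetric cycle: equal occupation thirds
  cyc_sym <- structure(list(tau_ini = 1, tau_el = 1, tau_ter = 1,
                            tau_tl = 3), class = "tlf_cycle")
  expect_equal(unname(ribosome_occupancies(cyc_sym, 0.3)),
               rep(0.1, 3))
  cyc0 <- structure(list(tau_ini = 1, tau_el = 2, tau_ter = 0, tau_tl = 3),
                    class = "tlf_cycle")
  expect_equal(unname(ribosome_occupancies(cyc0, 0.3))[3], 0)
})

test_that("factor waits scale-consistently and decrease convexly in levels", {
  p <- tlf_params_default()
  s <- tlf_specs_default()
  lv <- tlf_levels_default()
  # multiplying kon by c and dividing phi by c leaves waits unchanged
  s2 <- s; c <- 3.7
  s2$kon <- s2$kon * c
  lv2 <- lv / c
  t1 <- tau_termination(lv, s, p)
  t2 <- tau_termination(lv2, s2, p)
  expect_equal(as.numeric(t1), as.numeric(t2), tolerance = 1e-12)
  # convexity of the termination time in phi_RFI
  f <- function(x) {
    l <- lv; l[["RFI"]] <- x
    as.numeric(tau_termination(l, s, p))
  }
  x <- lv[["RFI"]]
  expect_gt((f(0.8 * x) + f(1.2 * x)) / 2, f(x))
})

test_that("queuing correction defaults to the fast-termination regime", {
  expect_identical(queuing_factor(0.05, 0.1), 1)
  expect_identical(queuing_factor(0, 0.1), 1)
  expect_error(queuing_factor(0.05, 0.1, backend = function(a, b) 0.5),
               "Q < 1")
  expect_equal(queuing_factor(0.05, 0.1,
                              backend = function(a, b) 1 + a * b), 1.005)
})

test_that("catalytic sequestration lowers the self-consistent growth rate", {
  p <- tlf_params_default()
  s <- tlf_specs_default()
  s$kcat[s$name %in% c("RFI", "RF4")] <- 10
  s$kcat[s$name == "EF-G"] <- 500
  lv <- tlf_levels_default()
  lam_b <- growth_rate_at(lv, s, p, "binding_limited")
  lam_c <- growth_rate_at(lv, s, p, "catalytic")
  expect_lt(lam_c, lam_b)
  expect_gt(lam_c, 0)
})
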