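test_that("square-root building block and the release-factor closed form", {
  p <- tlf_params_default()
  expect_equal(optimal_sqrt_term(0, 5e-4, 2.6e6), 0)
  expect_equal(optimal_sqrt_term(3, 4 * 5e-4, 2.6e6),
               2 * optimal_sqrt_term(3, 5e-4, 2.6e6))
  expect_error(optimal_sqrt_term(-1, 5e-4, 2.6e6), "non-negative")
  # the raw-rate coefficient l_ribo*l/( <l>*kon_hat ) with kon_hat
  # re-expressed through the rescaled rate reproduces the direct formula
  s <- tlf_specs_default()
  row <- s[s$name == "RFI", ]
  lam <- 5e-4
  via_hat <- optimal_sqrt_term(
    p$len_ribo * row$length_aa / (p$avg_len * row$kon_hat), lam, p$P)
  via_kon <- sqrt(p$len_ribo * lam / (p$avg_len * row$kon))
  expect_rel(via_hat, via_kon, 1e-12)
})

test_that("termination optima match hand evaluation and degenerate limits", {
  p <- tlf_params_default()
  s <- toy_specs(kon = c(RFI = 4e4, RF4 = 4e4),
                 len = c(RFI = 362, RF4 = 185))
  opt <- optimal_termination(p, s, 5e-4)
  expect_equal(opt[[1]]$phi_star, 6.7546e-4, tolerance = 1e-4)
  expect_equal(opt[[1]]$phi_star, opt[[2]]$phi_star)  # equal kinetics
  expect_equal(optimal_termination(p, s, 0)[[1]]$phi_star, 0)
  # with one unused stop class the split model reduces to the single-RF one
  p0 <- global_params(stop_freqs = c(UAA = 0.7, UAG = 0.3, UGA = 0))
  split <- optimal_termination(p0, s, 5e-4, split_rf = TRUE)
  expect_equal(split[[1]]$phi_star, opt[[1]]$phi_star, tolerance = 1e-12)
  # delta > 0 raises the combined release-factor requirement
  split2 <- optimal_termination(p, s, 5e-4, split_rf = TRUE)
  expect_gt(split2[[1]]$phi_star, opt[[1]]$phi_star)
})

test_that("elongation-over-termination and EF-Tu-over-EF-G abundance ratios", {
  p <- tlf_params_default()
  # equal rescaled rates: EF-G optimum exceeds the RF optimum by sqrt(<l>)
  s <- toy_specs(kon = c(RFI = 4e4, RF4 = 4e4, `EF-Tu` = 4e4, `EF-G` = 4e4,
                         `EF-Ts` = 4e4),
                 len = c(RFI = 362, RF4 = 185, `EF-Tu` = 394, `EF-G` = 704,
                         `EF-Ts` = 283))
  lam <- 5e-4
  g <- optimal_elongation(p, s, lam)[[1]]$phi_star
  rf <- optimal_termination(p, s, lam)[[1]]$phi_star
  expect_equal(g / rf, sqrt(200), tolerance = 1e-10)
  # equal raw association rates: EF-Tu direct over EF-G is sqrt(n_aa*l_Tu/l_G)
  s2 <- s
  s2$kon_hat[] <- 6.4
  s2$kon <- kon_rescale(s2$kon_hat, s2$length_aa, p$P)
  el <- optimal_elongation(p, s2, lam)
  tu_direct <- el[[3]]$terms$value[el[[3]]$terms$label == "diffusion_direct"]
  expect_equal(tu_direct / el[[1]]$phi_star, sqrt(20 * 394 / 704),
               tolerance = 1e-10)
  expect_equal(optimal_elongation(p, s, 0)[[3]]$phi_star, 0)
  # the EF-Tu total includes the nucleotide-exchange (EF-Ts) sequestration
  expect_equal(el[[3]]$phi_star - tu_direct, el[[2]]$phi_star,
               tolerance = 1e-12)
})

test_that("the synthetase optimum sits on the transition line and tracks the budget", {
  p <- tlf_params_default(); s <- tlf_specs_default()
  alloc <- tlf_alloc_default()
  lam <- alloc$lambda_star
  aars <- alloc$factors$aaRS
  phi_tc <- alloc$factors[["EF-Tu"]]$terms$value[1]
  lv <- tlf_levels_default()
  others <- lv[setdiff(names(lv), "EF-Tu")]
  tl <- transition_line(phi_tc, others, s, p, lambda_override = lam)
  expect_rel(aars$phi_star, tl$phi_aars, 1e-6)
  # infinite budget: no synthetase investment needed beyond catalysis
  p_hi <- global_params(psi_trna = 1e3)
  expect_lt(optimal_aars(p_hi, s, lam)$phi_star, 1e-8)
  # halving the excess budget doubles the requirement (Delta in denominator)
  d_star <- attr(aars, "delta_trna_star")
  p2 <- p
  p2$psi_trna <- p$psi_trna - d_star / 2  # shifts Delta* to d_star/2
  aars2 <- optimal_aars(p2, s, lam, phi_TC_star = phi_tc)
  expect_equal(aars2$phi_star / aars$phi_star, 2, tolerance = 1e-9)
  # exhausted budget is a hard error naming the cause
  p3 <- global_params(psi_trna = 1e-5)
  expect_error(optimal_aars(p3, s, lam), "tRNA budget exhausted")
})

test_that("initiation optima decompose into direct, shared and catalytic terms", {
  p <- tlf_params_default(); s <- tlf_specs_default()
  lam <- 5e-4
  ini <- optimal_initiation(p, s, lam)
  names(ini) <- vapply(ini, function(f) f$name, "")
  # single-term reduction for IF2: direct term only, with the 3/4 prefactor
  if2 <- ini$IF2
  direct <- if2$terms$value[if2$terms$label == "diffusion_direct"]
  row <- s[s$name == "IF2", ]
  expect_equal(direct,
               sqrt(0.75 * p$len_ribo * row$length_aa * lam /
                      (p$avg_len * row$kon_hat * p$P)),
               tolerance = 1e-12)
  # IF2 and IF3 share the same sequestration ("other") pools up to length
  o2 <- if2$terms$value[if2$terms$label == "diffusion_other"]
  o3 <- ini$IF3$terms$value[ini$IF3$terms$label == "diffusion_other"]
  expect_equal(o2 / o3, s$length_aa[s$name == "IF2"] /
                 s$length_aa[s$name == "IF3"], tolerance = 1e-12)
  # binding-limited IF levels scale as sqrt(lambda)
  ini4 <- optimal_initiation(p, s, 4 * lam)
  for (k in 1:3)
    expect_equal(ini4[[k]]$phi_star / ini[[k]]$phi_star, 2,
                 tolerance = 1e-12)
  # IF1 with a unit bracket equals the RF solution at matching l and kon:
  # the bracket is the only structural difference of the direct terms
  p_small <- global_params(len_ribo = 7300)
  b <- 1 + (s$length_aa[s$name == "IF2"] + s$length_aa[s$name == "IF3"]) /
    p$len_ribo
  if1_direct <- ini$IF1$terms$value[1]
  rf_like <- sqrt(p$len_ribo * lam /
                    (p$avg_len * s$kon[s$name == "IF1"]))
  expect_equal(if1_direct, sqrt(b) * rf_like, tolerance = 1e-12)
  # catalytic column appears only with finite initiation catalytic rates
  p_cat <- global_params(k_rna = 5, k_cat_ini = 10)
  ini_cat <- optimal_initiation(p_cat, s, lam, mode = "catalytic")
  extra <- ini_cat[[1]]$terms$value[ini_cat[[1]]$terms$label == "catalytic"]
  expect_equal(extra, s$length_aa[s$name == "IF1"] / p$avg_len *
                 (1 / 5 + 1 / 10) * lam, tolerance = 1e-12)
})

test_that("effective proteome fraction is minimized exactly at equipartition", {
  p <- tlf_params_default()
  kon <- 4e4
  lam <- 5e-4
  phi_star <- sqrt(lam * p$len_ribo / (kon * p$avg_len))
  f <- function(x) effective_fraction(x, lam, kon, p)
  expect_equal(f(phi_star), 2 * phi_star, tolerance = 1e-12)
  expect_gt(f(0.5 * phi_star), f(phi_star))
  expect_gt(f(2 * phi_star), f(phi_star))
  # the two summands are equal at the optimum
  waiting <- (lam / (phi_star * kon)) * p$len_ribo / p$avg_len
  expect_equal(waiting, phi_star, tolerance = 1e-12)
})

test_that("self-consistent optimum converges and closes the allocation", {
  p <- tlf_params_default(); s <- tlf_specs_default()
  alloc <- tlf_alloc_default()
  expect_true(alloc$convergence$residual < 1e-10)
  phi_sum <- sum(vapply(alloc$factors, function(f) f$phi_star, 0))
  expect_equal(p$phi_tl,
               p$phi_ribo_inactive + alloc$phi_ribo_active_star + phi_sum,
               tolerance = 1e-10)
  # the growth law evaluated at the optimum reproduces lambda*
  lam_check <- alloc$phi_ribo_active_star * p$avg_len /
    (alloc$cycle_star$tau_tl * p$len_ribo)
  expect_equal(lam_check, alloc$lambda_star, tolerance = 1e-10)
  # per-factor term decomposition sums to the reported optimum
  for (f in alloc$factors)
    expect_equal(sum(f$terms$value), f$phi_star, tolerance = 1e-12)
  # a larger translation sector supports faster growth
  p2 <- global_params(phi_tl = 0.45)
  alloc2 <- solve_self_consistent(p2, s)
  expect_gt(alloc2$lambda_star, alloc$lambda_star)
  # finite catalytic rates slow the optimum down
  s_cat <- s
  s_cat$kcat[s_cat$name %in% c("RFI", "RF4", "EF-G", "EF-Ts", "aaRS")] <- 30
  alloc_cat <- solve_self_consistent(p, s_cat, mode = "catalytic")
  expect_lt(alloc_cat$lambda_star, alloc$lambda_star)
})

test_that("equipartition holds for every binding-limited waiting pool at the optimum", {
  alloc <- tlf_alloc_default()
  for (nm in c("IF1", "IF2", "IF3", "50S", "EF-G", "EF-Ts", "EF-Tu",
               "RFI", "RF4")) {
    eq <- alloc$factors[[nm]]$equipartition
    expect_rel(unname(eq[1]), unname(eq[2]), 1e-8,
               label = paste("equipartition pool for", nm))
  }
})
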