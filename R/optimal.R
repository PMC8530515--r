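# Closed-form growth-optimal factor abundances. Every binding wait of the
# form b/phi contributes a square-root optimum phi* = sqrt(b*lambda*
# len_ribo/avg_len) via the arithmetic-geometric-mean (equipartition)
# argument; sequestration on partner complexes and at catalytic steps adds
# terms linear in lambda. Each optimum is assembled from additive terms
# labelled by their physical origin.

#' Square-root building block of the diffusion-limited optima
#'
#' Every diffusion-column entry of an optimal abundance has the form
#' `sqrt(coeff * lambda / P)` with a dimensionless-after-division
#' coefficient built from protein lengths and raw association rate
#' constants.
#'
#' @param coeff Non-negative coefficient (units such that `coeff*lambda/P`
#'   is dimensionless).
#' @param lambda_ Growth rate, 1/s.
#' @param P In-protein amino-acid concentration, micromolar.
#' @return The optimal-fraction contribution.
#' @export
optimal_sqrt_term <- function(coeff, lambda_, P) {
  if (any(coeff < 0)) stop("coefficient must be non-negative", call. = FALSE)
  sqrt(coeff * lambda_ / P)
}

new_optimal_factor <- function(name, terms, equipartition = NULL) {
  phi <- sum(terms$value)
  out <- list(name = name, phi_star = phi, terms = terms,
              equipartition = equipartition)
  class(out) <- "tlf_optimal_factor"
  out
}

#' @export
print.tlf_optimal_factor <- function(x, ...) {
  cat(sprintf("%-8s phi* = %.4g\n", x$name, x$phi_star))
  for (i in seq_len(nrow(x$terms)))
    cat(sprintf("    %-24s %.4g\n", x$terms$label[i], x$terms$value[i]))
  invisible(x)
}

term_df <- function(labels, values) {
  data.frame(label = labels, value = values, stringsAsFactors = FALSE)
}

# diffusion-direct term for a single binding wait b/phi entering tau_tl,
# with b in seconds*fraction; phi* = sqrt(b*lambda*len_ribo/avg_len).
.direct_term <- function(b, lambda_, params) {
  sqrt(b * lambda_ * params$len_ribo / params$avg_len)
}

.cat_term <- function(name, specs, params, lambda_, mode) {
  if (mode != "catalytic") return(0)
  row <- spec_row(specs, name)
  row$per_protein_uses * lambda_ * row$length_aa / (params$avg_len * row$kcat)
}

.equi_pair <- function(phi_free, b, lambda_, params) {
  c(free_factor = phi_free,
    waiting_ribosome = (lambda_ * params$len_ribo / params$avg_len) *
      b / phi_free)
}

#' Optimal release- and recycling-factor abundances
#'
#' Binding-limited optima `phi* = sqrt(len_ribo * lambda / (avg_len * kon))`
#' for the class-I release factor (combined RFI, or RF1+RF2 with the
#' `(1+delta)` stop-codon correction) and the recycling factor RF4;
#' catalytic mode appends the sequestered fraction `l*lambda/(avg_len*kcat)`.
#'
#' @param params A `tlf_params` object.
#' @param specs A `tlf_factors` table.
#' @param lambda_ Growth rate, 1/s.
#' @param mode `"binding_limited"` or `"catalytic"`.
#' @param split_rf Use the two-release-factor model with stop-codon
#'   specificity (adds `delta = 2*f_UAG*f_UGA` inside the radicand).
#' @return List of two `tlf_optimal_factor` records (release, recycling).
#' @export
optimal_termination <- function(params, specs, lambda_,
                                mode = c("binding_limited", "catalytic"),
                                split_rf = FALSE) {
  mode <- match.arg(mode)
  delta <- if (split_rf)
    stop_codon_delta(params$stop_freqs[["UAG"]], params$stop_freqs[["UGA"]])
  else 0
  b_rel <- (1 + delta) / spec_kon(specs, "RFI")
  rel_direct <- .direct_term(b_rel, lambda_, params)
  rel <- new_optimal_factor(
    if (split_rf) "RF1+RF2" else "RFI",
    term_df(c("diffusion_direct", "catalytic"),
            c(rel_direct, .cat_term("RFI", specs, params, lambda_, mode))),
    .equi_pair(rel_direct, b_rel, lambda_, params))
  b4 <- 1 / spec_kon(specs, "RF4")
  rf4_direct <- .direct_term(b4, lambda_, params)
  rf4 <- new_optimal_factor(
    "RF4",
    term_df(c("diffusion_direct", "catalytic"),
            c(rf4_direct, .cat_term("RF4", specs, params, lambda_, mode))),
    .equi_pair(rf4_direct, b4, lambda_, params))
  list(rel, rf4)
}

#' Optimal elongation-factor abundances (EF-G, EF-Ts, EF-Tu)
#'
#' The EF-G wait recurs `avg_len` times per protein, so its binding wait in
#' the cycle is `avg_len/(kon_G*phi_G)` and the optimum gains a
#' `sqrt(avg_len)` over the termination factors. The EF-Tu direct term
#' carries the additional `n_aa` from codon-specific ternary-complex
#' arrival; its "diffusion (other)" term is the EF-Tu(GDP) pool sequestered
#' while awaiting nucleotide exchange, equal to the EF-Ts optimum. EF-Ts
#' itself optimizes the exchange wait against the sequestered EF-Tu(GDP).
#'
#' @inheritParams optimal_termination
#' @return List of three `tlf_optimal_factor` records (EF-G, EF-Ts, EF-Tu).
#' @export
optimal_elongation <- function(params, specs, lambda_,
                               mode = c("binding_limited", "catalytic")) {
  mode <- match.arg(mode)
  b_g <- params$avg_len / spec_kon(specs, "EF-G")
  g_direct <- .direct_term(b_g, lambda_, params)
  efg <- new_optimal_factor(
    "EF-G",
    term_df(c("diffusion_direct", "catalytic"),
            c(g_direct, .cat_term("EF-G", specs, params, lambda_, mode))),
    .equi_pair(g_direct, b_g, lambda_, params))

  # EF-Ts: phi_Ts* = sqrt(l_Tu*l_Ts*lambda/(kon_hat_Ts*P)); the "ribosome"
  # of its equipartition is the EF-Tu(GDP) pool.
  ts_row <- spec_row(specs, "EF-Ts")
  ts_direct <- optimal_sqrt_term(
    spec_len(specs, "EF-Tu") * ts_row$length_aa / ts_row$kon_hat,
    lambda_, params$P)
  efts <- new_optimal_factor(
    "EF-Ts",
    term_df(c("diffusion_direct", "catalytic"),
            c(ts_direct, .cat_term("EF-Ts", specs, params, lambda_, mode))),
    c(free_factor = ts_direct,
      waiting_tu_gdp = lambda_ * spec_len(specs, "EF-Tu") /
        (spec_kon(specs, "EF-Ts") * ts_direct)))

  b_tu <- params$avg_len * params$n_aa / spec_kon(specs, "EF-Tu")
  tu_direct <- .direct_term(b_tu, lambda_, params)
  cat_tu <- if (mode == "catalytic")
    spec_len(specs, "EF-Tu") * lambda_ *
      (1 / spec_kcat(specs, "EF-Tu") + 1 / spec_kcat(specs, "EF-Ts"))
  else 0
  eftu <- new_optimal_factor(
    "EF-Tu",
    term_df(c("diffusion_direct", "diffusion_other:EF-Ts", "catalytic"),
            c(tu_direct, ts_direct, cat_tu)),
    .equi_pair(tu_direct, b_tu, lambda_, params))
  list(efg, efts, eftu)
}

#' Optimal lumped aminoacyl-tRNA synthetase abundance
#'
#' The synthetase optimum is the intersection of the transition line with
#' the EF-Tu optimum, so it is set by the excess tRNA budget there:
#' `phi_aaRS* = n_aa * lambda / (kon_aaRS * Delta_tRNA*)` plus a catalytic
#' term, with
#' `Delta_tRNA* = psi_trna - n_aa*lambda/(kon_TC*phi_TC*) -
#' 2*lambda/k_el_max - phi_TC*/l_Tu - lambda/kcat_aaRS`.
#'
#' @inheritParams optimal_termination
#' @param phi_Tu_star Full optimal EF-Tu fraction (for the record).
#' @param phi_TC_star Ternary-complex fraction at the optimum; defaults to
#'   the EF-Tu diffusion-direct term.
#' @return A `tlf_optimal_factor` with attribute `delta_trna_star`.
#' @export
optimal_aars <- function(params, specs, lambda_,
                         phi_Tu_star = NULL, phi_TC_star = NULL,
                         mode = c("binding_limited", "catalytic")) {
  mode <- match.arg(mode)
  if (is.null(phi_TC_star)) {
    phi_TC_star <- .direct_term(
      params$avg_len * params$n_aa / spec_kon(specs, "EF-Tu"),
      lambda_, params)
  }
  kcat <- spec_kcat(specs, "aaRS")
  delta_star <- params$psi_trna -
    params$n_aa * lambda_ / (spec_kon(specs, "EF-Tu") * phi_TC_star) -
    2 * lambda_ / params$k_el_max -
    phi_TC_star / spec_len(specs, "EF-Tu") -
    (if (mode == "catalytic") lambda_ / kcat else 0)
  if (delta_star <= 0)
    stop(sprintf(
      "tRNA budget exhausted at the EF-Tu optimum (Delta_tRNA* = %.3g): no synthetase optimum exists at psi_trna = %.3g",
      delta_star, params$psi_trna), call. = FALSE)
  diff_term <- params$n_aa * lambda_ /
    (spec_kon(specs, "aaRS") * delta_star)
  out <- new_optimal_factor(
    "aaRS",
    term_df(c("diffusion_direct", "catalytic"),
            c(diff_term, .cat_term("aaRS", specs, params, lambda_, mode))),
    c(free_factor = diff_term,
      waiting_uncharged_trna = params$n_aa * lambda_ /
        (spec_kon(specs, "aaRS") * diff_term)))
  attr(out, "delta_trna_star") <- delta_star
  out
}

#' Optimal initiation-factor abundances (IF1, IF2, IF3)
#'
#' Assembled from the additive waiting pools of 30S-complex assembly: each
#' direct term is the square-root optimum of the factor's own binding wait
#' (IF1 carrying the structural bracket `1+(l_IF2+l_IF3)/l_ribo`, IF2 and
#' IF3 a 3/4 prefactor); the "diffusion (other)" terms are the factor pools
#' sequestered on initiation complexes during the remaining waits (IF1
#' during 50S joining; IF2/IF3 during both the IF1 wait and 50S joining);
#' the catalytic column is `l/avg_len * (1/k_rna + 1/k_cat_ini) * lambda`.
#'
#' @inheritParams optimal_termination
#' @return List of three `tlf_optimal_factor` records.
#' @export
optimal_initiation <- function(params, specs, lambda_,
                               mode = c("binding_limited", "catalytic")) {
  mode <- match.arg(mode)
  l1 <- spec_len(specs, "IF1"); l2 <- spec_len(specs, "IF2")
  l3 <- spec_len(specs, "IF3")
  bracket <- 1 + (l2 + l3) / params$len_ribo
  # sqrt factors shared by the "other" columns
  s_if1 <- optimal_sqrt_term(
    params$len_ribo * l1 / (params$avg_len * spec_row(specs, "IF1")$kon_hat),
    lambda_, params$P)
  s_50s <- optimal_sqrt_term(
    params$avg_len / spec_row(specs, "50S")$kon_hat, lambda_, params$P)
  cat_time <- 1 / params$k_rna + 1 / params$k_cat_ini
  cat_col <- function(l) if (mode == "catalytic")
    l / params$avg_len * cat_time * lambda_ else 0

  mk <- function(name, l, direct_coeff_prefac) {
    b <- direct_coeff_prefac / spec_kon(specs, name)
    direct <- .direct_term(b, lambda_, params)
    other <- if (name == "IF1") (l / params$avg_len) * s_50s
             else (l / params$avg_len) * (s_if1 + s_50s)
    new_optimal_factor(
      name,
      term_df(c("diffusion_direct", "diffusion_other", "catalytic"),
              c(direct, other, cat_col(l))),
      .equi_pair(direct, b, lambda_, params))
  }
  list(mk("IF1", l1, bracket), mk("IF2", l2, 0.75), mk("IF3", l3, 0.75))
}

# Free 50S-subunit pool awaiting joining, optimized like a factor whose
# binding wait is 1/(kon_50S * phi_50S); effective length = full ribosomal
# protein complement.
.optimal_50s <- function(params, specs, lambda_) {
  b <- 1 / spec_kon(specs, "50S")
  direct <- .direct_term(b, lambda_, params)
  new_optimal_factor("50S",
                     term_df("diffusion_direct", direct),
                     .equi_pair(direct, b, lambda_, params))
}

#' Effective proteome fraction of a factor-plus-waiting-ribosomes pool
#'
#' `phi + (lambda/(phi*kon)) * len_ribo/avg_len`: the proteome space of the
#' free factor plus the ribosomes waiting for it. By the AM-GM inequality it
#' is minimized, at value `2*phi*`, where the two summands are equal
#' (equipartition).
#'
#' @param phi_factor Free factor proteome fraction.
#' @param lambda_ Growth rate, 1/s.
#' @param kon Rescaled association rate, 1/s per proteome fraction.
#' @param params A `tlf_params` object.
#' @return The effective proteome fraction.
#' @export
effective_fraction <- function(phi_factor, lambda_, kon, params) {
  if (any(c(phi_factor, lambda_, kon) <= 0))
    stop("inputs must be positive", call. = FALSE)
  phi_factor + (lambda_ / (phi_factor * kon)) * params$len_ribo /
    params$avg_len
}

#' Self-consistent growth optimum over all factors
#'
#' Closes the loop between the growth rate and the lambda-dependent optimal
#' abundances by damped fixed-point iteration: given `lambda_t`, all
#' `phi*_i(lambda_t)` are evaluated; the active-ribosome fraction follows
#' from the allocation constraint and the optimal cycle time from the
#' equipartition waits; the updated growth rate is damped with factor 0.5.
#' Converges when the relative change is below `1e-10` (at most 500
#' iterations).
#'
#' @inheritParams optimal_termination
#' @param include_aars Include the synthetase (requires a feasible tRNA
#'   budget).
#' @return An object of class `tlf_allocation`: list with `factors` (named
#'   list of `tlf_optimal_factor`), `lambda_star`, `phi_ribo_active_star`,
#'   `cycle_star`, `delta_trna_star`, `convergence`, `params`, `mode`.
#' @export
solve_self_consistent <- function(params, specs,
                                  mode = c("binding_limited", "catalytic"),
                                  split_rf = FALSE, include_aars = TRUE) {
  mode <- match.arg(mode)
  lambda <- 3e-4
  trace <- numeric(0)
  converged <- FALSE
  for (it in 1:500) {
    facs <- .all_optima(params, specs, lambda, mode, split_rf, include_aars)
    phi_sum <- sum(vapply(facs, function(f) f$phi_star, 0))
    phi_act <- params$phi_tl - params$phi_ribo_inactive - phi_sum
    if (phi_act <= 0)
      stop(sprintf(
        "allocation infeasible at iterate %d: optimal factors (%.4g) exhaust phi_tl (%.4g)",
        it, phi_sum, params$phi_tl), call. = FALSE)
    cyc <- .optimal_cycle(facs, params, specs, lambda, mode)
    lambda_new <- phi_act * params$avg_len / (cyc$tau_tl * params$len_ribo)
    resid <- abs(lambda_new - lambda) / lambda
    trace <- c(trace, lambda_new)
    lambda <- lambda + 0.5 * (lambda_new - lambda)
    if (resid < 1e-10) { converged <- TRUE; break }
  }
  if (!converged)
    stop("self-consistent iteration did not converge; lambda trace tail: ",
         paste(signif(utils::tail(trace, 5), 6), collapse = ", "),
         call. = FALSE)
  facs <- .all_optima(params, specs, lambda, mode, split_rf, include_aars)
  phi_sum <- sum(vapply(facs, function(f) f$phi_star, 0))
  phi_act <- params$phi_tl - params$phi_ribo_inactive - phi_sum
  cyc <- .optimal_cycle(facs, params, specs, lambda, mode)
  out <- list(
    factors = stats::setNames(facs, vapply(facs, function(f) f$name, "")),
    lambda_star = lambda,
    phi_ribo_active_star = phi_act,
    cycle_star = cyc,
    delta_trna_star = if (include_aars)
      attr(facs[[which(vapply(facs, function(f) f$name, "") == "aaRS")]],
           "delta_trna_star") else NA_real_,
    convergence = list(iterations = it, residual = resid),
    params = params, mode = mode)
  class(out) <- "tlf_allocation"
  out
}

.all_optima <- function(params, specs, lambda, mode, split_rf, include_aars) {
  facs <- c(optimal_initiation(params, specs, lambda, mode),
            list(.optimal_50s(params, specs, lambda)),
            optimal_elongation(params, specs, lambda, mode),
            optimal_termination(params, specs, lambda, mode, split_rf))
  if (include_aars)
    facs <- c(facs, list(optimal_aars(params, specs, lambda, mode = mode)))
  facs
}

# Cycle times at the optimum, from the equipartition identity: every
# ribosome-waiting pool equals the corresponding free-factor (direct) term,
# so each binding wait is phi_direct * avg_len / (lambda * len_ribo).
# EF-Ts and aaRS pools hold EF-Tu and tRNAs, not ribosomes, and do not
# enter ribosome transit times.
.optimal_cycle <- function(facs, params, specs, lambda, mode) {
  nm <- vapply(facs, function(f) f$name, "")
  direct <- vapply(facs, function(f)
    f$terms$value[f$terms$label == "diffusion_direct"], 0)
  names(direct) <- nm
  wait <- function(n) direct[[n]] * params$avg_len /
    (lambda * params$len_ribo)
  cat_time <- function(n) if (mode == "catalytic")
    1 / spec_kcat(specs, n) else 0
  rel_name <- if ("RF1+RF2" %in% nm) "RF1+RF2" else "RFI"
  tau_ini <- wait("IF1") + wait("IF2") + wait("IF3") + wait("50S") +
    (if (mode == "catalytic") 1 / params$k_rna + 1 / params$k_cat_ini else 0)
  tau_aa <- (wait("EF-Tu") + wait("EF-G")) / params$avg_len +
    1 / params$k_el_max
  if (mode == "catalytic")
    tau_aa <- tau_aa + 1 / spec_kcat(specs, "EF-G") +
      1 / spec_kcat(specs, "EF-Tu")
  tau_el <- params$avg_len * tau_aa
  tau_ter <- wait(rel_name) + wait("RF4") +
    cat_time("RFI") + cat_time("RF4")
  out <- list(tau_ini = tau_ini, tau_el = tau_el, tau_ter = tau_ter,
              tau_aa = tau_aa, tau_tl = tau_ini + tau_el + tau_ter,
              breakdown = list())
  class(out) <- "tlf_cycle"
  out
}

#' @export
print.tlf_allocation <- function(x, ...) {
  cat("Growth-optimal translation-factor allocation (",
      x$mode, " mode)\n", sep = "")
  cat(sprintf("  lambda* = %.4g /s (doubling time %.1f min)\n",
              x$lambda_star, log(2) / x$lambda_star / 60))
  cat(sprintf("  active ribosomes phi = %.4g; cycle time %.3g s\n",
              x$phi_ribo_active_star, x$cycle_star$tau_tl))
  for (f in x$factors) print(f)
  invisible(x)
}

#' Serialize an optimal allocation to JSON
#'
#' @param x A `tlf_allocation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allocation <- function(x, path) {
  doc <- list(
    mode = x$mode,
    lambda_star = x$lambda_star,
    doubling_time_min = log(2) / x$lambda_star / 60,
    phi_ribo_active_star = x$phi_ribo_active_star,
    cycle = x$cycle_star[c("tau_ini", "tau_el", "tau_ter", "tau_tl")],
    delta_trna_star = x$delta_trna_star,
    convergence = x$convergence,
    factors = lapply(x$factors, function(f)
      list(phi_star = f$phi_star,
           terms = stats::setNames(as.list(f$terms$value), f$terms$label))))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
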