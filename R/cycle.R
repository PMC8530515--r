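# Coarse-grained ribosome transit times and the growth-rate/allocation
# relations. Factor abundances ("levels") are named numeric vectors of total
# proteome fractions, e.g. c(`EF-Tu` = 0.05, `EF-G` = 0.015, ...).

#' Stop-codon read-degeneracy correction for the split RF1/RF2 model
#'
#' When RF1 (reads UAA, UAG) and RF2 (reads UAA, UGA) are modeled separately
#' with their codon specificities, the combined release-factor optimum picks
#' up a factor `(1 + delta)` inside the radicand, with
#' `delta = 2 * f_UAG * f_UGA`.
#'
#' @param f_UAG,f_UGA Genomic usage fractions of the UAG and UGA stop codons.
#' @return The dimensionless correction `delta`.
#' @export
stop_codon_delta <- function(f_UAG, f_UGA) {
  if (any(c(f_UAG, f_UGA) < 0) || any(c(f_UAG, f_UGA) > 1) ||
      f_UAG + f_UGA > 1)
    stop("stop-codon frequencies must be fractions with f_UAG + f_UGA <= 1",
         call. = FALSE)
  2 * f_UAG * f_UGA
}

# Fraction of factor `name` sequestered at its catalytic step at growth rate
# lambda: r * lambda * l / (<l> * kcat), with r the number of uses per
# completed protein. Zero in the binding-limited regime (kcat = Inf).
sequestered_fraction <- function(name, specs, params, lambda) {
  row <- spec_row(specs, name)
  row$per_protein_uses * lambda * row$length_aa /
    (params$avg_len * row$kcat)
}

# Free (unsequestered) level of a factor; binding waits use this fraction.
free_level <- function(phi_total, name, specs, params, mode, lambda) {
  if (mode == "binding_limited") return(phi_total)
  if (is.null(lambda))
    stop("catalytic mode requires the growth rate for sequestration",
         call. = FALSE)
  max(phi_total - sequestered_fraction(name, specs, params, lambda), 0)
}

# A binding wait 1/(kon * phi); phi = 0 yields an explicit Inf so optimizers
# can penalize boundary points instead of crashing.
bind_wait <- function(kon, phi) {
  ifelse(phi > 0, 1 / (kon * phi), Inf)
}

#' Ribosome transit time at termination
#'
#' Peptide release (RFI, or RF1+RF2 combined) followed by ribosome recycling
#' (RF4). In the binding-limited regime each step contributes the diffusive
#' search time `1/(kon * phi)`; in catalytic mode each step additionally
#' contributes `1/kcat` and the binding waits use the free (unsequestered)
#' factor fractions.
#'
#' @param levels Named vector of total factor proteome fractions; must
#'   contain `RFI` (or `RF1`/`RF2` when `split_rf = TRUE`) and `RF4`.
#' @param specs A `tlf_factors` table.
#' @param params A `tlf_params` object.
#' @param mode `"binding_limited"` or `"catalytic"`.
#' @param lambda Growth rate (1/s), required in catalytic mode.
#' @param split_rf Model RF1 and RF2 separately with their stop-codon
#'   specificities instead of the combined RFI.
#' @return Termination time in seconds (possibly `Inf`), with per-step
#'   breakdown in attribute `"breakdown"`.
#' @export
tau_termination <- function(levels, specs, params,
                            mode = c("binding_limited", "catalytic"),
                            lambda = NULL, split_rf = FALSE) {
  mode <- match.arg(mode)
  if (split_rf) {
    # Effective release wait with codon-specific RFs: a UAG stop can only be
    # read by RF1, a UGA stop only by RF2, UAA by either.
    f <- params$stop_freqs
    phi1 <- free_level(levels[["RF1"]], "RF1", specs, params, mode, lambda)
    phi2 <- free_level(levels[["RF2"]], "RF2", specs, params, mode, lambda)
    k1 <- spec_kon(specs, "RF1"); k2 <- spec_kon(specs, "RF2")
    tau_stop <- f[["UAG"]] * bind_wait(k1, phi1) +
      f[["UGA"]] * bind_wait(k2, phi2) +
      f[["UAA"]] / (k1 * phi1 + k2 * phi2)
    kcat_rel <- spec_kcat(specs, "RF1")
  } else {
    phiI <- free_level(levels[["RFI"]], "RFI", specs, params, mode, lambda)
    tau_stop <- bind_wait(spec_kon(specs, "RFI"), phiI)
    kcat_rel <- spec_kcat(specs, "RFI")
  }
  phi4 <- free_level(levels[["RF4"]], "RF4", specs, params, mode, lambda)
  tau_recyc <- bind_wait(spec_kon(specs, "RF4"), phi4)
  if (mode == "catalytic") {
    tau_stop <- tau_stop + 1 / kcat_rel
    tau_recyc <- tau_recyc + 1 / spec_kcat(specs, "RF4")
  }
  out <- tau_stop + tau_recyc
  attr(out, "breakdown") <- c(tau_stop = unname(tau_stop),
                              tau_recyc = unname(tau_recyc))
  out
}

#' Factor-dependent ribosome transit time through one codon
#'
#' Two sequential binding steps per codon: arrival of the ternary complex
#' (codon-specific, hence carrying the `1/n_aa` coarse-graining rescale of
#' its association rate) and arrival of EF-G. In catalytic mode, finite
#' factor catalytic rates add `1/kcat` residences. The ribosome's intrinsic
#' catalytic time per codon (`1/k_el_max`) is accounted for separately when
#' the full cycle is assembled (see [cycle_times()]).
#'
#' @param phi_TC Ternary-complex proteome fraction (protein mass of EF-Tu in
#'   TCs).
#' @param phi_G EF-G proteome fraction (free fraction in catalytic mode).
#' @inheritParams tau_termination
#' @return Per-codon factor-dependent time in seconds.
#' @export
tau_codon <- function(phi_TC, phi_G, specs, params,
                      mode = c("binding_limited", "catalytic")) {
  mode <- match.arg(mode)
  out <- params$n_aa * bind_wait(spec_kon(specs, "EF-Tu"), phi_TC) +
    bind_wait(spec_kon(specs, "EF-G"), phi_G)
  if (mode == "catalytic")
    out <- out + 1 / spec_kcat(specs, "EF-G") + 1 / spec_kcat(specs, "EF-Tu")
  out
}

#' Ribosome transit time at initiation
#'
#' Additive waiting steps of 30S-complex assembly and 50S joining: IF1
#' binding (carrying the structural bracket
#' `1 + (l_IF2 + l_IF3)/l_ribo`), IF2 and IF3 binding (each with a 3/4
#' structural prefactor), 50S-subunit joining, plus the catalytic times
#' `1/k_rna + 1/k_cat_ini` (zero when those rates are infinite). A level of
#' `Inf` disables the corresponding binding wait exactly.
#'
#' @param levels Named vector with entries `IF1`, `IF2`, `IF3`, `50S`.
#' @inheritParams tau_termination
#' @return Initiation time in seconds, with per-step breakdown in attribute
#'   `"breakdown"`.
#' @export
tau_initiation <- function(levels, specs, params,
                           mode = c("binding_limited", "catalytic"),
                           lambda = NULL) {
  mode <- match.arg(mode)
  bracket <- 1 + (spec_len(specs, "IF2") + spec_len(specs, "IF3")) /
    params$len_ribo
  lv <- function(nm) free_level(levels[[nm]], nm, specs, params, mode, lambda)
  terms <- c(
    IF1 = bracket * bind_wait(spec_kon(specs, "IF1"), lv("IF1")),
    IF2 = 0.75 * bind_wait(spec_kon(specs, "IF2"), lv("IF2")),
    IF3 = 0.75 * bind_wait(spec_kon(specs, "IF3"), lv("IF3")),
    `50S` = bind_wait(spec_kon(specs, "50S"), lv("50S")),
    catalytic = 1 / params$k_rna + 1 / params$k_cat_ini
  )
  out <- sum(terms)
  attr(out, "breakdown") <- terms
  out
}

#' Assemble the full translation-cycle times
#'
#' Builds the coarse-grained cycle `tau_tl = tau_ini + tau_el + tau_ter`.
#' The elongation time is `avg_len` repeats of the per-codon time, which is
#' the factor-dependent part ([tau_codon()]) plus the ribosome's intrinsic
#' catalytic residence `1/k_el_max`.
#'
#' @param levels Named vector of total factor proteome fractions (IF1, IF2,
#'   IF3, 50S, EF-Tu, EF-G, RFI or RF1/RF2, RF4; EF-Ts and aaRS do not enter
#'   ribosome transit times directly).
#' @param phi_TC Ternary-complex fraction; defaults to the EF-Tu level
#'   (EF-Tu-limited approximation). Supply the [solve_tc()] value for the
#'   full nonlinear treatment.
#' @inheritParams tau_termination
#' @return An object of class `tlf_cycle`: list with `tau_ini`, `tau_el`,
#'   `tau_ter`, `tau_tl`, `tau_aa`, and per-subreaction `breakdown`.
#' @export
cycle_times <- function(levels, specs, params,
                        mode = c("binding_limited", "catalytic"),
                        phi_TC = NULL, lambda = NULL, split_rf = FALSE) {
  mode <- match.arg(mode)
  if (is.null(phi_TC)) phi_TC <- levels[["EF-Tu"]]
  phi_G <- free_level(levels[["EF-G"]], "EF-G", specs, params, mode, lambda)
  t_ini <- tau_initiation(levels, specs, params, mode, lambda)
  t_aa <- tau_codon(phi_TC, phi_G, specs, params, mode) + 1 / params$k_el_max
  t_el <- params$avg_len * t_aa
  t_ter <- tau_termination(levels, specs, params, mode, lambda, split_rf)
  out <- list(tau_ini = as.numeric(t_ini), tau_el = as.numeric(t_el),
              tau_ter = as.numeric(t_ter), tau_aa = as.numeric(t_aa),
              tau_tl = as.numeric(t_ini) + as.numeric(t_el) +
                as.numeric(t_ter),
              breakdown = list(initiation = attr(t_ini, "breakdown"),
                               termination = attr(t_ter, "breakdown")))
  class(out) <- "tlf_cycle"
  out
}

#' @export
print.tlf_cycle <- function(x, ...) {
  cat("Translation cycle times (s)\n")
  cat(sprintf("  initiation  %.4g\n", x$tau_ini))
  cat(sprintf("  elongation  %.4g  (%.4g per codon)\n", x$tau_el, x$tau_aa))
  cat(sprintf("  termination %.4g\n", x$tau_ter))
  cat(sprintf("  full cycle  %.4g\n", x$tau_tl))
  invisible(x)
}

#' Growth rate from the allocation-constrained ribosome flux
#'
#' `lambda = phi_act * avg_len / (tau_tl * len_ribo)`, with
#' `phi_act = phi_tl - phi_ribo_inactive - sum(levels)` the active-ribosome
#' proteome fraction left after factor allocation.
#'
#' @param levels Named vector of all factor proteome fractions counted
#'   against the translation sector.
#' @param cycle A `tlf_cycle` object (or any list with `tau_tl`).
#' @param params A `tlf_params` object.
#' @return Growth rate in 1/s.
#' @export
growth_rate <- function(levels, cycle, params) {
  if (any(!is.finite(levels)))
    stop("factor levels must be finite for the allocation constraint",
         call. = FALSE)
  phi_act <- params$phi_tl - params$phi_ribo_inactive - sum(levels)
  if (phi_act <= 0)
    stop(sprintf(
      "allocation infeasible: phi_tl (%.4g) cannot cover inactive ribosomes (%.4g) plus factors (%.4g)",
      params$phi_tl, params$phi_ribo_inactive, sum(levels)), call. = FALSE)
  if (cycle$tau_tl <= 0) stop("tau_tl must be positive", call. = FALSE)
  phi_act * params$avg_len / (cycle$tau_tl * params$len_ribo)
}

#' Growth rate at given factor levels
#'
#' Convenience wrapper assembling the cycle and evaluating [growth_rate()].
#' In catalytic mode the transit times depend on the growth rate through
#' factor sequestration, so a small internal fixed point is iterated to
#' self-consistency.
#'
#' @inheritParams cycle_times
#' @return Growth rate in 1/s; `NA` if the cycle time is infinite.
#' @export
growth_rate_at <- function(levels, specs, params,
                           mode = c("binding_limited", "catalytic"),
                           phi_TC = NULL, split_rf = FALSE) {
  mode <- match.arg(mode)
  cyc <- cycle_times(levels, specs, params, "binding_limited", phi_TC,
                     split_rf = split_rf)
  if (!is.finite(cyc$tau_tl)) return(NA_real_)
  lam <- growth_rate(levels, cyc, params)
  if (mode == "catalytic") {
    for (i in 1:100) {
      cyc <- cycle_times(levels, specs, params, "catalytic", phi_TC,
                         lambda = lam, split_rf = split_rf)
      if (!is.finite(cyc$tau_tl)) return(NA_real_)
      lam_new <- growth_rate(levels, cyc, params)
      if (abs(lam_new - lam) <= 1e-13 * lam) { lam <- lam_new; break }
      lam <- lam_new
    }
  }
  lam
}

#' Ribosome occupancies per cycle step
#'
#' In steady state no ribosome accumulates in any intermediate state, so the
#' fraction of active ribosomes at each step equals the fraction of cycle
#' time spent there: `phi_step = phi_ribo_active * tau_step / tau_tl`, and
#' every step flux `phi_step / tau_step` equals `lambda * len_ribo /
#' avg_len`.
#'
#' @param cycle A `tlf_cycle` object.
#' @param phi_ribo_active Active-ribosome proteome fraction.
#' @return Named vector `c(initiation=, elongation=, termination=)` summing
#'   exactly to `phi_ribo_active`.
#' @export
ribosome_occupancies <- function(cycle, phi_ribo_active) {
  if (cycle$tau_tl <= 0) stop("tau_tl must be positive", call. = FALSE)
  tau <- c(initiation = cycle$tau_ini, elongation = cycle$tau_el,
           termination = cycle$tau_ter)
  phi_ribo_active * tau / cycle$tau_tl
}

#' Queuing correction for slow termination
#'
#' Interface hook for the regime where ribosomes queue upstream of stop
#' codons. The default backend returns 1 (fast termination, physiological
#' regime); alternative backends must return a value >= 1.
#'
#' @param tau_ter Termination time, seconds.
#' @param initiation_rate Per-mRNA initiation rate, 1/s.
#' @param backend Optional function `(tau_ter, initiation_rate) -> Q >= 1`.
#' @return The queuing factor Q.
#' @export
queuing_factor <- function(tau_ter, initiation_rate, backend = NULL) {
  if (any(c(tau_ter, initiation_rate) < 0))
    stop("inputs must be non-negative", call. = FALSE)
  if (is.null(backend)) return(1)
  q <- backend(tau_ter, initiation_rate)
  if (q < 1) stop("queuing backend returned Q < 1", call. = FALSE)
  q
}
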