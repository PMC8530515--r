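# Nonlinear steady state of the tRNA/EF-Tu charging cycle. The tRNA budget
# (psi_trna, total tRNA divided by P) is partitioned among ribosome-held
# tRNAs, free uncharged tRNAs, free charged tRNAs, and ternary complexes;
# the conservation equation is closed because the growth rate depends on
# EF-Tu and aaRS only through the ternary-complex fraction phi_TC.

# Constants of lambda(phi_TC) that do not depend on the EF-Tu/aaRS point:
# with all other factors fixed, lambda = amp * phi_TC / (K_TC + phi_TC),
# where tau0 is the cycle time with the TC arrival wait removed and amp
# carries the allocation-dependent active-ribosome fraction.
.tc_base <- function(levels, specs, params) {
  lv <- levels
  lv <- lv[setdiff(names(lv), c("EF-Tu", "aaRS"))]
  lv[["EF-Tu"]] <- 1  # unused: the TC wait is supplied via phi_TC
  cyc0 <- cycle_times(lv, specs, params, "binding_limited", phi_TC = Inf)
  kon_tc <- spec_kon(specs, "EF-Tu")
  tau0 <- cyc0$tau_tl
  list(
    sum_others = sum(lv) - 1,
    tau0 = tau0,
    kon_tc = kon_tc,
    kon_aars = spec_kon(specs, "aaRS"),
    kon_tu = attr(specs, "kon_tu"),
    len_tu = spec_len(specs, "EF-Tu"),
    K_TC = params$avg_len * params$n_aa / (kon_tc * tau0)
  )
}

# Point-specific environment for a given (phi_Tu, phi_aaRS).
.tc_env_at <- function(base, params, phi_Tu, phi_aaRS) {
  phi_act <- params$phi_tl - params$phi_ribo_inactive - base$sum_others -
    phi_Tu - phi_aaRS
  if (phi_act <= 0)
    stop(sprintf(
      "allocation infeasible: factor fractions (%.4g) exhaust the sector",
      base$sum_others + phi_Tu + phi_aaRS), call. = FALSE)
  env <- base
  env$phi_act <- phi_act
  env$amp <- phi_act * params$avg_len / (base$tau0 * params$len_ribo)
  env$phi_Tu <- phi_Tu
  env$phi_aaRS <- phi_aaRS
  env
}

.tc_env <- function(levels, specs, params, phi_Tu, phi_aaRS) {
  .tc_env_at(.tc_base(levels, specs, params), params, phi_Tu, phi_aaRS)
}

.tc_lambda <- function(phi_TC, env) {
  env$amp * phi_TC / (env$K_TC + phi_TC)
}

# Residual of the tRNA conservation equation given a candidate phi_TC and an
# environment of precomputed constants.
.tc_residual <- function(phi_TC, env, params) {
  lam <- .tc_lambda(phi_TC, env)
  phi_tu_gtp <- env$phi_Tu - phi_TC
  r_empty <- params$n_aa * lam / (env$kon_tc * phi_TC)
  r_filled <- 2 * lam / params$k_el_max
  unch <- params$n_aa * lam / (env$kon_aars * env$phi_aaRS)
  free_aa <- if (phi_tu_gtp > 0)
    r_empty * lam / (env$kon_tu * phi_tu_gtp) else Inf
  tc_bound <- phi_TC / env$len_tu
  params$psi_trna - (r_empty + r_filled + unch + free_aa + tc_bound)
}

#' Residual of the tRNA conservation equation
#'
#' Evaluates `psi_trna` minus the bookkeeping of all tRNA pools (P-site
#' tRNAs of ribosomes with empty A site, the two tRNAs of ribosomes with
#' filled A site, free uncharged tRNAs waiting for synthetases, free charged
#' tRNAs waiting for EF-Tu capture, and TC-bound tRNAs) at a candidate
#' ternary-complex fraction. The growth rate entering each pool is evaluated
#' from the full allocation-constrained cycle, holding all factors other
#' than EF-Tu/aaRS at `levels`.
#'
#' @param phi_TC Candidate ternary-complex proteome fraction, in
#'   `(0, phi_Tu]`.
#' @param phi_Tu,phi_aaRS Total EF-Tu and lumped-synthetase proteome
#'   fractions.
#' @param levels Named vector of the remaining factor levels (IF1-3, 50S,
#'   EF-Ts, EF-G, RFI, RF4).
#' @param specs A `tlf_factors` table.
#' @param params A `tlf_params` object.
#' @return Dimensionless residual; positive when the budget exceeds the
#'   pools, `-Inf` in the limit of vanishing free EF-Tu.
#' @export
conservation_residual <- function(phi_TC, phi_Tu, phi_aaRS, levels, specs,
                                  params) {
  if (phi_TC > phi_Tu)
    stop("phi_TC cannot exceed phi_Tu", call. = FALSE)
  if (phi_TC <= 0) stop("phi_TC must be positive", call. = FALSE)
  env <- .tc_env(levels, specs, params, phi_Tu, phi_aaRS)
  .tc_residual(phi_TC, env, params)
}

#' Solve the tRNA-charging steady state for the ternary-complex fraction
#'
#' Finds the root of [conservation_residual()] in `(0, phi_Tu)` by bracketed
#' bisection refined to a residual below `1e-10 * psi_trna`, and populates
#' all species pools consistently.
#'
#' @inheritParams conservation_residual
#' @return An object of class `tlf_elongation_state`: list with `phi_TC`,
#'   `phi_Tu_GTP`, `free_charged_trna`, `free_uncharged_trna`,
#'   `ribo_A_site_empty`, `ribo_A_site_filled`, `tc_bound_trna`, `lambda`,
#'   and the achieved `residual`.
#' @export
solve_tc <- function(phi_Tu, phi_aaRS, levels, specs, params) {
  if (phi_Tu <= 0 || phi_aaRS <= 0)
    stop("phi_Tu and phi_aaRS must be positive", call. = FALSE)
  env <- .tc_env(levels, specs, params, phi_Tu, phi_aaRS)
  .solve_tc_env(env, params)
}

.solve_tc_env <- function(env, params) {
  phi_Tu <- env$phi_Tu
  phi_aaRS <- env$phi_aaRS
  # Solve in the free-EF-Tu pool g = phi_Tu - phi_TC (log scale): deep in
  # the EF-Tu-limited regime g is many orders below phi_Tu and solving for
  # phi_TC directly would lose it to cancellation. The residual computed
  # with an exact g is then accurate to machine precision everywhere.
  res_g <- function(g) {
    x <- phi_Tu - g
    lam <- .tc_lambda(x, env)
    r_empty <- params$n_aa * lam / (env$kon_tc * x)
    params$psi_trna -
      (r_empty + 2 * lam / params$k_el_max +
         params$n_aa * lam / (env$kon_aars * phi_aaRS) +
         r_empty * lam / (env$kon_tu * g) +
         x / env$len_tu)
  }
  g_lo <- phi_Tu * 1e-16          # phi_TC at the EF-Tu ceiling
  g_hi <- phi_Tu * (1 - 1e-12)    # phi_TC near zero
  f_ceiling <- res_g(g_lo)
  if (!is.finite(res_g(g_hi)) || res_g(g_hi) < 0)
    stop(sprintf(
      "tRNA budget infeasible: psi_trna = %.4g cannot cover the minimal pools",
      params$psi_trna), call. = FALSE)
  if (f_ceiling > 0) {
    # Budget ample even with essentially all EF-Tu in TCs.
    g <- g_lo
  } else {
    a <- log(g_lo); b <- log(g_hi)   # res_g increasing in g
    for (i in 1:120) {
      m <- 0.5 * (a + b)
      if (res_g(exp(m)) > 0) b <- m else a <- m
    }
    g <- exp(0.5 * (a + b))
  }
  root <- phi_Tu - g

  lam <- .tc_lambda(root, env)
  phi_tu_gtp <- g
  r_empty <- params$n_aa * lam / (env$kon_tc * root)
  out <- list(
    phi_TC = root,
    phi_Tu_GTP = phi_tu_gtp,
    free_charged_trna = if (phi_tu_gtp > 0)
      r_empty * lam / (env$kon_tu * phi_tu_gtp) else Inf,
    free_uncharged_trna = params$n_aa * lam / (env$kon_aars * phi_aaRS),
    ribo_A_site_empty = r_empty,
    ribo_A_site_filled = 2 * lam / params$k_el_max,
    tc_bound_trna = root / env$len_tu,
    lambda = lam,
    residual = res_g(g)
  )
  class(out) <- "tlf_elongation_state"
  out
}

#' @export
print.tlf_elongation_state <- function(x, ...) {
  cat("tRNA-charging steady state\n")
  cat(sprintf("  phi_TC          %.4g\n", x$phi_TC))
  cat(sprintf("  phi_Tu^GTP      %.4g\n", x$phi_Tu_GTP))
  cat(sprintf("  lambda          %.4g /s\n", x$lambda))
  cat(sprintf("  residual        %.3g\n", x$residual))
  invisible(x)
}

#' Excess tRNA budget along the transition line
#'
#' The tRNAs remaining after subtracting ribosome-held and TC-bound pools
#' from the total budget, evaluated with the transition-line convention
#' `phi_TC = phi_Tu_bar` (no free EF-Tu):
#' `Delta_tRNA = psi_trna - n_aa*lambda/(kon_TC*phi_Tu_bar)
#'   - 2*lambda/k_el_max - phi_Tu_bar/l_Tu`.
#'
#' @param phi_Tu_bar EF-Tu proteome fraction on the transition line.
#' @param levels Named vector of the remaining factor levels; must include
#'   an `aaRS` entry for the allocation constraint.
#' @param lambda_override Use this growth rate instead of re-evaluating the
#'   cycle (e.g. a converged `lambda_star` when checking that an optimum
#'   lies on the line).
#' @inheritParams conservation_residual
#' @return The dimensionless excess `Delta_tRNA` (may be negative when the
#'   budget is exhausted).
#' @export
excess_trna <- function(phi_Tu_bar, levels, specs, params,
                        lambda_override = NULL) {
  if (phi_Tu_bar <= 0) stop("phi_Tu_bar must be positive", call. = FALSE)
  if (is.null(lambda_override)) {
    lv <- levels
    lv[["EF-Tu"]] <- phi_Tu_bar
    cyc <- cycle_times(lv, specs, params, "binding_limited",
                       phi_TC = phi_Tu_bar)
    lam <- growth_rate(lv, cyc, params)
  } else lam <- lambda_override
  params$psi_trna -
    params$n_aa * lam / (spec_kon(specs, "EF-Tu") * phi_Tu_bar) -
    2 * lam / params$k_el_max -
    phi_Tu_bar / spec_len(specs, "EF-Tu")
}

#' The EF-Tu/aaRS transition line
#'
#' Curve in the (EF-Tu, aaRS) expression plane where both factors are
#' co-limiting for the ternary-complex concentration. For each sampled
#' `phi_Tu_bar` with positive excess tRNA, the matched synthetase level is
#' `phi_aars_bar = n_aa * lambda / (kon_aaRS * Delta_tRNA)`; points with
#' exhausted budget are flagged infeasible (the plateau's far side).
#'
#' @param phi_Tu_samples Positive EF-Tu fractions to sample.
#' @inheritParams excess_trna
#' @return A data.frame with columns `phi_Tu`, `lambda`, `delta_trna`,
#'   `phi_aars`, `feasible`.
#' @export
transition_line <- function(phi_Tu_samples, levels, specs, params,
                            lambda_override = NULL) {
  if (any(phi_Tu_samples <= 0))
    stop("phi_Tu samples must be positive", call. = FALSE)
  kon_aars <- spec_kon(specs, "aaRS")
  rows <- lapply(phi_Tu_samples, function(tu) {
    if (is.null(lambda_override)) {
      lv <- levels
      lv[["EF-Tu"]] <- tu
      cyc <- cycle_times(lv, specs, params, "binding_limited", phi_TC = tu)
      lam <- growth_rate(lv, cyc, params)
    } else lam <- lambda_override
    d <- excess_trna(tu, levels, specs, params, lambda_override)
    data.frame(phi_Tu = tu, lambda = lam, delta_trna = d,
               phi_aars = if (d > 0) params$n_aa * lam / (kon_aars * d)
                          else NA_real_,
               feasible = d > 0)
  })
  do.call(rbind, rows)
}

#' Steady-state landscape over the EF-Tu/aaRS expression plane
#'
#' Dense evaluation of [solve_tc()] on a grid, reporting the ternary-complex
#' fraction (also scaled by the effective half-saturation fraction
#' `K_TC_effective`), the free charged-tRNA pool, the free EF-Tu fraction,
#' and the transition-line overlay. Cells where the tRNA budget or the
#' proteome allocation is infeasible are masked (NA with `mask = TRUE`).
#'
#' @param tu_grid,aars_grid Positive, sorted grids of EF-Tu and synthetase
#'   proteome fractions. Defaults: 60-point logarithmic grids spanning
#'   1e-4 to 1e-1.
#' @inheritParams excess_trna
#' @return An object of class `tlf_landscape`: list of grid vectors,
#'   matrices `phi_TC`, `free_tu_frac`, `free_charged_trna`, `lambda`,
#'   `residual`, logical `mask`, the `transition` data.frame and
#'   `K_TC_effective`.
#' @export
tc_landscape <- function(tu_grid = NULL, aars_grid = NULL, levels, specs,
                         params) {
  if (is.null(tu_grid))
    tu_grid <- 10^seq(-4, -1, length.out = 60)
  if (is.null(aars_grid))
    aars_grid <- 10^seq(-4, -1, length.out = 60)
  if (any(tu_grid <= 0) || any(aars_grid <= 0) ||
      is.unsorted(tu_grid) || is.unsorted(aars_grid))
    stop("grids must be positive and sorted", call. = FALSE)
  nt <- length(tu_grid); na <- length(aars_grid)
  base <- .tc_base(levels, specs, params)
  # Vectorized bisection over all cells at once: the residual is elementwise
  # arithmetic in phi_TC, so the whole grid is solved in ~100 matrix sweeps.
  TU <- matrix(tu_grid, nt, na)
  AA <- matrix(aars_grid, nt, na, byrow = TRUE)
  phi_act <- params$phi_tl - params$phi_ribo_inactive - base$sum_others -
    TU - AA
  amp <- phi_act * params$avg_len / (base$tau0 * params$len_ribo)
  res_g <- function(G) {
    X <- TU - G
    lamm <- amp * X / (base$K_TC + X)
    r_empty <- params$n_aa * lamm / (base$kon_tc * X)
    params$psi_trna -
      (r_empty + 2 * lamm / params$k_el_max +
         params$n_aa * lamm / (base$kon_aars * AA) +
         r_empty * lamm / (base$kon_tu * G) +
         X / base$len_tu)
  }
  mask <- phi_act <= 0 | res_g(TU * (1 - 1e-12)) < 0
  pinned <- !mask & res_g(TU * 1e-16) > 0
  a <- matrix(log(1e-16), nt, na) + log(TU)
  b <- log(TU * (1 - 1e-12))
  for (it in 1:120) {
    m <- 0.5 * (a + b)
    up <- res_g(exp(m)) > 0
    b[up] <- m[up]
    a[!up] <- m[!up]
  }
  gtp <- exp(0.5 * (a + b))
  gtp[pinned] <- (TU * 1e-16)[pinned]
  phi_TC <- TU - gtp
  lam <- amp * phi_TC / (base$K_TC + phi_TC)
  free_tu <- gtp / TU
  free_aa <- (params$n_aa * lam / (base$kon_tc * phi_TC)) * lam /
    (base$kon_tu * gtp) / params$psi_trna
  resid <- res_g(gtp)
  phi_TC[mask] <- free_tu[mask] <- free_aa[mask] <- lam[mask] <-
    resid[mask] <- NA_real_
  tl_levels <- levels
  if (!("aaRS" %in% names(tl_levels)))
    tl_levels[["aaRS"]] <- aars_grid[1]
  out <- list(tu_grid = tu_grid, aars_grid = aars_grid,
              phi_TC = phi_TC, free_tu_frac = free_tu,
              free_charged_trna = free_aa, lambda = lam, residual = resid,
              mask = mask,
              transition = transition_line(tu_grid, tl_levels, specs,
                                           params),
              K_TC_effective = base$K_TC)
  class(out) <- "tlf_landscape"
  out
}

#' @export
print.tlf_landscape <- function(x, ...) {
  cat(sprintf("Ternary-complex landscape: %d x %d grid, %d masked cells\n",
              length(x$tu_grid), length(x$aars_grid), sum(x$mask)))
  cat(sprintf("  K_TC_effective = %.4g\n", x$K_TC_effective))
  cat(sprintf("  transition line feasible over %d of %d EF-Tu samples\n",
              sum(x$transition$feasible), nrow(x$transition)))
  invisible(x)
}

#' Plot a ternary-complex landscape
#'
#' Image of `phi_TC / K_TC_effective` (log10) over the expression plane with
#' the transition line overlaid.
#'
#' @param x A `tlf_landscape`.
#' @param which One of `"phi_TC"`, `"free_tu_frac"`, `"free_charged_trna"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.tlf_landscape <- function(x, which = "phi_TC", ...) {
  z <- x[[which]]
  if (which == "phi_TC") z <- log10(z / x$K_TC_effective)
  graphics::image(log10(x$tu_grid), log10(x$aars_grid), z,
                  xlab = "log10 phi_Tu", ylab = "log10 phi_aaRS",
                  main = which, ...)
  tr <- x$transition[x$transition$feasible, ]
  graphics::lines(log10(tr$phi_Tu), log10(tr$phi_aars), lwd = 2,
                  col = "orange")
  invisible(x)
}

#' Serialize a landscape to JSON (and optional TSV grid dumps)
#'
#' @param x A `tlf_landscape`.
#' @param path Output JSON path.
#' @param tsv_dir Optional directory for tab-separated matrix dumps.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(x, path, tsv_dir = NULL) {
  doc <- list(tu_grid = x$tu_grid, aars_grid = x$aars_grid,
              K_TC_effective = x$K_TC_effective,
              phi_TC = x$phi_TC, free_tu_frac = x$free_tu_frac,
              free_charged_trna = x$free_charged_trna,
              mask = x$mask, transition = x$transition)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  if (!is.null(tsv_dir)) {
    dir.create(tsv_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("phi_TC", "free_tu_frac", "free_charged_trna")) {
      utils::write.table(x[[nm]], file.path(tsv_dir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}
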