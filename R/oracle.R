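# Independent numerical maximization of the allocation-constrained growth
# rate over factor fractions: exhaustive logarithmic grids (optima span
# decades) followed by coordinate-wise golden-section refinement. Used as
# the verification oracle for every analytic optimum; deliberately avoids
# the analytic square-root forms.

#' Specify a brute-force growth-rate search
#'
#' @param free_factors Character vector of factor names to optimize (at most
#'   3 for the exhaustive grid stage).
#' @param bounds Named list of `c(lo, hi)` proteome-fraction bounds per free
#'   factor.
#' @param resolution Grid points per axis (>= 16).
#' @param refine Number of coordinate-wise golden-section passes.
#' @return A `tlf_search` list.
#' @export
search_spec <- function(free_factors, bounds, resolution = 32, refine = 4) {
  if (resolution < 16) stop("resolution must be >= 16", call. = FALSE)
  for (nm in free_factors) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2 || b[1] <= 0 || b[1] >= b[2])
      stop("bounds for '", nm, "' must be positive with lo < hi",
           call. = FALSE)
  }
  structure(list(free_factors = free_factors, bounds = bounds,
                 resolution = resolution, refine = refine),
            class = "tlf_search")
}

# Growth-rate evaluator at a candidate point. When both EF-Tu and aaRS are
# in play and `use_tc` is set, the ternary complex is obtained from the full
# nonlinear steady state; otherwise the EF-Tu-limited approximation
# phi_TC = phi_Tu is used. With `ts_sequestration`, the EF-Tu(GDP) pool
# awaiting nucleotide exchange, lambda*l_Tu/(kon_Ts*phi_Ts), is charged
# against the allocation (lambda then solves a linear self-consistency).
# Infeasible points score -Inf.
.oracle_lambda <- function(phi_free, search, specs, params, fixed_levels,
                           use_tc, ts_sequestration = FALSE) {
  lv <- fixed_levels
  lv[search$free_factors] <- phi_free
  if (use_tc) {
    others <- lv[setdiff(names(lv), c("EF-Tu", "aaRS"))]
    st <- tryCatch(solve_tc(lv[["EF-Tu"]], lv[["aaRS"]], others, specs,
                            params),
                   error = function(e) NULL)
    if (is.null(st)) return(-Inf)
    return(st$lambda)
  }
  lam <- tryCatch(growth_rate_at(lv, specs, params, "binding_limited"),
                  error = function(e) NA_real_)
  if (!is.finite(lam)) return(-Inf)
  if (ts_sequestration) {
    cyc <- cycle_times(lv, specs, params, "binding_limited")
    B <- params$avg_len / (cyc$tau_tl * params$len_ribo)
    c_tu <- spec_len(specs, "EF-Tu") / spec_kon(specs, "EF-Ts")
    lam <- lam / (1 + B * c_tu / lv[["EF-Ts"]])
  }
  lam
}

#' Brute-force maximization of the growth rate
#'
#' Evaluates the full kinetic model on an exhaustive logarithmic grid over
#' the free factors, then refines each coordinate by golden-section search
#' (on the log scale) to a relative tolerance of 1e-6. Deterministic for
#' fixed inputs.
#'
#' @param search A `tlf_search` from [search_spec()].
#' @param params A `tlf_params` object.
#' @param specs A `tlf_factors` table.
#' @param fixed_levels Named vector of the remaining factor levels.
#' @param use_tc Solve the tRNA-charging steady state for the ternary
#'   complex (required when EF-Tu and aaRS are both free); default guesses
#'   from the free set.
#' @param ts_sequestration Charge the EF-Tu(GDP) pool awaiting nucleotide
#'   exchange against the allocation (for the EF-Ts subsystem).
#' @return List with `argmax` (named vector), `lambda_max`, and `trace`
#'   (data.frame of all grid evaluations).
#' @export
grid_maximize <- function(search, params, specs, fixed_levels,
                          use_tc = all(c("EF-Tu", "aaRS") %in%
                                         search$free_factors),
                          ts_sequestration = FALSE) {
  d <- length(search$free_factors)
  if (d < 1 || d > 3)
    stop("exhaustive grids support 1-3 free factors", call. = FALSE)
  axes <- lapply(search$free_factors, function(nm) {
    b <- search$bounds[[nm]]
    exp(seq(log(b[1]), log(b[2]), length.out = search$resolution))
  })
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- search$free_factors
  lam <- vapply(seq_len(nrow(grid)), function(i)
    .oracle_lambda(grid[i, ], search, specs, params, fixed_levels,
                   use_tc, ts_sequestration),
    0)
  if (all(!is.finite(lam)))
    stop("all grid points infeasible", call. = FALSE)
  best <- which.max(lam)
  x <- grid[best, ]
  lam_best <- lam[best]

  for (pass in seq_len(search$refine)) {
    for (k in seq_len(d)) {
      nm <- search$free_factors[k]
      b <- search$bounds[[nm]]
      f1 <- function(logphi) {
        xx <- x; xx[k] <- exp(logphi)
        .oracle_lambda(xx, search, specs, params, fixed_levels, use_tc,
                       ts_sequestration)
      }
      opt <- stats::optimize(f1, lower = log(b[1]), upper = log(b[2]),
                             maximum = TRUE, tol = 1e-7)
      if (opt$objective >= lam_best) {
        x[k] <- exp(opt$maximum)
        lam_best <- opt$objective
      }
    }
  }
  list(argmax = x, lambda_max = lam_best,
       trace = data.frame(grid, lambda = lam, check.names = FALSE))
}

#' Write an oracle search trace as a tab-separated file
#'
#' @param result A [grid_maximize()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path) {
  utils::write.table(result$trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
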