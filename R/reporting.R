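# Predicted-versus-observed comparison and growth-rate scaling diagnostics.

.known_factors <- c("IF1", "IF2", "IF3", "EF-Tu", "EF-Ts", "EF-G", "aaRS",
                    "RF1", "RF2", "RFI", "RF1+RF2", "RF4", "50S",
                    "ribosome")

#' Load an observed synthesis-fraction table
#'
#' Tab-separated file with header `species`, `factor`, `synthesis_fraction`.
#' A small synthetic three-species table is bundled (see
#' `system.file("extdata", "observed_synthesis_fractions_synthetic.tsv",
#' package = "tlfopt")`).
#'
#' @param path Path to the table; defaults to the bundled synthetic table.
#' @return A validated data.frame of class `tlf_observed`.
#' @export
load_observed <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata",
                        "observed_synthesis_fractions_synthetic.tsv",
                        package = "tlfopt")
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2)
    stop("observed table is empty: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("species", "factor", "synthesis_fraction")))
    stop("observed table must have header: species, factor, ",
         "synthesis_fraction", call. = FALSE)
  rows <- lapply(seq_along(lines[-1]), function(i) {
    parts <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3)
      stop("malformed observed-table row at line ", i + 1, ": '",
           lines[i + 1], "'", call. = FALSE)
    frac <- suppressWarnings(as.numeric(parts[3]))
    if (is.na(frac))
      stop("non-numeric synthesis fraction at line ", i + 1, call. = FALSE)
    data.frame(species = parts[1], factor = parts[2],
               synthesis_fraction = frac, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  bad <- tab$synthesis_fraction <= 0 | tab$synthesis_fraction >= 1
  if (any(bad))
    stop("synthesis fractions must lie in (0, 1); offending factor(s): ",
         paste(unique(tab$factor[bad]), collapse = ", "), call. = FALSE)
  unknown <- setdiff(unique(tab$factor), .known_factors)
  if (length(unknown) > 0)
    warning("unknown factor name(s) in observed table: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  class(tab) <- c("tlf_observed", "data.frame")
  tab
}

#' Compare predicted optimal abundances with observed fractions
#'
#' Averages the observed synthesis fractions over species (unweighted
#' arithmetic mean), joins them with the predicted optima, and reports
#' observed/predicted ratios, the observed and predicted EF-Tu/EF-G ratios,
#' the elongation-versus-initiation/termination hierarchy, and a minimal
#' tRNA-per-ribosome budget diagnostic (2 ribosome sites plus the TC-bound
#' EF-Tu complement).
#'
#' @param allocation A `tlf_allocation` from [solve_self_consistent()].
#' @param observed A `tlf_observed` table from [load_observed()].
#' @param specs The `tlf_factors` table used for the prediction (for the
#'   EF-Tu length in the tRNA budget diagnostic).
#' @return An object of class `tlf_comparison`.
#' @export
compare_observed <- function(allocation, observed,
                             specs = factor_specs(allocation$params)) {
  pred <- vapply(allocation$factors, function(f) f$phi_star, 0)
  names(pred) <- vapply(allocation$factors, function(f) f$name, "")
  obs_mean <- tapply(observed$synthesis_fraction, observed$factor, mean)
  common <- intersect(names(pred), names(obs_mean))
  if (length(common) == 0)
    stop("no overlapping factors between prediction and observation",
         call. = FALSE)
  common <- common[order(match(common, .known_factors))]
  tab <- data.frame(
    factor = common,
    predicted = unname(pred[common]),
    observed_mean = unname(obs_mean[common]),
    ratio_obs_pred = unname(obs_mean[common] / pred[common]),
    stringsAsFactors = FALSE)
  tab$within_2x <- tab$ratio_obs_pred >= 0.5 & tab$ratio_obs_pred <= 2
  tab$within_5x <- tab$ratio_obs_pred >= 0.2 & tab$ratio_obs_pred <= 5

  tu_g_obs <- vapply(split(observed, observed$species), function(d) {
    tu <- d$synthesis_fraction[d$factor == "EF-Tu"]
    g <- d$synthesis_fraction[d$factor == "EF-G"]
    if (length(tu) == 1 && length(g) == 1) tu / g else NA_real_
  }, 0)
  tu_g_pred <- if (all(c("EF-Tu", "EF-G") %in% names(pred)))
    pred[["EF-Tu"]] / pred[["EF-G"]] else NA_real_

  elong <- intersect(c("EF-Tu", "EF-G"), common)
  other <- intersect(c("IF1", "IF2", "IF3", "RFI", "RF1+RF2", "RF1", "RF2",
                       "RF4"), common)
  hierarchy_ok <- length(elong) > 0 && length(other) > 0 &&
    min(pred[elong]) > max(pred[other])

  # EF-Tu complement per ribosome: from the measured stoichiometry when the
  # observed table carries ribosome rows, else from the model optimum.
  len_tu <- spec_len(specs, "EF-Tu")
  len_ribo <- allocation$params$len_ribo
  tu_per_ribo <- if ("ribosome" %in% observed$factor) {
    per_species <- vapply(split(observed, observed$species), function(d) {
      tu <- d$synthesis_fraction[d$factor == "EF-Tu"]
      rb <- d$synthesis_fraction[d$factor == "ribosome"]
      if (length(tu) == 1 && length(rb) == 1)
        (tu / len_tu) / (rb / len_ribo) else NA_real_
    }, 0)
    mean(per_species, na.rm = TRUE)
  } else if ("EF-Tu" %in% names(pred)) {
    (pred[["EF-Tu"]] / len_tu) /
      (allocation$phi_ribo_active_star / len_ribo)
  } else NA_real_

  out <- list(table = tab,
              tu_over_g_observed = tu_g_obs,
              tu_over_g_predicted = tu_g_pred,
              hierarchy_elongation_above_rest = hierarchy_ok,
              max_ratio = max(pmax(tab$ratio_obs_pred,
                                   1 / tab$ratio_obs_pred)),
              trna_budget = list(
                ribosome_sites = 2,
                tc_bound_per_ribosome = unname(tu_per_ribo),
                minimum_per_ribosome = 2 + unname(tu_per_ribo)))
  class(out) <- "tlf_comparison"
  out
}

#' @export
print.tlf_comparison <- function(x, ...) {
  cat("Predicted vs observed translation-factor abundances\n")
  print(x$table, digits = 3, row.names = FALSE)
  cat("EF-Tu/EF-G observed:",
      paste(sprintf("%s %.2g", names(x$tu_over_g_observed),
                    x$tu_over_g_observed), collapse = ", "), "\n")
  cat(sprintf("EF-Tu/EF-G predicted: %.2f\n", x$tu_over_g_predicted))
  cat("Elongation factors predicted above initiation/termination factors:",
      x$hierarchy_elongation_above_rest, "\n")
  cat(sprintf("Minimum tRNA/ribosome budget: 2 ribosome sites + %.1f in TC = %.1f\n",
              x$trna_budget$tc_bound_per_ribosome,
              x$trna_budget$minimum_per_ribosome))
  invisible(x)
}

#' Growth-rate scaling of the optimal abundances
#'
#' Sweeps the translation-sector size, re-solving the self-consistent
#' optimum at each value, and reports `phi*_i / sqrt(lambda*)` per factor.
#' For binding-limited factors this column is constant (the square-root
#' growth law); the synthetase column is not, because the excess tRNA
#' budget shifts with the growth rate.
#'
#' @param params A `tlf_params` object (template; `phi_tl` is replaced).
#' @param specs A `tlf_factors` table.
#' @param phi_tl_values Translation-sector fractions to sweep.
#' @param mode Kinetic regime passed to [solve_self_consistent()].
#' @param include_aars Include the synthetase in the sweep.
#' @return A data.frame: one row per feasible `phi_tl`, with `lambda_star`
#'   and per-factor `phi_star.<name>` and `scaled.<name>` columns
#'   (`phi*/sqrt(lambda*)`).
#' @export
scaling_table <- function(params, specs, phi_tl_values,
                          mode = "binding_limited", include_aars = TRUE) {
  rows <- list()
  for (ptl in phi_tl_values) {
    p <- params
    p$phi_tl <- ptl
    alloc <- tryCatch(
      solve_self_consistent(p, specs, mode, include_aars = include_aars),
      error = function(e) {
        warning("phi_tl = ", ptl, " infeasible: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(alloc)) next
    phis <- vapply(alloc$factors, function(f) f$phi_star, 0)
    names(phis) <- vapply(alloc$factors, function(f) f$name, "")
    row <- c(phi_tl = ptl, lambda_star = alloc$lambda_star,
             stats::setNames(phis, paste0("phi_star.", names(phis))),
             stats::setNames(phis / sqrt(alloc$lambda_star),
                             paste0("scaled.", names(phis))))
    rows[[length(rows) + 1]] <- row
  }
  if (length(rows) == 0) stop("no feasible phi_tl values", call. = FALSE)
  as.data.frame(do.call(rbind, rows), check.names = FALSE)
}
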