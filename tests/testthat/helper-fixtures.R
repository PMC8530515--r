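# Shared fixtures. The default parameterization and the converged optimum
# are computed once per test run and memoized.

.tlf_cache <- new.env(parent = emptyenv())

tlf_params_default <- function() {
  if (is.null(.tlf_cache$params)) .tlf_cache$params <- global_params()
  .tlf_cache$params
}

tlf_specs_default <- function() {
  if (is.null(.tlf_cache$specs))
    .tlf_cache$specs <- factor_specs(tlf_params_default())
  .tlf_cache$specs
}

tlf_alloc_default <- function() {
  if (is.null(.tlf_cache$alloc))
    .tlf_cache$alloc <- solve_self_consistent(tlf_params_default(),
                                              tlf_specs_default())
  .tlf_cache$alloc
}

# Named vector of all optimal factor levels.
tlf_levels_default <- function() {
  alloc <- tlf_alloc_default()
  v <- vapply(alloc$factors, function(f) f$phi_star, 0)
  names(v) <- vapply(alloc$factors, function(f) f$name, "")
  v
}

# Strict relative comparison (expect_equal's tolerance is absolute for
# values below 1, far too lax for proteome fractions of order 1e-4).
expect_rel <- function(object, expected, tol, label = NULL) {
  expect_lt(max(abs(object / expected - 1)), tol, label = label)
}

# Minimal handcrafted specification table with chosen rescaled association
# rates (kon, 1/s per proteome fraction); kon_hat back-computed so that the
# two representations stay consistent.
toy_specs <- function(kon, len, params = tlf_params_default(),
                      kcat = NULL) {
  nm <- names(kon)
  if (is.null(kcat)) kcat <- stats::setNames(rep(Inf, length(nm)), nm)
  out <- data.frame(
    name = nm,
    step = "toy",
    length_aa = unname(len[nm]),
    diffusion = NA_real_,
    kon_hat = unname(kon[nm]) * len[nm] / params$P,
    kcat = unname(kcat[nm]),
    codon_specific = FALSE,
    per_protein_uses = 1,
    kon = unname(kon[nm]),
    stringsAsFactors = FALSE)
  attr(out, "kon_tu") <- 1e5
  attr(out, "kon_tu_hat") <- 1e5 * len[[1]] / params$P
  class(out) <- c("tlf_factors", "data.frame")
  out
}
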