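#' Global cell-scale parameters
#'
#' Constructs the registry of cell-scale constants used throughout the
#' translation-cycle model. All factor abundances are handled internally in
#' proteome-fraction units; molar concentrations appear only at the I/O
#' boundary (see [conc_to_phi()]).
#'
#' @param P In-protein amino-acid concentration of the cell, in micromolar.
#'   Approximately growth-rate independent.
#' @param avg_len Average number of codons per protein, weighted by
#'   expression (see [avg_protein_length()]).
#' @param len_ribo Number of amino acids in the ribosomal proteins of one
#'   ribosome.
#' @param n_aa Number of coarse-grained codon/amino-acid classes. Association
#'   rates of codon-specific reactions are rescaled by `1/n_aa` when the
#'   elongation cycle is collapsed to a single effective codon.
#' @param phi_tl Proteome fraction of the translation sector (ribosomes plus
#'   translation factors), fixed by the nutrient condition.
#' @param phi_ribo_inactive Proteome fraction of inactive ribosomes
#'   (assembly intermediates, hibernating ribosomes).
#' @param psi_trna Total tRNA concentration divided by `P` (dimensionless).
#' @param k_el_max Maximal codon elongation rate in 1/s, excluding the
#'   ternary-complex diffusion contribution. The intrinsic catalytic
#'   residence per codon is `1/k_el_max`.
#' @param stop_freqs Named numeric vector `c(UAA=, UAG=, UGA=)` of genomic
#'   stop-codon usage fractions; must sum to 1.
#' @param k_rna Rate of the mRNA-associated catalytic step of initiation in
#'   1/s; `Inf` in the binding-limited regime.
#' @param k_cat_ini Catalytic rate of the initiation GTPase step in 1/s;
#'   `Inf` in the binding-limited regime.
#'
#' @return An object of class `tlf_params` (a validated list).
#' @examples
#' p <- global_params()
#' p$len_ribo / p$avg_len  # growth-law rescaling factor, 36.5
#' @export
global_params <- function(P = 2.6e6,
                          avg_len = 200,
                          len_ribo = 7300,
                          n_aa = 20,
                          phi_tl = 0.345,
                          phi_ribo_inactive = 0.012,
                          psi_trna = 2.2e-4,
                          k_el_max = 22,
                          stop_freqs = c(UAA = 0.6, UAG = 0.1, UGA = 0.3),
                          k_rna = Inf,
                          k_cat_ini = Inf) {
  p <- list(P = P, avg_len = avg_len, len_ribo = len_ribo, n_aa = n_aa,
            phi_tl = phi_tl, phi_ribo_inactive = phi_ribo_inactive,
            psi_trna = psi_trna, k_el_max = k_el_max,
            stop_freqs = stop_freqs, k_rna = k_rna, k_cat_ini = k_cat_ini)
  validate_global_params(p)
  class(p) <- "tlf_params"
  p
}

validate_global_params <- function(p) {
  num_pos <- c("P", "avg_len", "len_ribo", "n_aa", "phi_tl",
               "phi_ribo_inactive", "psi_trna", "k_el_max", "k_rna",
               "k_cat_ini")
  for (f in num_pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("parameter '", f, "' must be a single positive number", call. = FALSE)
  }
  sf <- p$stop_freqs
  if (!is.numeric(sf) || length(sf) != 3L || any(sf < 0))
    stop("stop_freqs must be three non-negative fractions", call. = FALSE)
  if (is.null(names(sf)) || !setequal(names(sf), c("UAA", "UAG", "UGA")))
    stop("stop_freqs must be named UAA, UAG, UGA", call. = FALSE)
  if (abs(sum(sf) - 1) > 1e-12)
    stop("stop_freqs must sum to 1 (got ", format(sum(sf)), ")", call. = FALSE)
  if (p$phi_tl >= 1)
    stop("phi_tl must be < 1", call. = FALSE)
  if (p$phi_ribo_inactive >= p$phi_tl)
    stop("phi_ribo_inactive must be smaller than phi_tl", call. = FALSE)
  invisible(p)
}

#' @export
print.tlf_params <- function(x, ...) {
  cat("Global translation-model parameters\n")
  cat(sprintf("  P                 %.3g uM\n", x$P))
  cat(sprintf("  <l>               %g codons\n", x$avg_len))
  cat(sprintf("  l_ribo            %g aa\n", x$len_ribo))
  cat(sprintf("  n_aa              %g\n", x$n_aa))
  cat(sprintf("  phi_tl            %g\n", x$phi_tl))
  cat(sprintf("  phi_ribo_inactive %g\n", x$phi_ribo_inactive))
  cat(sprintf("  psi_tRNA          %g\n", x$psi_trna))
  cat(sprintf("  k_el_max          %g /s\n", x$k_el_max))
  cat(sprintf("  stop freqs        UAA %.2f  UAG %.2f  UGA %.2f\n",
              x$stop_freqs[["UAA"]], x$stop_freqs[["UAG"]],
              x$stop_freqs[["UGA"]]))
  invisible(x)
}

#' Read global parameters from a YAML key-value file
#'
#' Keys must be exactly the field names of [global_params()]; unknown keys are
#' a hard error so that typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `tlf_params` object.
#' @export
read_global_params <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(global_params))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0)
    stop("unknown global parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$stop_freqs)) raw$stop_freqs <- unlist(raw$stop_freqs)
  do.call(global_params, raw)
}

# ---- unit conversions -------------------------------------------------------

#' Convert molar concentration to proteome fraction
#'
#' The proteome fraction of protein A is `phi_A = [A] * l_A / P`, where `l_A`
#' is the protein length in amino acids and `P` the in-protein amino-acid
#' concentration.
#'
#' @param conc Concentration in micromolar.
#' @param length_aa Protein length in amino acids (codons).
#' @param P In-protein amino-acid concentration, micromolar.
#' @return Proteome fraction (dimensionless).
#' @seealso [phi_to_conc()], [kon_rescale()]
#' @export
conc_to_phi <- function(conc, length_aa, P) {
  if (any(P <= 0)) stop("P must be positive", call. = FALSE)
  if (any(conc < 0) || any(length_aa < 0))
    stop("conc and length_aa must be non-negative", call. = FALSE)
  conc * length_aa / P
}

#' Convert proteome fraction to molar concentration
#' @param phi Proteome fraction.
#' @inheritParams conc_to_phi
#' @return Concentration in micromolar.
#' @export
phi_to_conc <- function(phi, length_aa, P) {
  if (any(P <= 0)) stop("P must be positive", call. = FALSE)
  if (any(length_aa <= 0)) stop("length_aa must be positive", call. = FALSE)
  phi * P / length_aa
}

#' Rescale an association rate constant to proteome-fraction units
#'
#' Converts a bimolecular association rate constant `kon_hat` (1/uM/s) into
#' the rescaled constant `kon = kon_hat * P / l` (1/s per unit proteome
#' fraction) such that `kon_hat * [A] == kon * phi_A` identically.
#'
#' @param kon_hat Association rate constant, 1/(uM s).
#' @param length_aa Length in amino acids of the species whose proteome
#'   fraction multiplies the rate.
#' @param P In-protein amino-acid concentration, micromolar.
#' @return Rescaled rate in 1/s per unit proteome fraction.
#' @export
kon_rescale <- function(kon_hat, length_aa, P) {
  if (any(length_aa <= 0)) stop("length_aa must be positive", call. = FALSE)
  if (any(kon_hat <= 0) || any(P <= 0))
    stop("kon_hat and P must be positive", call. = FALSE)
  kon_hat * P / length_aa
}

#' Estimate an association rate constant by diffusion scaling
#'
#' Scales a reference measured association rate constant (by default the
#' ternary-complex/ribosome rate) by the summed diffusion coefficients of the
#' reacting species: `kon_hat = ref * (D_A + D_B) / (D_ref_A + D_ref_B)`.
#' This assumes comparable reactive radii and orientational constraints
#' across reactions.
#'
#' @param D_A,D_B Diffusion coefficients of the two reacting species, um^2/s.
#' @param ref_kon_hat Reference association rate constant, 1/(uM s).
#' @param D_ref_A,D_ref_B Diffusion coefficients of the reference reaction's
#'   species (ternary complex and ribosome for the bundled defaults).
#' @return Estimated association rate constant, 1/(uM s).
#' @export
kon_from_diffusion <- function(D_A, D_B, ref_kon_hat = 6.4,
                               D_ref_A, D_ref_B) {
  if (any(c(D_A, D_B, D_ref_A, D_ref_B) <= 0))
    stop("diffusion constants must be positive", call. = FALSE)
  ref_kon_hat * (D_A + D_B) / (D_ref_A + D_ref_B)
}

#' Estimate a diffusion constant from protein size
#'
#' Cube-root scaling with chain length from the Stokes-Einstein relation,
#' anchored on a species with a measured diffusion coefficient:
#' `D = ref_D * (ref_length / length_aa)^(1/3)`.
#'
#' @param length_aa Length of the protein of interest, amino acids.
#' @param ref_length Length of the anchor protein, amino acids.
#' @param ref_D Measured diffusion coefficient of the anchor, um^2/s.
#' @return Estimated diffusion coefficient, um^2/s.
#' @export
diffusion_from_length <- function(length_aa, ref_length, ref_D) {
  if (any(c(length_aa, ref_length, ref_D) <= 0))
    stop("inputs must be positive", call. = FALSE)
  ref_D * (ref_length / length_aa)^(1 / 3)
}

#' Expression-weighted average protein length
#'
#' Computes `<l> = sum(e_i * l_i) / sum(e_i)` from a tabulated expression
#' table, where `e_i` is the protein synthesis rate of gene i (equal to the
#' proteome mass fraction for a stable proteome).
#'
#' @param length_aa Numeric vector of protein lengths in codons.
#' @param synthesis_rate Numeric vector of synthesis rates (weights), same
#'   length; non-negative, not all zero.
#' @return The weighted average length in codons.
#' @export
avg_protein_length <- function(length_aa, synthesis_rate) {
  if (length(length_aa) == 0)
    stop("empty expression table", call. = FALSE)
  if (length(length_aa) != length(synthesis_rate))
    stop("length_aa and synthesis_rate must have equal length", call. = FALSE)
  if (any(synthesis_rate < 0))
    stop("synthesis rates must be non-negative", call. = FALSE)
  tot <- sum(synthesis_rate)
  if (tot == 0) stop("all synthesis rates are zero", call. = FALSE)
  sum(synthesis_rate * length_aa) / tot
}
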