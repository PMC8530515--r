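# Reaction topology of the coarse-grained cycle: for each factor, the species
# whose diffusion sets its association step (the factor itself unless it acts
# through a complex) and the binding partner. EF-Tu reaches the ribosome as
# part of the ternary complex; its secondary reaction (capturing a charged
# tRNA) is handled separately, see kon_tu().
.reaction_map <- list(
  "IF1"   = c(self = "IF1",   partner = "ribosome30S"),
  "IF2"   = c(self = "IF2",   partner = "ribosome30S"),
  "IF3"   = c(self = "IF3",   partner = "ribosome30S"),
  "50S"   = c(self = "50S",   partner = "ribosome30S"),
  "EF-Tu" = c(self = "TC",    partner = "ribosome"),
  "EF-Ts" = c(self = "EF-Ts", partner = "EF-Tu"),
  "EF-G"  = c(self = "EF-G",  partner = "ribosome"),
  "aaRS"  = c(self = "aaRS",  partner = "tRNA"),
  "RFI"   = c(self = "RFI",   partner = "ribosome"),
  "RF1"   = c(self = "RF1",   partner = "ribosome"),
  "RF2"   = c(self = "RF2",   partner = "ribosome"),
  "RF4"   = c(self = "RF4",   partner = "ribosome")
)

#' Read a per-factor parameter table
#'
#' Parses the tab-separated factor table (columns `name`, `step`,
#' `length_aa`, `diffusion_um2_s`, `kon_hat_uM_s`, `kcat_s`,
#' `codon_specific`, `per_protein_uses`). Empty cells mean "absent";
#' `inf` is allowed for `kcat_s` (binding-limited reaction).
#'
#' @param path Path to the table; defaults to the bundled compilation.
#' @return A raw `data.frame`; use [factor_specs()] to complete and validate.
#' @export
read_factor_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "factor_params.tsv", package = "tlfopt")
  tab <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "character", "character", "character",
                                          "logical", "character"))
  expect_cols <- c("name", "step", "length_aa", "diffusion_um2_s",
                   "kon_hat_uM_s", "kcat_s", "codon_specific",
                   "per_protein_uses")
  if (!identical(names(tab), expect_cols))
    stop("factor table must have columns: ",
         paste(expect_cols, collapse = ", "), call. = FALSE)
  num_or_na <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  tab$diffusion_um2_s <- num_or_na(tab$diffusion_um2_s)
  tab$kon_hat_uM_s <- num_or_na(tab$kon_hat_uM_s)
  tab$kcat_s <- num_or_na(ifelse(tolower(tab$kcat_s) == "inf", "Inf",
                                 tab$kcat_s))
  bad <- which(is.na(tab$length_aa) | tab$length_aa < 1)
  if (length(bad) > 0)
    stop("invalid length_aa in factor table row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  tab
}

#' Complete and validate a factor specification table
#'
#' Fills in missing biophysical parameters following the model's estimation
#' strategy: diffusion constants missing from the table are estimated by
#' cube-root size scaling anchored on EF-Tu ([diffusion_from_length()]);
#' association rate constants missing from the table are estimated by
#' scaling the measured ternary-complex/ribosome rate by the summed
#' diffusion coefficients of the reacting species ([kon_from_diffusion()]).
#' Rescaled rates `kon = kon_hat * P / l` (1/s per proteome fraction) are
#' attached for direct use in the kinetic equations.
#'
#' @param params A `tlf_params` object.
#' @param table A raw factor table from [read_factor_table()]; defaults to
#'   the bundled compilation.
#' @return A `tlf_factors` data.frame with columns `name`, `step`,
#'   `length_aa`, `diffusion`, `kon_hat`, `kcat`, `codon_specific`,
#'   `per_protein_uses` (numeric), `kon`, plus attribute `kon_tu`
#'   (rescaled EF-Tu/charged-tRNA capture rate).
#' @export
factor_specs <- function(params = global_params(), table = read_factor_table()) {
  tab <- table
  anchor <- tab[tab$name == "EF-Tu", , drop = FALSE]
  if (nrow(anchor) != 1 || is.na(anchor$diffusion_um2_s))
    stop("factor table must contain an EF-Tu row with a measured diffusion ",
         "constant (size-scaling anchor)", call. = FALSE)
  miss <- is.na(tab$diffusion_um2_s)
  tab$diffusion_um2_s[miss] <- diffusion_from_length(
    tab$length_aa[miss], anchor$length_aa, anchor$diffusion_um2_s)

  dref <- stats::setNames(tab$diffusion_um2_s, tab$name)
  ref_row <- tab[tab$name == "TC", , drop = FALSE]
  if (nrow(ref_row) != 1 || is.na(ref_row$kon_hat_uM_s))
    stop("factor table must contain a TC row carrying the measured ",
         "association rate constant", call. = FALSE)
  ref_kon <- ref_row$kon_hat_uM_s
  D_ref <- dref[["TC"]] + dref[["ribosome"]]

  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]
    rx <- .reaction_map[[nm]]
    if (is.null(rx)) next  # reference species other than TC need no rate
    est <- kon_from_diffusion(dref[[rx[["self"]]]], dref[[rx[["partner"]]]],
                              ref_kon, dref[["TC"]], dref[["ribosome"]])
    if (!is.na(tab$kon_hat_uM_s[i])) {
      message("factor ", nm, ": measured kon_hat (", tab$kon_hat_uM_s[i],
              ") overrides diffusion-scaled estimate (",
              signif(est, 3), ")")
    } else {
      tab$kon_hat_uM_s[i] <- est
    }
  }
  # EF-Tu binds the ribosome as the ternary complex: use the measured anchor.
  tab$kon_hat_uM_s[tab$name == "EF-Tu"] <- ref_kon

  uses <- ifelse(tab$per_protein_uses == "avg_len", params$avg_len,
                 suppressWarnings(as.numeric(tab$per_protein_uses)))
  if (any(is.na(uses) | !(uses == 1 | uses == params$avg_len)))
    stop("per_protein_uses must be 1 or avg_len", call. = FALSE)

  out <- data.frame(name = tab$name, step = tab$step,
                    length_aa = tab$length_aa,
                    diffusion = tab$diffusion_um2_s,
                    kon_hat = tab$kon_hat_uM_s,
                    kcat = tab$kcat_s,
                    codon_specific = tab$codon_specific,
                    per_protein_uses = uses,
                    stringsAsFactors = FALSE)
  out$kon <- NA_real_
  ok <- !is.na(out$kon_hat)
  out$kon[ok] <- kon_rescale(out$kon_hat[ok], out$length_aa[ok], params$P)
  # Secondary EF-Tu reaction: free activated EF-Tu capturing a charged tRNA
  # (codon-agnostic, hence fast relative to the rescaled reactions).
  kon_tu_hat <- kon_from_diffusion(dref[["EF-Tu"]], dref[["aatRNA"]],
                                   ref_kon, dref[["TC"]], dref[["ribosome"]])
  attr(out, "kon_tu_hat") <- kon_tu_hat
  attr(out, "kon_tu") <- kon_rescale(kon_tu_hat,
                                     out$length_aa[out$name == "EF-Tu"],
                                     params$P)
  class(out) <- c("tlf_factors", "data.frame")
  out
}

# Row accessor with a clear error for missing factors.
spec_row <- function(specs, name) {
  i <- match(name, specs$name)
  if (is.na(i)) stop("factor '", name, "' not found in specification table",
                     call. = FALSE)
  specs[i, , drop = FALSE]
}

# Rescaled association rate (1/s per proteome fraction) for a factor.
spec_kon <- function(specs, name) {
  v <- spec_row(specs, name)$kon
  if (is.na(v)) stop("factor '", name, "' has no association rate",
                     call. = FALSE)
  v
}

spec_kcat <- function(specs, name) {
  v <- spec_row(specs, name)$kcat
  if (is.na(v)) Inf else v
}

spec_len <- function(specs, name) spec_row(specs, name)$length_aa

#' @export
print.tlf_factors <- function(x, ...) {
  cat("Translation-factor specification table (", nrow(x), " rows )\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  cat(sprintf("EF-Tu/charged-tRNA capture rate: %.3g /uM/s\n",
              attr(x, "kon_tu_hat")))
  invisible(x)
}
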