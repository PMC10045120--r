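#' Equilibrium protein abundance from mRNA level
#'
#' Fixed point of the synthesis/degradation balance `dP/dt = k_sp R - k_dp P`,
#' i.e. `P = k_sp R / k_dp`. Used to convert per-cell mRNA levels of the
#' mapped redox genes into protein copy numbers.
#'
#' @param mrna_copies Nonnegative mRNA level(s).
#' @param k_sp Translation rate (protein per mRNA per hour).
#' @param k_dp Protein degradation rate (per hour), strictly positive.
#' @return Protein copies, same length as `mrna_copies`.
#' @export
protein_equilibrium <- function(mrna_copies, k_sp, k_dp) {
  if (any(mrna_copies < 0)) stop("mRNA levels must be nonnegative", call. = FALSE)
  if (any(k_dp <= 0)) stop("degradation rate must be > 0", call. = FALSE)
  k_sp * mrna_copies / k_dp
}

#' Linear RNA-to-protein map
#'
#' Fallback for genes without synthesis/degradation rate constants (used for
#' AQP3): `protein = slope * rna + intercept`, floored at zero.
#'
#' @param rna_level Nonnegative RNA level(s).
#' @param slope,intercept Regression coefficients (protein copies per RNA unit).
#' @return Protein copies, floored at 0.
#' @export
protein_linear <- function(rna_level, slope, intercept = 0) {
  if (any(rna_level < 0)) stop("RNA levels must be nonnegative", call. = FALSE)
  if (!all(is.finite(slope))) stop("slope must be finite", call. = FALSE)
  pmax(slope * rna_level + intercept, 0)
}

#' Convert molecule copies to molar concentration
#'
#' @param copies Molecule count(s).
#' @param volume_liters Compartment volume, > 0.
#' @return Concentration in molar: `copies / (N_A * volume)`.
#' @export
copies_to_molar <- function(copies, volume_liters) {
  if (any(volume_liters <= 0)) stop("volume must be > 0", call. = FALSE)
  copies / (6.02214076e23 * volume_liters)
}

#' @rdname copies_to_molar
#' @param molar Concentration(s) in molar.
#' @export
molar_to_copies <- function(molar, volume_liters) {
  if (any(volume_liters <= 0)) stop("volume must be > 0", call. = FALSE)
  molar * 6.02214076e23 * volume_liters
}

#' Read a per-gene rate-constant table
#'
#' TSV with columns `gene`, `k_sp`, `k_dp` and optionally `k_sr`, `k_dr`
#' (mRNA synthesis/degradation). The packaged table
#' `rate_constants_synthetic.tsv` carries synthetic stand-in values with
#' realistic scales (translation 1-100 per hour, protein half-lives
#' 1-100 h); slots are documented for substituting measured constants.
#'
#' @param path TSV path; defaults to the packaged synthetic table.
#' @return data.frame keyed by gene.
#' @export
read_rate_constants <- function(path = system.file(
  "extdata", "rate_constants_synthetic.tsv", package = "redoxcell",
  mustWork = TRUE)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "k_sp", "k_dp") %in% names(tab)))
  if (any(tab$k_dp <= 0, na.rm = TRUE))
    stop("degradation rates must be > 0", call. = FALSE)
  tab
}

#' Read a linear RNA-to-protein map table
#'
#' TSV with columns `gene`, `slope`, `intercept`.
#'
#' @param path TSV path; defaults to the packaged table (AQP3).
#' @return data.frame keyed by gene.
#' @export
read_linear_maps <- function(path = system.file(
  "extdata", "linear_maps_synthetic.tsv", package = "redoxcell",
  mustWork = TRUE)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "slope", "intercept") %in% names(tab)))
  tab
}

#' Per-gene protein abundance for an expression vector
#'
#' Applies the equilibrium synthesis/degradation model gene by gene; genes
#' missing from the rate-constant table fall back to the linear map, and an
#' error names any gene covered by neither. Normalized expression is scaled
#' to mRNA copies by a configurable global factor (counts in scRNA-seq are
#' relative; default scale 1).
#'
#' @param expression Named nonnegative numeric vector (genes).
#' @param constants Rate-constant table from [read_rate_constants()].
#' @param linear_maps Optional linear-map table from [read_linear_maps()].
#' @param scale Global expression-to-copies scale factor.
#' @return Named vector of protein copies.
#' @export
protein_abundances <- function(expression, constants, linear_maps = NULL,
                               scale = 1) {
  genes <- names(expression)
  out <- stats::setNames(numeric(length(genes)), genes)
  for (g in genes) {
    i <- match(g, constants$gene)
    if (!is.na(i)) {
      out[g] <- protein_equilibrium(expression[[g]] * scale,
                                    constants$k_sp[i], constants$k_dp[i])
    } else {
      j <- if (is.null(linear_maps)) NA_integer_ else match(g, linear_maps$gene)
      if (is.na(j))
        stop("no rate constants or linear map for gene '", g, "'", call. = FALSE)
      out[g] <- protein_linear(expression[[g]] * scale,
                               linear_maps$slope[j], linear_maps$intercept[j])
    }
  }
  out
}

#' Fit a linear RNA-to-protein map by least squares
#'
#' @param rna,protein Paired observations.
#' @return A list with `slope` and `intercept`.
#' @export
fit_protein_linear <- function(rna, protein) {
  fit <- stats::lm(protein ~ rna)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}
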