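#' @title Units and dose conversions
#' @name units
#' @description
#' Internal units are fixed throughout the package: amounts in nmol, volumes
#' in mL, time in h, concentrations in nmol/mL. All user-facing inputs
#' (doses in mg of metformin hydrochloride, the clinical unit) are converted
#' at the boundary.
#'
#' Metformin molar mass is fixed at 129.16 g/mol and the hydrochloride
#' salt-to-free-base mass factor at 0.7784, so a 1000 mg hydrochloride dose
#' corresponds to exactly 778.4 mg of free metformin. Both constants are used
#' as-is rather than recomputed from atomic masses so that dose bookkeeping is
#' reproducible to the printed digit.
NULL

#' Metformin molar mass (g/mol)
#' @export
MW_METFORMIN <- 129.16

#' Mass fraction of free metformin base in metformin hydrochloride
#' @export
SALT_FACTOR <- 0.7784

#' Convert milligrams of metformin free base to nmol
#'
#' @param mg amount of metformin free base (mg)
#' @return amount in nmol
#' @export
#' @examples
#' mg_to_nmol(778.4) # a 1000 mg hydrochloride dose, as free base
mg_to_nmol <- function(mg) mg * 1e6 / MW_METFORMIN

#' Convert nmol of metformin to milligrams of free base
#'
#' @param nmol amount (nmol)
#' @return amount in mg free base
#' @export
nmol_to_mg <- function(nmol) nmol * MW_METFORMIN / 1e6

#' Convert a metformin hydrochloride dose (mg) to free base (mg)
#'
#' @param mg_hcl dose in mg of metformin hydrochloride
#' @return dose in mg of metformin free base
#' @export
hcl_to_base_mg <- function(mg_hcl) mg_hcl * SALT_FACTOR

#' Convert a metformin hydrochloride dose (mg) to nmol of free base
#'
#' @param mg_hcl dose in mg of metformin hydrochloride
#' @return dose in nmol of metformin
#' @export
#' @examples
#' dose_hcl_mg_to_nmol(1000) # ~6.0266e6 nmol
dose_hcl_mg_to_nmol <- function(mg_hcl) mg_to_nmol(hcl_to_base_mg(mg_hcl))
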