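#' Rate-law primitives
#'
#' The elementary kinetic forms from which both species models are assembled:
#' flow-limited tissue exchange, Michaelis-Menten carrier transport, linear
#' (non-saturable) transport, and total renal clearance as the sum of
#' glomerular filtration and active tubular secretion.
#'
#' @name rate_laws
NULL

#' Flow-limited (well-stirred) tissue exchange rate
#'
#' Net exchange between a perfusing plasma compartment and a well-stirred
#' tissue: `Q * (C_source - C_tissue / Ktp)`. A positive value is net transport
#' into the tissue; the sign gives the direction.
#'
#' @param Q blood (plasma) flow to the compartment, mL/h; must be >= 0
#' @param C_source perfusing plasma concentration, nmol/mL
#' @param C_tissue tissue concentration, nmol/mL
#' @param Ktp tissue:plasma partition coefficient (dimensionless, > 0)
#' @return net rate, nmol/h
#' @export
#' @examples
#' flow_exchange_rate(5, 2, 0, 4) # 10 nmol/h into the tissue
flow_exchange_rate <- function(Q, C_source, C_tissue, Ktp) {
  if (any(Ktp <= 0)) stop("invalid parameter: Ktp must be > 0", call. = FALSE)
  if (any(Q < 0)) stop("invalid parameter: Q must be >= 0", call. = FALSE)
  Q * (C_source - C_tissue / Ktp)
}

#' Michaelis-Menten transport rate
#'
#' Saturable carrier-mediated transport `Vmax * S / (Km + S)`; monotone
#' non-decreasing in the substrate concentration and bounded by `Vmax`.
#'
#' @param Vmax maximal transport velocity, nmol/h (>= 0)
#' @param Km half-saturation constant, nmol/mL (> 0)
#' @param S substrate-side concentration, nmol/mL (>= 0)
#' @return rate, nmol/h
#' @export
#' @examples
#' michaelis_menten_rate(100, 1, 1) # half-saturation: 50
michaelis_menten_rate <- function(Vmax, Km, S) {
  if (any(S < 0)) stop("invalid state: substrate concentration S < 0", call. = FALSE)
  if (any(Km <= 0)) stop("invalid parameter: Km must be > 0", call. = FALSE)
  if (any(Vmax < 0)) stop("invalid parameter: Vmax must be >= 0", call. = FALSE)
  Vmax * S / (Km + S)
}

#' Linear (non-saturable) transport rate
#'
#' First-order transport `Kd * S`, the non-saturable diffusion component of
#' carrier transport.
#'
#' @param Kd transport coefficient, mL/h (>= 0)
#' @param S substrate-side concentration, nmol/mL
#' @return rate, nmol/h
#' @export
linear_transport_rate <- function(Kd, S) {
  if (any(Kd < 0)) stop("invalid parameter: Kd must be >= 0", call. = FALSE)
  Kd * S
}

#' Total renal clearance
#'
#' Renal clearance of unbound drug as the sum of passive glomerular
#' filtration and active transporter-mediated tubular secretion:
#' `CL_renal = Q_GFR + CL_active`.
#'
#' @param Q_GFR glomerular filtration rate, mL/h (>= 0)
#' @param CL_active active secretion clearance, mL/h (>= 0)
#' @return total renal clearance, mL/h
#' @export
renal_clearance_total <- function(Q_GFR, CL_active) {
  if (any(Q_GFR < 0) || any(CL_active < 0)) {
    stop("invalid parameter: clearances must be >= 0", call. = FALSE)
  }
  Q_GFR + CL_active
}
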