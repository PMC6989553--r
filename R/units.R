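# Unit conversion constants. All internal quantities are SI
# (meters, Pa, m^3/s, Pa.s); reporting helpers convert to the
# conventional units of the field (um, mmHg, ml/min, cm/s).

#' Unit conversion constants
#'
#' Conversion factors between the package's internal SI units and the
#' conventional reporting units used in coronary physiology.
#'
#' @format A named list:
#' \describe{
#'   \item{mmHg_to_Pa}{1 mmHg = 133.322 Pa}
#'   \item{Pa_to_mmHg}{inverse of the above}
#'   \item{m3s_to_mlmin}{m^3/s to ml/min (1e6 * 60)}
#'   \item{m_to_um}{meters to micrometers}
#'   \item{mps_to_cmps}{m/s to cm/s}
#' }
#' @export
units_si <- list(
  mmHg_to_Pa   = 133.322,
  Pa_to_mmHg   = 1 / 133.322,
  m3s_to_mlmin = 1e6 * 60,
  m_to_um      = 1e6,
  um_to_m      = 1e-6,
  mps_to_cmps  = 100
)

#' Convert pressures between mmHg and Pa
#'
#' @param x numeric vector.
#' @return converted numeric vector.
#' @export
mmHg_to_Pa <- function(x) x * units_si$mmHg_to_Pa

#' @rdname mmHg_to_Pa
#' @export
Pa_to_mmHg <- function(x) x * units_si$Pa_to_mmHg
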