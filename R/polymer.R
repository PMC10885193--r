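#' Polymer coil parameters
#'
#' Describes a double-stranded DNA molecule as an ideal (freely jointed)
#' chain: `n_bp` base pairs at `rise_nm_per_bp` nanometres of contour length
#' per base pair, with Kuhn segments of length `kuhn_nm` (twice the
#' persistence length; ~100 nm for dsDNA under physiological conditions).
#'
#' @param n_bp Number of base pairs (non-negative integer).
#' @param rise_nm_per_bp Helical rise per base pair in nm (default 0.34).
#' @param kuhn_nm Kuhn length in nm (default 100).
#' @return An object of class `polymer_params` with the fields above plus
#'   the derived `contour_nm`.
#' @examples
#' polymer_params(20000)
#' @export
polymer_params <- function(n_bp, rise_nm_per_bp = 0.34, kuhn_nm = 100) {
  if (!is.numeric(n_bp) || length(n_bp) != 1L || !is.finite(n_bp) || n_bp < 0)
    stop_invalid("n_bp must be a finite non-negative count")
  check_scalar_pos(rise_nm_per_bp, "rise_nm_per_bp")
  check_scalar_pos(kuhn_nm, "kuhn_nm")
  structure(list(n_bp = n_bp, rise_nm_per_bp = rise_nm_per_bp,
                 kuhn_nm = kuhn_nm,
                 contour_nm = n_bp * rise_nm_per_bp),
            class = "polymer_params")
}

#' Ideal-chain radius of gyration
#'
#' Root-mean-square distance of chain segments from the coil centre of mass
#' for an ideal chain: Rg = sqrt(L * b / 6) with contour length
#' L = n_bp * rise and Kuhn length b. For 10/20/48 kbp dsDNA with the
#' default rise (0.34 nm/bp) and Kuhn length (100 nm) this gives coils of
#' roughly 238, 337 and 522 nm — several times the diffraction-limited spot,
#' which is why a bound molecule images as an extended, lobed blob rather
#' than a compact point-spread function.
#'
#' @param p A [polymer_params()] object.
#' @return Radius of gyration in nm.
#' @examples
#' radius_of_gyration(polymer_params(20000)) # ~337 nm
#' @export
radius_of_gyration <- function(p) {
  if (!inherits(p, "polymer_params")) p <- do.call(polymer_params, as.list(p))
  sqrt(p$contour_nm * p$kuhn_nm / 6)
}

#' Frame period from acquisition rate
#'
#' @param frame_rate_hz Acquisition rate in Hz.
#' @return Frame period in milliseconds (1000 / rate). At the camera rate
#'   used for the movies analysed here, 90.5 Hz, this is ~11 ms.
#' @examples
#' frame_period_ms(90.5)
#' @export
frame_period_ms <- function(frame_rate_hz) {
  check_scalar_pos(frame_rate_hz, "frame_rate_hz")
  1000 / frame_rate_hz
}
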