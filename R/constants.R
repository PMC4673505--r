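# Physical constants and isotope data.

#' Gyromagnetic ratios
#'
#' CODATA / IAEA recommended gyromagnetic ratios for the isotopes handled by
#' the simulator, in rad s^-1 T^-1.  Signs follow the physical sign of the
#' magnetic moment (all isotopes here have gamma > 0 except none).
#'
#' @param isotope character, one of `"1H"`, `"2H"`, `"13C"`, `"14N"`,
#'   `"15N"`, `"17O"`.
#' @return gyromagnetic ratio in rad s^-1 T^-1.
#' @export
#' @examples
#' nmr_gamma("1H") / nmr_gamma("14N")
nmr_gamma <- function(isotope) {
  g <- c(
    "1H"  =  267.5221874e6,
    "2H"  =   41.0662919e6,
    "13C" =   67.2828400e6,
    "14N" =   19.3377980e6,
    "15N" =  -27.1261804e6,
    "17O" =  -36.2808000e6
  )
  if (!isotope %in% names(g)) {
    stop("unknown isotope '", isotope, "'; known: ", paste(names(g), collapse = ", "))
  }
  unname(g[[isotope]])
}

#' Spin quantum numbers of supported isotopes
#' @param isotope character isotope label.
#' @return spin quantum number (1/2 or 1).
#' @export
isotope_spin <- function(isotope) {
  s <- c("1H" = 0.5, "2H" = 1, "13C" = 0.5, "14N" = 1, "15N" = 0.5, "17O" = 2.5)
  if (!isotope %in% names(s)) stop("unknown isotope '", isotope, "'")
  unname(s[[isotope]])
}

#' The magic angle
#'
#' arccos(1/sqrt(3)), the rotor tilt that zeroes the rank-2 Legendre factor
#' P2(cos theta).
#' @return angle in radians.
#' @export
magic_angle <- function() acos(1 / sqrt(3))

# vacuum permeability over 4 pi (T m / A), hbar (J s)
.mu0_over_4pi <- 1e-7
.hbar <- 1.054571817e-34
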