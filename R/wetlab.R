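#' Infection-fraction / MOI conversions
#'
#' Under Poisson infection statistics the fraction of infected cells P and
#' the multiplicity of infection m are linked by P = 1 - exp(-m);
#' \code{moiFromFraction} is the exact inverse.
#'
#' @param m multiplicity of infection, >= 0.
#' @param P infected fraction in [0, 1).
#' @return The converted value.
#' @examples
#' infectedFraction(1)      # 0.6321
#' moiFromFraction(0.5)     # 0.6931
#' @export
infectedFraction <- function(m) {
    stopifnot(all(m >= 0))
    1 - exp(-m)
}

#' @rdname infectedFraction
#' @export
moiFromFraction <- function(P) {
    if (any(P < 0 | P >= 1)) stop("P must be in [0, 1)")
    -log(1 - P)
}

#' Ellipsoid tumor volume from caliper diameters
#'
#' volume = d^2 * D / 2 with d the shortest and D the longest diameter.
#'
#' @param d shortest diameter (mm), > 0.
#' @param D longest diameter (mm), >= d.
#' @return Volume in mm^3.
#' @examples
#' tumorVolume(4, 8)  # 64
#' @export
tumorVolume <- function(d, D) {
    if (any(d <= 0)) stop("d must be positive")
    if (any(d > D)) stop("d must not exceed D")
    d^2 * D / 2
}
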