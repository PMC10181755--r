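#' @include AllClasses.R AllGenerics.R
NULL

#' Jones matrices of the system's optical elements
#'
#' Returns the 2x2 operator for one of the polarization elements used by
#' the four-channel interferometer, in the unnormalized convention under
#' which the closed-form channel intensities carry their 1/4
#' coefficients (global energy scale is immaterial for phase retrieval,
#' which is a ratio of intensity differences).
#'
#' Supported kinds:
#' \describe{
#'   \item{`polarizer45`}{linear polarizer at 45 degrees,
#'     `[[1,1],[1,1]]`.}
#'   \item{`qwp_x`}{quarter-wave plate, fast axis parallel to x,
#'     `[[1,0],[0,i]]`.}
#'   \item{`qwp45_fast`}{quarter-wave plate, fast axis at 45 degrees,
#'     `[[1,-i],[-i,1]]`.}
#'   \item{`qwp45_slow`}{quarter-wave plate, slow axis at 45 degrees,
#'     `[[1,i],[i,1]]`.}
#'   \item{`pbs_transmit`}{polarizing beamsplitter transmission
#'     (p-polarization), `[[1,0],[0,0]]`.}
#'   \item{`pbs_reflect`}{polarizing beamsplitter reflection
#'     (s-polarization) with the half-wave-loss sign flip,
#'     `[[0,0],[0,-1]]`.}
#' }
#'
#' The two PBS kinds take a scalar `prefactor`: `"half"` (default)
#' multiplies by 1/2, the amplitude split of the first beamsplitter
#' passage; `"unit"` gives the bare projection used where the splitter
#' merely routes already-separated orthogonal components.
#'
#' @param kind element kind, see above.
#' @param prefactor `"half"` or `"unit"` (PBS kinds only).
#' @return a [JonesMatrix].
#' @examples
#' elementMatrix("qwp_x")
#' elementMatrix("pbs_reflect")        # (1/2) * [[0,0],[0,-1]]
#' @export
elementMatrix <- function(kind, prefactor = c("half", "unit")) {
  prefactor <- match.arg(prefactor)
  m <- switch(kind,
    polarizer45  = matrix(c(1, 1, 1, 1), 2, 2),
    qwp_x        = matrix(c(1, 0, 0, 1i), 2, 2),
    qwp45_fast   = matrix(c(1, -1i, -1i, 1), 2, 2),
    qwp45_slow   = matrix(c(1, 1i, 1i, 1), 2, 2),
    pbs_transmit = matrix(c(1, 0, 0, 0), 2, 2),
    pbs_reflect  = matrix(c(0, 0, 0, -1), 2, 2),
    stop("unsupported optical element: '", kind, "'", call. = FALSE))
  if (kind %in% c("pbs_transmit", "pbs_reflect") && prefactor == "half")
    m <- m / 2
  new("JonesMatrix", m = m + 0i, label = kind)
}

#' Apply a Jones matrix to a field
#'
#' Componentwise matrix-vector product; for matrix-valued fields the
#' operator acts pixelwise.
#'
#' @param m a [JonesMatrix].
#' @param v a [JonesVector].
#' @return the transformed [JonesVector].
#' @examples
#' v <- jonesVector(1, 0)
#' jonesApply(elementMatrix("polarizer45"), v)  # 45-degree light (1, 1)
#' @export
jonesApply <- function(m, v) {
  stopifnot(is(m, "JonesMatrix"), is(v, "JonesVector"))
  jonesVector(m@m[1, 1] * v@ex + m@m[1, 2] * v@ey,
              m@m[2, 1] * v@ex + m@m[2, 2] * v@ey)
}

#' @describeIn jonesApply matrix product syntax `m %*% v`.
#' @export
setMethod("%*%", signature("JonesMatrix", "JonesVector"),
  function(x, y) jonesApply(x, y))

setMethod("Arith", signature("JonesVector", "JonesVector"),
  function(e1, e2) {
    if (!.Generic %in% c("+", "-"))
      stop("operation '", .Generic, "' not defined for JonesVector pairs")
    jonesVector(callGeneric(e1@ex, e2@ex), callGeneric(e1@ey, e2@ey))
  })

setMethod("Arith", signature("JonesVector", "ANY"),
  function(e1, e2) {
    if (!.Generic %in% c("*", "/"))
      stop("operation '", .Generic, "' not defined for JonesVector and scalar")
    jonesVector(callGeneric(e1@ex, e2), callGeneric(e1@ey, e2))
  })

setMethod("Arith", signature("ANY", "JonesVector"),
  function(e1, e2) {
    if (.Generic != "*")
      stop("operation '", .Generic, "' not defined for scalar and JonesVector")
    jonesVector(e1 * e2@ex, e1 * e2@ey)
  })
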