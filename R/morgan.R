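#' Constants of the Morgan reciprocal-length formula
#'
#' The Morgan formula models axial length (AL, mm) as the reciprocal of a
#' linear combination of corneal curvature and refractive error:
#' \deqn{AL = 1 / (a/CR + b \cdot SER + c)}
#' where `CR` is the anterior corneal radius in mm and `SER` the spherical
#' equivalent refractive error in diopters at the corneal plane. All three
#' constants are reciprocal-length quantities: `a/CR` and `c` are in 1/mm,
#' `b` converts diopters to 1/mm.
#'
#' @param a numerator scale divided by `CR` (mm) to give 1/mm; default 0.22273.
#' @param b diopter-to-reciprocal-mm coefficient (1/(mm D)); default 0.00070.
#' @param c additive reciprocal-length offset (1/mm); default 0.01368.
#'
#' @return An object of class `morgan_constants`, a named list with
#'   elements `a`, `b`, `c`.
#' @examples
#' k <- morgan_constants()
#' al_morgan(7.78, -6.04, k)
#' @export
morgan_constants <- function(a = 0.22273, b = 0.00070, c = 0.01368) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            length(a) == 1L, length(b) == 1L, length(c) == 1L)
  if (!(a > 0 && b > 0 && c > 0)) {
    stop("Morgan constants must all be positive (got a=", a,
         ", b=", b, ", c=", c, ")", call. = FALSE)
  }
  structure(list(a = a, b = b, c = c), class = "morgan_constants")
}

#' @export
print.morgan_constants <- function(x, ...) {
  cat("Morgan formula constants: AL = 1 / (a/CR + b*SER + c)\n")
  cat(sprintf("  a = %.5f (scale over CR, mm)\n", x$a))
  cat(sprintf("  b = %.5f (1/(mm*D))\n", x$b))
  cat(sprintf("  c = %.5f (1/mm)\n", x$c))
  invisible(x)
}

#' Morgan axial-length estimate
#'
#' Evaluates the Morgan formula `AL = 1/(a/CR + b*SER + c)`. The estimate is
#' strictly increasing in `cr` and strictly decreasing in `ser`: flatter
#' corneas and more myopic refractions both imply longer eyes.
#'
#' @param cr anterior corneal radius of curvature, mm (mean of flat and steep
#'   keratometry meridians). Must be positive.
#' @param ser spherical equivalent refractive error, diopters, at the corneal
#'   plane; negative values are myopic.
#' @param constants a [morgan_constants()] object.
#'
#' @return Estimated axial length in mm (vectorized over `cr` and `ser`).
#' @examples
#' al_morgan(7.78, -6.04)  # about 26.26 mm
#' al_morgan(7.78, 0)      # the emmetropic length, 23.64 mm
#' @seealso [al_emmetropia()], [delta_al()], [implied_ser()]
#' @export
al_morgan <- function(cr, ser, constants = morgan_constants()) {
  stopifnot(inherits(constants, "morgan_constants"))
  if (!all(is.finite(cr)) || !all(is.finite(ser))) {
    stop("cr and ser must be finite", call. = FALSE)
  }
  if (any(cr <= 0)) {
    stop("corneal radius must be positive (got ", cr[cr <= 0][1L], " mm)",
         call. = FALSE)
  }
  denom <- constants$a / cr + constants$b * ser + constants$c
  if (any(denom <= 0)) {
    i <- which(denom <= 0)[1L]
    stop(sprintf(paste0("Morgan formula undefined: reciprocal length ",
                        "non-positive for cr=%.3f mm, ser=%.2f D"),
                 rep_len(cr, length(denom))[i], rep_len(ser, length(denom))[i]),
         call. = FALSE)
  }
  1 / denom
}

#' Emmetropic axial length for a given corneal radius
#'
#' The axial length at which an eye with anterior corneal radius `cr` would
#' have zero refractive error under the Morgan formula; identical to
#' `al_morgan(cr, ser = 0)`.
#'
#' @inheritParams al_morgan
#' @return Emmetropic axial length in mm.
#' @examples
#' al_emmetropia(7.78)  # 23.64 mm
#' @export
al_emmetropia <- function(cr, constants = morgan_constants()) {
  al_morgan(cr, ser = 0, constants = constants)
}

#' Axial increment
#'
#' Signed difference between measured axial length and the emmetropic axial
#' length: the model's estimate of myopia-attributable axial elongation.
#' Positive values mean the eye is longer than its emmetropic focal length.
#'
#' @param al measured axial length, mm.
#' @param al_emmetropia emmetropic axial length, mm (see [al_emmetropia()]).
#' @return `al - al_emmetropia`, in mm.
#' @examples
#' delta_al(25.88, 23.59)  # 2.29 mm
#' @export
delta_al <- function(al, al_emmetropia) {
  if (!all(is.finite(al)) || !all(is.finite(al_emmetropia))) {
    stop("al and al_emmetropia must be finite", call. = FALSE)
  }
  al - al_emmetropia
}

#' Refraction implied by an axial length and corneal radius
#'
#' Algebraic inverse of the Morgan formula in `ser`:
#' `ser = (1/al - a/cr - c) / b`. Round-trips with [al_morgan()] to machine
#' precision; returns 0 D when `al` equals [al_emmetropia()] of the same
#' cornea.
#'
#' @param al axial length, mm; must be positive.
#' @inheritParams al_morgan
#' @return Spherical equivalent refractive error in diopters.
#' @examples
#' implied_ser(26.01, 7.78)  # about -5.52 D
#' @export
implied_ser <- function(al, cr, constants = morgan_constants()) {
  stopifnot(inherits(constants, "morgan_constants"))
  if (!all(is.finite(al)) || !all(is.finite(cr))) {
    stop("al and cr must be finite", call. = FALSE)
  }
  if (any(al <= 0)) {
    stop("axial length must be positive (got ", al[al <= 0][1L], " mm)",
         call. = FALSE)
  }
  if (any(cr <= 0)) {
    stop("corneal radius must be positive (got ", cr[cr <= 0][1L], " mm)",
         call. = FALSE)
  }
  (1 / al - constants$a / cr - constants$c) / constants$b
}

#' Keratometric power to corneal radius
#'
#' Converts mean keratometry in diopters to an anterior corneal radius in mm
#' via the keratometric index convention `r = (index - 1) * 1000 / K`
#' (337.5/K at the default index 1.3375).
#'
#' @param k keratometric power, diopters; must be positive.
#' @param index keratometric refractive index; default 1.3375.
#' @return Corneal radius of curvature in mm.
#' @examples
#' keratometry_to_radius(43.38)  # 7.78 mm
#' @export
keratometry_to_radius <- function(k, index = 1.3375) {
  stopifnot(is.numeric(k), is.numeric(index), length(index) == 1L)
  if (!all(is.finite(k)) || any(k <= 0)) {
    stop("keratometric power must be finite and positive", call. = FALSE)
  }
  if (index <= 1) stop("keratometric index must exceed 1", call. = FALSE)
  (index - 1) * 1000 / k
}
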