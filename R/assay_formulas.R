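#' Malondialdehyde content from TBA-assay absorbances
#'
#' MDA is quantified via the thiobarbituric acid reaction from crude leaf
#' extracts read at 532 nm (MDA-TBA adduct), 600 nm (turbidity baseline)
#' and 450 nm (soluble-sugar interference):
#'
#'   MDA (umol/g FW) = \[6.452 (A532 - A600) - 0.559 A450\] x (V/W) x 1000
#'
#' with `V` the supernatant volume in mL and `W` the fresh tissue mass in
#' g. The x1000 factor and mL convention are applied verbatim; reported
#' magnitudes depend on this convention, so keep inputs in the stated
#' units.
#'
#' @param a450,a532,a600 absorbances (unitless, >= 0).
#' @param v supernatant volume (mL, > 0).
#' @param w fresh tissue mass (g, > 0).
#' @return MDA content, umol per g fresh weight. Vectorized.
#' @export
#' @examples
#' mda_content(a450 = 0.10, a532 = 0.20, a600 = 0.05, v = 8, w = 0.15)
mda_content <- function(a450, a532, a600, v, w) {
  if (any(c(a450, a532, a600) < 0)) stop("domain error: absorbance < 0")
  if (any(v <= 0)) stop("domain error: supernatant volume V must be > 0")
  if (any(w <= 0)) stop("domain error: fresh mass W must be > 0")
  (6.452 * (a532 - a600) - 0.559 * a450) * (v / w) * 1000
}

#' Leaf relative water content
#'
#' RWC (%) = 100 (Wf - Wd) / (Wt - Wd), from fresh (Wf), turgid/saturated
#' (Wt) and oven-dry (Wd) leaf weights. The expected ordering
#' Wt >= Wf >= Wd > 0 is checked with a warning (weighing error), not
#' clamped.
#'
#' @param wf fresh weight (g).
#' @param wt turgid weight after saturation (g).
#' @param wd dry weight (g).
#' @return RWC in percent. Vectorized.
#' @export
rwc_percent <- function(wf, wt, wd) {
  if (any(wt == wd)) stop("domain error: turgid and dry weight equal (zero denominator)")
  if (any(wd <= 0)) warning("dry weight <= 0: check balance readings")
  if (any(wf > wt | wf < wd)) {
    warning("weights violate Wt >= Wf >= Wd; value returned unclamped")
  }
  100 * (wf - wd) / (wt - wd)
}

#' Pigment concentration by the Arnon relation
#'
#' C (g/L) = (A x V x 1000) / (E x l) with absorbance `A`, extract volume
#' `V` (mL), molar absorption coefficient `E` (L/(mol cm)) and optical path
#' `l` (cm). The coefficient is pigment- and wavelength-specific and must
#' be supplied by the user; no default coefficient table is imposed.
#'
#' @param a absorbance (unitless).
#' @param v extract volume (mL, > 0).
#' @param e molar absorption coefficient (L/(mol cm), > 0).
#' @param l path length (cm, > 0).
#' @return concentration in g/L. Vectorized.
#' @export
pigment_concentration <- function(a, v, e, l) {
  if (any(e <= 0) || any(l <= 0)) {
    stop("domain error: absorption coefficient E and path length l must be > 0")
  }
  if (any(v <= 0)) stop("domain error: extract volume V must be > 0")
  (a * v * 1000) / (e * l)
}

#' Electrolyte leakage from conductivity readings
#'
#' The standard conductivity-ratio form EL (%) = 100 C_initial / C_total,
#' where `c_initial` is the conductivity of the bathing solution after
#' incubation of intact tissue and `c_total` after complete tissue
#' disruption (boiling). Supplying `c_blank` switches to the
#' blank-corrected form 100 (C1 - C0) / (C2 - C0).
#'
#' @param c_initial conductivity before disruption.
#' @param c_total conductivity after full disruption (> 0).
#' @param c_blank optional blank (solution-only) conductivity.
#' @return EL in percent. Vectorized.
#' @export
el_percent <- function(c_initial, c_total, c_blank = NULL) {
  if (!is.null(c_blank)) {
    c_initial <- c_initial - c_blank
    c_total <- c_total - c_blank
  }
  if (any(c_total == 0)) stop("domain error: total conductivity is zero")
  if (any(c_initial > c_total)) {
    warning("initial conductivity exceeds total; EL > 100%")
  }
  100 * c_initial / c_total
}

#' Batch assay computation over a CSV-style readings table
#'
#' Applies one assay calculator to each row of a readings table with the
#' fixed column names `A450,A532,A600,V,W` (mda), `Wf,Wt,Wd` (rwc),
#' `A,V,E,l` (pigment) or `C_initial,C_total` (el).
#'
#' @param readings data.frame of instrument readings.
#' @param assay one of `"mda"`, `"rwc"`, `"pigment"`, `"el"`.
#' @return the input with an appended `value` column.
#' @export
compute_assays <- function(readings, assay = c("mda", "rwc", "pigment", "el")) {
  assay <- match.arg(assay)
  need <- switch(assay,
    mda = c("A450", "A532", "A600", "V", "W"),
    rwc = c("Wf", "Wt", "Wd"),
    pigment = c("A", "V", "E", "l"),
    el = c("C_initial", "C_total"))
  miss <- setdiff(need, names(readings))
  if (length(miss)) {
    stop("format error: readings table missing column(s): ",
         paste(miss, collapse = ", "))
  }
  readings$value <- switch(assay,
    mda = mda_content(readings$A450, readings$A532, readings$A600,
                      readings$V, readings$W),
    rwc = rwc_percent(readings$Wf, readings$Wt, readings$Wd),
    pigment = pigment_concentration(readings$A, readings$V,
                                    readings$E, readings$l),
    el = el_percent(readings$C_initial, readings$C_total))
  readings
}
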