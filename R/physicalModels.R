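## Closed-form physical models: random-coil linker extension, linker
## decomposition of the mean radius, torus volume and local kinase-domain
## concentration.

#' Random-coil model of the variable linker
#'
#' @param residues number of residues in the disordered linker. The linker
#'   spans residues 301-344; the published arithmetic treats it as a
#'   45-residue chain, which is the default (an inclusive count of 44 can
#'   be configured).
#' @param stepConstant random-walk step constant b (A per sqrt residue).
#' @return object of class \code{"CoilModel"}.
#' @export
coilModel <- function(residues = 45, stepConstant = 3.5) {
  stopifnot(residues >= 1, stepConstant > 0)
  structure(list(residues = residues, stepConstant = stepConstant),
            class = "CoilModel")
}

#' Random-coil linker extension
#'
#' Random-walk scaling of the end-to-end extension of a disordered chain,
#' \eqn{b \sqrt{N}}. With the defaults (b = 3.5 A, N = 45) this gives
#' ~23.5 A, matching the expected extension of the CaMKII variable linker.
#'
#' @param model a [coilModel()].
#' @return expected extension (A).
#' @examples
#' randomCoilExtension()  # ~23.5 A for a 45-residue chain
#' @export
randomCoilExtension <- function(model = coilModel()) {
  stopifnot(inherits(model, "CoilModel"))
  model$stepConstant * sqrt(model$residues)
}

#' Mean linker extension from the mean kinase radius
#'
#' Decomposes the mean measured kinase radius of extension by subtracting
#' the volume already accounted for by ordered structure: the hub-complex
#' radius (55 A) and the kinase/regulatory domain diameter (45 A). With the
#' measured mean radius of ~127 A this yields an average linker extension
#' of ~27 A.
#'
#' @param meanRadius mean kinase radius of extension (A).
#' @param consts a [geometryConstants()] object.
#' @return mean linker extension (A).
#' @examples
#' meanLinkerExtension(127)  # 27 A
#' @export
meanLinkerExtension <- function(meanRadius, consts = geometryConstants()) {
  occupied <- consts$hubRadius + consts$kinaseDiameter
  ext <- meanRadius - occupied
  if (ext < 0)
    stop("mean radius ", meanRadius, " A is below the ", occupied,
         " A occupied by hub and kinase domains: negative linker extension",
         call. = FALSE)
  ext
}

#' Torus model of the kinase-domain occupancy volume
#'
#' The volume swept by the kinase domains around the hub is modelled as a
#' torus with major radius R and minor radius r. The defaults R = 126 A,
#' r = 49 A derive from the minimum and maximum measured kinase radii
#' (77 and 175 A): R is their midpoint and r their half-range (see
#' [torusFromRadiusBounds()]).
#'
#' @param majorRadius R (A).
#' @param minorRadius r (A); must satisfy R > r > 0.
#' @param nKinase number of kinase domains in the holoenzyme.
#' @return object of class \code{"TorusModel"}.
#' @export
torusModel <- function(majorRadius = 126, minorRadius = 49, nKinase = 12) {
  stopifnot(majorRadius > minorRadius, minorRadius > 0, nKinase >= 0)
  structure(list(majorRadius = majorRadius, minorRadius = minorRadius,
                 nKinase = nKinase),
            class = "TorusModel")
}

#' Torus model from radius bounds
#'
#' @param minRadius,maxRadius minimum and maximum kinase radius of
#'   extension (A).
#' @param nKinase number of kinase domains.
#' @return a [torusModel()] with R = (min + max)/2, r = (max - min)/2.
#' @examples
#' torusFromRadiusBounds(77, 175)  # R = 126, r = 49
#' @export
torusFromRadiusBounds <- function(minRadius, maxRadius, nKinase = 12) {
  stopifnot(maxRadius > minRadius, minRadius > 0)
  torusModel((minRadius + maxRadius) / 2, (maxRadius - minRadius) / 2, nKinase)
}

#' Torus volume
#'
#' \eqn{V = (\pi r^2)(2 \pi R) = 2 \pi^2 R r^2}.
#'
#' @param model a [torusModel()].
#' @return volume in cubic Angstrom.
#' @examples
#' torusVolume()  # ~5.97e6 A^3
#' @export
torusVolume <- function(model = torusModel()) {
  stopifnot(inherits(model, "TorusModel"))
  2 * pi^2 * model$majorRadius * model$minorRadius^2
}

#' Local kinase-domain concentration
#'
#' Effective concentration of kinase domains confined to the torus of
#' occupancy: \eqn{(n / N_A) / (V \times 10^{-27}\,\mathrm{L})}, reported
#' in mM. With the defaults (12 kinase domains, R = 126 A, r = 49 A) this
#' is ~3.3 mM, the scale at which even a weak (Kd 200-600 uM) kinase-domain
#' dimerisation becomes significantly populated.
#'
#' @param model a [torusModel()].
#' @return local concentration (mM).
#' @examples
#' localConcentration()  # ~3.3 mM
#' @export
localConcentration <- function(model = torusModel()) {
  avogadro <- 6.02214076e23
  volumeL <- torusVolume(model) * 1e-27
  (model$nKinase / avogadro) / volumeL * 1e3
}
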