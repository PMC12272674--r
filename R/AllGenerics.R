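#' Accessor generics
#'
#' Small accessor generics shared by the container classes: \code{frames}
#' extracts the raw frame array of a \linkS4class{FrameStack},
#' \code{frameMeta} its per-frame metadata, \code{pixelSize} the pixel pitch
#' in micrometres of any gridded object, \code{visibility} the fringe
#' visibility of a \linkS4class{SinusoidFit}, \code{amplitudeTrace} and
#' \code{phaseTrace} the per-frame traces of a \linkS4class{PatternEstimate},
#' and \code{frcResolution} the resolution (nm) stored in a
#' \linkS4class{FrcCurve}.
#'
#' @param x object.
#' @return The slot value; see the class documentation for units.
#' @name accessors
#' @aliases frames frameMeta pixelSize visibility amplitudeTrace phaseTrace
#'   frcResolution
#' @examples
#' fit <- new("SinusoidFit", visibility = 0.9, fringe_vector = c(5, 0),
#'            phase = 0, offset = 1, residual_rms = 0)
#' visibility(fit)
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("frameMeta", function(x) standardGeneric("frameMeta"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("visibility", function(x) standardGeneric("visibility"))

#' @rdname accessors
#' @export
setGeneric("amplitudeTrace", function(x) standardGeneric("amplitudeTrace"))

#' @rdname accessors
#' @export
setGeneric("phaseTrace", function(x) standardGeneric("phaseTrace"))

#' @rdname accessors
#' @export
setGeneric("frcResolution", function(x) standardGeneric("frcResolution"))

#' Intensity of an interference field
#'
#' Collapses the complex three-component electric field to its intensity
#' (sum of squared moduli over the field components).
#'
#' @param x an \linkS4class{InterferenceField}.
#' @return An \linkS4class{IntensityGrid} with the same pixel size.
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
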