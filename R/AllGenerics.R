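#' @rdname GenotypeData-class
#' @param x object.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypeData-class
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname GenotypeData-class
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname GenotypeData-class
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname GenotypeData-class
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname VarianceComponents-class
#' @param x object.
#' @export
setGeneric("varA", function(x) standardGeneric("varA"))

#' @rdname VarianceComponents-class
#' @export
setGeneric("varE", function(x) standardGeneric("varE"))

#' @rdname VarianceComponents-class
#' @export
setGeneric("varP", function(x) standardGeneric("varP"))

#' @rdname VarianceComponents-class
#' @export
setGeneric("h2", function(x) standardGeneric("h2"))

#' @rdname MarkerEffects-class
#' @param x object.
#' @export
setGeneric("markerEffects", function(x) standardGeneric("markerEffects"))

#' @rdname MarkerEffects-class
#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))

#' Kinship values as a plain matrix
#' @param x a GRM or IBSMatrix.
#' @param ... ignored.
#' @export
setGeneric("kinshipValues", function(x, ...) standardGeneric("kinshipValues"))
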