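#' @rdname TruePool-class
#' @param x a package object.
#' @export
setGeneric("poolSpecies", function(x) standardGeneric("poolSpecies"))

#' @rdname LibraryProtocol-class
#' @param x a package object.
#' @export
setGeneric("protocolName", function(x) standardGeneric("protocolName"))

#' @rdname SimulatedLibrary-class
#' @param x a package object.
#' @export
setGeneric("libraryReads", function(x) standardGeneric("libraryReads"))

#' @rdname SimulatedLibrary-class
#' @export
setGeneric("libraryTruth", function(x) standardGeneric("libraryTruth"))

#' @rdname AssignedLibrary-class
#' @param x a package object.
#' @export
setGeneric("compartmentCounts", function(x) standardGeneric("compartmentCounts"))

#' @rdname AssignedLibrary-class
#' @export
setGeneric("targetHits", function(x) standardGeneric("targetHits"))

#' @rdname AssignedLibrary-class
#' @export
setGeneric("spikeinCounts", function(x) standardGeneric("spikeinCounts"))

#' @rdname AssignedLibrary-class
#' @export
setGeneric("mirnaCounts", function(x) standardGeneric("mirnaCounts"))

#' @rdname ReferenceBundle-class
#' @param x a package object.
#' @export
setGeneric("bundleTarget", function(x) standardGeneric("bundleTarget"))

#' @rdname ReferenceBundle-class
#' @export
setGeneric("bundleGenome", function(x) standardGeneric("bundleGenome"))

#' @rdname ReferenceBundle-class
#' @export
setGeneric("bundleMirnas", function(x) standardGeneric("bundleMirnas"))

#' @rdname ReferenceBundle-class
#' @export
setGeneric("bundleSpikeins", function(x) standardGeneric("bundleSpikeins"))

#' @rdname ScreenResult-class
#' @param x a package object.
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname ScreenResult-class
#' @export
setGeneric("effectSize", function(x) standardGeneric("effectSize"))

#' @rdname ScreenResult-class
#' @export
setGeneric("pvalue", function(x) standardGeneric("pvalue"))
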