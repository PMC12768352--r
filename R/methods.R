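# Accessors and show methods.

#' @rdname TruePool-class
#' @export
setMethod("poolSpecies", "TruePool", function(x) x@species)

#' @rdname LibraryProtocol-class
#' @export
setMethod("protocolName", "LibraryProtocol", function(x) x@name)

#' @rdname TruePool-class
#' @export
setMethod("protocolName", "TruePool", function(x) x@protocol)

#' @rdname SimulatedLibrary-class
#' @export
setMethod("libraryReads", "SimulatedLibrary", function(x) x@reads)

#' @rdname SimulatedLibrary-class
#' @export
setMethod("libraryTruth", "SimulatedLibrary", function(x) x@truth)

#' @rdname AssignedLibrary-class
#' @export
setMethod("compartmentCounts", "AssignedLibrary",
          function(x) x@totals$perCompartment)

#' @rdname AssignedLibrary-class
#' @export
setMethod("targetHits", "AssignedLibrary", function(x) x@hits)

#' @rdname AssignedLibrary-class
#' @export
setMethod("spikeinCounts", "AssignedLibrary", function(x) x@spikeinCounts)

#' @rdname AssignedLibrary-class
#' @export
setMethod("mirnaCounts", "AssignedLibrary", function(x) x@mirnaCounts)

#' @rdname ReferenceBundle-class
#' @export
setMethod("bundleTarget", "ReferenceBundle", function(x) x@target)

#' @rdname ReferenceBundle-class
#' @export
setMethod("bundleGenome", "ReferenceBundle", function(x) x@genomeProxy)

#' @rdname ReferenceBundle-class
#' @export
setMethod("bundleMirnas", "ReferenceBundle", function(x) x@mirnas)

#' @rdname ReferenceBundle-class
#' @export
setMethod("bundleSpikeins", "ReferenceBundle", function(x) x@spikeins)

#' @rdname ScreenResult-class
#' @export
setMethod("verdict", "ScreenResult", function(x) x@verdict)

#' @rdname ScreenResult-class
#' @export
setMethod("effectSize", "ScreenResult", function(x) x@effect)

#' @rdname ScreenResult-class
#' @export
setMethod("pvalue", "ScreenResult", function(x) x@pValue)

setMethod("show", "LibraryProtocol", function(object) {
  cat(sprintf("LibraryProtocol '%s' (5'ppp: %s, modified: %s)\n",
              object@name,
              if (object@capturesTriphosphate) "captured" else "lost",
              if (object@capturesModified) "captured" else "lost"))
})

setMethod("show", "SimConfig", function(object) {
  iv <- object@injectedInterval
  cat("SimConfig\n")
  cat(sprintf("  target: %s (%d nt), injected interval [%d, %d)\n",
              object@targetName, nchar(object@targetSequence), iv[1], iv[2]))
  cat(sprintf("  fractions: target %.3f (secondary %.3f), noise %.3f, spike-ins 4 x %.4f\n",
              object@targetFraction, object@secondaryFraction,
              object@noiseFraction, object@spikeinAbundance))
  cat(sprintf("  dicing: %s; hotspot conc. %.3g, strand-bias conc. %.3g\n",
              if (object@phased) sprintf("phased (step %d)", object@phaseStep)
              else "internal initiation",
              object@hotspotConcentration, object@strandBiasConcentration))
  cat(sprintf("  depth %g; seeds: biology %g, sampling %g\n",
              object@depth, object@biologySeed, object@samplingSeed))
})

setMethod("show", "TruePool", function(object) {
  sp <- object@species
  cat(sprintf("TruePool: %d species on '%s' (protocol: %s)\n",
              nrow(sp), object@targetName, object@protocol))
  if (nrow(sp)) {
    tab <- tapply(sp$abundance, sp$origin, sum)
    cat("  abundance by origin:\n")
    for (o in names(tab))
      cat(sprintf("    %-15s %.4f\n", o, tab[[o]] / sum(sp$abundance)))
  }
})

setMethod("show", "SimulatedLibrary", function(object) {
  cat(sprintf("SimulatedLibrary '%s': %d reads (protocol %s, seed %g)\n",
              object@sample, length(object@reads), object@protocol,
              object@samplingSeed))
  if (nrow(object@truth)) {
    tab <- table(object@truth$origin)
    cat("  reads by origin:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
})

setMethod("show", "ReferenceBundle", function(object) {
  cat(sprintf("ReferenceBundle: target '%s' (%d nt), %d genome-proxy seqs, %d miRNAs, %d spike-ins\n",
              names(object@target), Biostrings::width(object@target),
              length(object@genomeProxy), length(object@mirnas),
              length(object@spikeins)))
})

setMethod("show", "AssignedLibrary", function(object) {
  cat(sprintf("AssignedLibrary: %g reads parsed, %g length-filtered\n",
              object@totals$parsed, object@totals$filtered))
  per <- object@totals$perCompartment
  for (k in names(per)) cat(sprintf("  %-11s %g\n", k, per[[k]]))
})

setMethod("show", "ScreenResult", function(object) {
  cat(sprintf("ScreenResult [%s]: verdict %s\n", object@screen,
              object@verdict))
  cat("  effect:",
      paste(sprintf("%s=%.4g", names(object@effect), object@effect),
            collapse = ", "), "\n")
  cat(sprintf("  statistic = %.4g, p = %.4g\n", object@statistic,
              object@pValue))
})
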