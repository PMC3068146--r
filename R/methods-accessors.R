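#' @rdname TissueSig-accessors
#' @export
setMethod("geneIds", "ExprSet", function(x, ...) rownames(x))

#' @rdname TissueSig-accessors
#' @export
setMethod("sampleIds", "ExprSet", function(x, ...) colnames(x))

#' @rdname TissueSig-accessors
#' @export
setMethod("tissueType", "ExprSet", function(x, ...)
  as.character(SummarizedExperiment::colData(x)$tissue[1L]))

#' @rdname TissueSig-accessors
#' @export
setMethod("patientIds", "ExprSet", function(x, ...)
  as.character(SummarizedExperiment::colData(x)$patient_id))

#' @rdname TissueSig-accessors
#' @export
setMethod("endpointNames", "ExprSet", function(x, ...)
  as.character(S4Vectors::metadata(x)$endpoints))

#' @rdname TissueSig-accessors
#' @export
setMethod("endpointLabels", "ExprSet", function(x, endpoint, ...) {
  if (!endpoint %in% endpointNames(x))
    stop("unknown endpoint '", endpoint, "'; available: ",
         paste(endpointNames(x), collapse = ", "))
  stats::setNames(as.integer(SummarizedExperiment::colData(x)[[endpoint]]),
                  colnames(x))
})

#' @rdname TissueSig-accessors
#' @export
setMethod("exprMatrix", "ExprSet", function(x, ...)
  SummarizedExperiment::assay(x, "exprs"))

#' @rdname TissueSig-accessors
#' @export
setMethod("modelRecords", "ModelPopulation", function(x, ...) x@records)

#' @rdname TissueSig-accessors
#' @export
setMethod("marginalInclusion", "ChainSummary",
          function(x, ...) x@marginalInclusion)

#' @rdname TissueSig-accessors
#' @export
setMethod("visitedSubsets", "ChainSummary", function(x, ...) x@visitedSubsets)

#' @rdname TissueSig-accessors
#' @export
setMethod("modelGenes", "RepresentativeModel", function(x, ...) x@genes)

#' @rdname TissueSig-accessors
#' @export
setMethod("modelGenes", "MLHDModel", function(x, ...) x@geneIds)

#' @rdname TissueSig-accessors
#' @param which `"inner"` or `"outer"`.
#' @export
setMethod("modelAccuracy", "RepresentativeModel",
          function(x, which = c("inner", "outer"), ...) {
  which <- match.arg(which)
  if (which == "inner") x@accuracyInner else x@accuracyOuter
})

#' @rdname TissueSig-accessors
#' @export
setMethod("sameTissueAccuracy", "SpecificityResult",
          function(x, ...) x@sameTissue)

#' @rdname TissueSig-accessors
#' @export
setMethod("crossTissueAccuracy", "SpecificityResult",
          function(x, ...) x@crossTissue)

#' @rdname TissueSig-accessors
#' @export
setMethod("pathwayScore", "ScoredPathway", function(x, ...) x@score)

setMethod("show", "ExprSet", function(object) {
  cat("ExprSet (", tissueType(object), " tissue): ",
      nrow(object), " genes x ", ncol(object), " samples\n", sep = "")
  cat("  patients:", length(unique(patientIds(object))),
      " endpoints:", paste(endpointNames(object), collapse = ", "), "\n")
})

setMethod("show", "MLHDModel", function(object) {
  cat("MLHDModel:", length(object@genes), "genes,",
      length(object@classes), "classes")
  if (object@ridge > 0) cat(" (ridge ", format(object@ridge), ")", sep = "")
  cat("\n  genes:", paste(utils::head(object@geneIds, 8), collapse = ", "))
  if (length(object@geneIds) > 8) cat(", ...")
  cat("\n")
})

setMethod("show", "ModelPopulation", function(object) {
  cat("ModelPopulation:", nrow(object@records), "models from",
      length(unique(object@records$run)), "run(s);")
  if (nrow(object@records))
    cat(" best fitness", format(max(object@records$fitness), digits = 4))
  cat("\n")
})

setMethod("show", "ChainSummary", function(object) {
  cat("ChainSummary:", nrow(object@visitedSubsets), "distinct subsets over",
      object@nIterations - object@burnIn, "post-burn-in iterations\n")
})

setMethod("show", "RepresentativeModel", function(object) {
  cat("RepresentativeModel [", object@method, "] ", object@endpoint, " / ",
      object@tissue, ": size ", object@size, "\n", sep = "")
  cat("  inner-CV accuracy ", format(object@accuracyInner, digits = 4),
      ", outer accuracy ", format(object@accuracyOuter, digits = 4),
      "\n  genes: ", paste(object@genes, collapse = ", "), "\n", sep = "")
})

setMethod("show", "SpecificityResult", function(object) {
  cat("SpecificityResult (", object@endpoint, ", signature from ",
      object@signatureTissue, " tissue, ", length(object@sameTissue),
      " repeats)\n", sep = "")
  cat("  same-tissue mean accuracy ",
      format(mean(object@sameTissue), digits = 4),
      "; cross-tissue mean accuracy ",
      format(mean(object@crossTissue), digits = 4), "\n", sep = "")
})

setMethod("show", "ScoredPathway", function(object) {
  cat("ScoredPathway: N=", object@N, " G=", object@G, " s=", object@s,
      " f=", object@f, "; p=", format(object@pRight, digits = 4),
      " score=", format(object@score, digits = 4), "\n", sep = "")
})
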