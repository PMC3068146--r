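#' @name TissueSig-accessors
#' @title Accessors for TissueSig objects
#' @description Small accessor generics for the package's S4 classes.
#' @param x an object.
#' @param ... further arguments for methods.
NULL

#' @rdname TissueSig-accessors
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))

#' @rdname TissueSig-accessors
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname TissueSig-accessors
#' @export
setGeneric("tissueType", function(x, ...) standardGeneric("tissueType"))

#' @rdname TissueSig-accessors
#' @export
setGeneric("patientIds", function(x, ...) standardGeneric("patientIds"))

#' @rdname TissueSig-accessors
#' @export
setGeneric("endpointNames", function(x, ...) standardGeneric("endpointNames"))

#' @rdname TissueSig-accessors
#' @param endpoint endpoint name.
#' @export
setGeneric("endpointLabels",
           function(x, endpoint, ...) standardGeneric("endpointLabels"))

#' @rdname TissueSig-accessors
#' @export
setGeneric("exprMatrix", function(x, ...) standardGeneric("exprMatrix"))

#' @rdname TissueSig-accessors
#' @export
setGeneric("modelRecords", function(x, ...) standardGeneric("modelRecords"))

#' @rdname TissueSig-accessors
#' @export
setGeneric("marginalInclusion",
           function(x, ...) standardGeneric("marginalInclusion"))

#' @rdname TissueSig-accessors
#' @export
setGeneric("visitedSubsets",
           function(x, ...) standardGeneric("visitedSubsets"))

#' @rdname TissueSig-accessors
#' @export
setGeneric("modelGenes", function(x, ...) standardGeneric("modelGenes"))

#' @rdname TissueSig-accessors
#' @export
setGeneric("modelAccuracy", function(x, ...) standardGeneric("modelAccuracy"))

#' @rdname TissueSig-accessors
#' @export
setGeneric("sameTissueAccuracy",
           function(x, ...) standardGeneric("sameTissueAccuracy"))

#' @rdname TissueSig-accessors
#' @export
setGeneric("crossTissueAccuracy",
           function(x, ...) standardGeneric("crossTissueAccuracy"))

#' @rdname TissueSig-accessors
#' @export
setGeneric("pathwayScore", function(x, ...) standardGeneric("pathwayScore"))
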