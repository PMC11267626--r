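#' @rdname ItemBank-accessors
#' @export
setGeneric("discrim", function(x, ...) standardGeneric("discrim"))

#' @rdname ItemBank-accessors
#' @export
setGeneric("thresholds", function(x, ...) standardGeneric("thresholds"))

#' @rdname ItemBank-accessors
#' @export
setGeneric("itemIds", function(x, ...) standardGeneric("itemIds"))

#' @rdname ItemBank-accessors
#' @export
setGeneric("nItems", function(x, ...) standardGeneric("nItems"))

#' @rdname ItemBank-accessors
#' @export
setGeneric("categoryScores", function(x, ...) standardGeneric("categoryScores"))

#' @rdname ResponseDataset-accessors
#' @export
setGeneric("personIds", function(x, ...) standardGeneric("personIds"))

#' @rdname ResponseDataset-accessors
#' @export
setGeneric("sourceResponses", function(x, ...) standardGeneric("sourceResponses"))

#' @rdname ResponseDataset-accessors
#' @export
setGeneric("targetResponses", function(x, ...) standardGeneric("targetResponses"))

#' @rdname ResponseDataset-accessors
#' @export
setGeneric("sourceSums", function(x, ...) standardGeneric("sourceSums"))

#' @rdname ResponseDataset-accessors
#' @export
setGeneric("targetSums", function(x, ...) standardGeneric("targetSums"))

#' @rdname ResponseDataset-accessors
#' @export
setGeneric("trueTraits", function(x, ...) standardGeneric("trueTraits"))

#' @rdname ResponseDataset-accessors
#' @export
setGeneric("nPersons", function(x, ...) standardGeneric("nPersons"))

#' @rdname GPCMFit-accessors
#' @export
setGeneric("itemBank", function(x, ...) standardGeneric("itemBank"))

#' @rdname CVReport-accessors
#' @export
setGeneric("cvSummary", function(x, ...) standardGeneric("cvSummary"))

#' @rdname CVReport-accessors
#' @export
setGeneric("cvFolds", function(x, ...) standardGeneric("cvFolds"))

#' @rdname CVReport-accessors
#' @export
setGeneric("cvScatter", function(x, ...) standardGeneric("cvScatter"))
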