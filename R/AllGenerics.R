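#' @rdname CohortBundle-accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname CohortBundle-accessors
#' @export
setGeneric("survTable", function(x) standardGeneric("survTable"))

#' @rdname CohortBundle-accessors
#' @export
setGeneric("cohortName", function(x) standardGeneric("cohortName"))

#' @rdname TFTargetNetwork-accessors
#' @export
setGeneric("regulons", function(x) standardGeneric("regulons"))

#' @rdname TFTargetNetwork-accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname RiskModel-accessors
#' @export
setGeneric("tfId", function(x) standardGeneric("tfId"))

#' @rdname RiskModel-accessors
#' @export
setGeneric("lncIds", function(x) standardGeneric("lncIds"))

#' @rdname RiskModel-accessors
#' @export
setGeneric("coefs", function(x) standardGeneric("coefs"))

#' @rdname RiskModel-accessors
#' @export
setGeneric("cutpoint", function(x) standardGeneric("cutpoint"))
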