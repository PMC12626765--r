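#' @rdname SumStats-accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname SumStats-accessors
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' @rdname SumStats-accessors
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))

#' @rdname SumStats-accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname SumStats-accessors
#' @export
setGeneric("dropLog", function(x) standardGeneric("dropLog"))

#' @rdname HarmonizedSet-accessors
#' @export
setGeneric("keptInstruments", function(x) standardGeneric("keptInstruments"))

#' @rdname HarmonizedSet-accessors
#' @export
setGeneric("droppedInstruments",
           function(x) standardGeneric("droppedInstruments"))

#' @rdname MRBattery-accessors
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' @rdname MRBattery-accessors
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' @rdname CascadeAudit-accessors
#' @export
setGeneric("auditStages", function(x) standardGeneric("auditStages"))

#' @rdname CascadeAudit-accessors
#' @export
setGeneric("auditDrops", function(x) standardGeneric("auditDrops"))

#' @rdname MediationResult-accessors
#' @export
setGeneric("mediationProportion",
           function(x) standardGeneric("mediationProportion"))

#' @rdname MediationResult-accessors
#' @export
setGeneric("indirectEffect", function(x) standardGeneric("indirectEffect"))

#' @rdname ldSource
#' @export
setGeneric("ldR2", function(ld, a, b) standardGeneric("ldR2"))

#' @rdname ldSource
#' @export
setGeneric("ldDomain", function(ld) standardGeneric("ldDomain"))
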