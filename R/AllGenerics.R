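## Generics. Accessors follow the usual convention of one generic per
## conceptual attribute; computational generics are defined next to their
## methods where single-class, here when shared.

#' @rdname classifyLM
#' @export
setGeneric("classifyLM", function(x) standardGeneric("classifyLM"))

#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname accessors
#' @export
setGeneric("fattyAcyl", function(x) standardGeneric("fattyAcyl"))

#' @rdname accessors
#' @export
setGeneric("esterDonor", function(x) standardGeneric("esterDonor"))

#' @rdname accessors
#' @export
setGeneric("configString", function(x) standardGeneric("configString"))

#' @rdname accessors
#' @export
setGeneric("modules", function(x) standardGeneric("modules"))

#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname accessors
#' @export
setGeneric("acquisition", function(x) standardGeneric("acquisition"))

#' @rdname accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname accessors
#' @export
setGeneric("rmsd", function(x) standardGeneric("rmsd"))

#' @rdname accessors
#' @export
setGeneric("decision", function(x) standardGeneric("decision"))

#' @rdname accessors
#' @export
setGeneric("bestId", function(x) standardGeneric("bestId"))

#' @rdname predictConfigs
#' @export
setGeneric("predictConfigs", function(arch, ...) standardGeneric("predictConfigs"))

#' @rdname hardConstraints
#' @export
setGeneric("hardConstraints", function(arch, ...) standardGeneric("hardConstraints"))
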