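## Generics for the CRN data model, the three simulation semantics and the
## validation layer.  Accessors are generics so that DualRailCircuit (which
## contains ReactionNetwork) inherits them.

#' @import methods
NULL

#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))

#' @export
setGeneric("reactionCount", function(object) standardGeneric("reactionCount"))

#' @export
setGeneric("rateConstants", function(object) standardGeneric("rateConstants"))

#' @export
setGeneric("initialCounts", function(object) standardGeneric("initialCounts"))

#' @export
setGeneric("initialCounts<-",
           function(object, value) standardGeneric("initialCounts<-"))

#' @export
setGeneric("volumetricFactor",
           function(object) standardGeneric("volumetricFactor"))

#' @export
setGeneric("netChange", function(object, reaction) standardGeneric("netChange"))

#' @export
setGeneric("conservedTotals", function(object) standardGeneric("conservedTotals"))

#' @export
setGeneric("drift", function(object, phi) standardGeneric("drift"))

#' @export
setGeneric("propensities",
           function(object, x) standardGeneric("propensities"))

#' @export
setGeneric("jacobianMatrix", function(object, phi) standardGeneric("jacobianMatrix"))

#' @export
setGeneric("diffusionMatrix", function(object, phi) standardGeneric("diffusionMatrix"))

#' @export
setGeneric("simulateODE",
           function(object, horizon, times = NULL, ...) standardGeneric("simulateODE"))

#' @export
setGeneric("simulateSSA",
           function(object, horizon, seed = 1L, ...) standardGeneric("simulateSSA"))

#' @export
setGeneric("simulateLNA",
           function(object, horizon, times = NULL, ...) standardGeneric("simulateLNA"))

#' @export
setGeneric("meanOverPaths",
           function(object, horizon, times = NULL, nPaths = 20L, seed = 1L, ...)
             standardGeneric("meanOverPaths"))

#' @export
setGeneric("crnText", function(object) standardGeneric("crnText"))

#' @export
setGeneric("addInjection",
           function(object, time, reactions) standardGeneric("addInjection"))

#' @export
setGeneric("injections", function(object) standardGeneric("injections"))

#' @export
setGeneric("renameSpecies", function(object, map) standardGeneric("renameSpecies"))

#' @export
setGeneric("inputRails", function(object) standardGeneric("inputRails"))

#' @export
setGeneric("outputRails", function(object) standardGeneric("outputRails"))

#' @export
setGeneric("railMax", function(object) standardGeneric("railMax"))

#' @export
setGeneric("speciesRoles", function(object) standardGeneric("speciesRoles"))

#' @export
setGeneric("composeSeries",
           function(first, second, wiring, crossed = FALSE,
                    instances = c("s1", "s2"))
             standardGeneric("composeSeries"))

#' @export
setGeneric("trajTimes", function(object) standardGeneric("trajTimes"))

#' @export
setGeneric("trajValues", function(object) standardGeneric("trajValues"))

#' @export
setGeneric("speciesAt", function(object, species, t) standardGeneric("speciesAt"))

#' @export
setGeneric("sdAt", function(object, species, t) standardGeneric("sdAt"))

#' @export
setGeneric("exportPrism",
           function(object, bounds = NULL, ...) standardGeneric("exportPrism"))
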