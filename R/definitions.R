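# Disorder definitions: how raw per-code diagnostic reports map onto the
# binary prediction targets. Two targets are composites (bipolar disorder
# aggregates the type I and II codes; psychotic symptoms aggregate
# hallucinations, delusions and the unspecified schizophrenia-spectrum code,
# from the parent interview only); all others are single-code.

#' Define a prediction target from component diagnosis codes
#'
#' @param target target disorder code.
#' @param components character vector (length >= 1) of component diagnosis
#'   codes whose OR forms the target.
#' @param scope which informants count: `"both"` or `"parent_only"`.
#' @return an object of class `disorder_definition`.
#' @export
disorder_definition <- function(target, components = target,
                                scope = c("both", "parent_only")) {
  scope <- match.arg(scope)
  stopifnot(length(target) == 1L, length(components) >= 1L)
  structure(list(target = target, components = components, scope = scope),
            class = "disorder_definition")
}

#' Default disorder definitions
#'
#' The ten prediction targets in their canonical reporting order: major
#' depressive disorder, bipolar disorder (composite of `bd1` and `bd2`),
#' psychotic symptoms (parent-report composite of hallucinations, delusions
#' and the unspecified schizophrenia-spectrum code), ADHD, oppositional
#' defiant disorder, conduct disorder, PTSD, OCD, generalized anxiety
#' disorder and social anxiety disorder.
#'
#' @return a named list of [disorder_definition()] objects.
#' @export
default_disorder_definitions <- function() {
  defs <- list(
    disorder_definition("mdd"),
    disorder_definition("bd", components = c("bd1", "bd2")),
    disorder_definition("ps", components = c("halluc", "delus", "uss"),
                        scope = "parent_only"),
    disorder_definition("adhd"),
    disorder_definition("odd"),
    disorder_definition("cd"),
    disorder_definition("ptsd"),
    disorder_definition("ocd"),
    disorder_definition("gad"),
    disorder_definition("sad")
  )
  stats::setNames(defs, vapply(defs, `[[`, "", "target"))
}

# definitions for a scenario: the canonical set when the scenario uses the
# canonical disorder names, otherwise one identity definition per disorder
definitions_for <- function(disorder_names) {
  if (identical(disorder_names, DISORDERS)) {
    default_disorder_definitions()
  } else {
    stats::setNames(lapply(disorder_names, disorder_definition), disorder_names)
  }
}
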