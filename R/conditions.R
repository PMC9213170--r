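# Classed conditions so callers (and tests) can distinguish failure modes
# without matching on message text.

abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "fcmseg_error")))
}

abort_invalid <- function(msg, ...) abort(msg, "fcmseg_invalid_input", ...)

abort_degenerate_cluster <- function(cluster) {
  abort(
    sprintf("cluster %d has zero total membership (degenerate cluster)", cluster),
    "fcmseg_degenerate_cluster", cluster = cluster
  )
}

abort_degenerate_input <- function(msg, ...) abort(msg, "fcmseg_degenerate_input", ...)

abort_numerical <- function(msg, ...) abort(msg, "fcmseg_numerical_failure", ...)

abort_no_brain <- function(msg = "no brain tissue found above the air threshold") {
  abort(msg, "fcmseg_no_brain_found")
}

abort_invalid_config <- function(msg, ...) abort(msg, "fcmseg_invalid_config", ...)
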