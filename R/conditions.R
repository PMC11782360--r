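#' @keywords internal
vt_stop <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "vt_error")))
}

vt_validate <- function(ok, message) {
  if (!isTRUE(ok)) vt_stop(message, "vt_validation_error")
  invisible(TRUE)
}

# Condition classes used as control-flow signals by the tracer:
#   vt_out_of_bounds       - subvolume requests data outside the global image
#   vt_empty_segmentation  - no voxel reaches the iso level
#   vt_no_outlet           - < 2 truncation boundaries on the local surface
#   vt_unreachable_target  - target cap disconnected from the source in the mask
#   vt_stall_error         - centerline gradient descent failed to reach source
#   vt_validation_error    - invalid user input
#   vt_trace_failed        - tracing failed at the very first step
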