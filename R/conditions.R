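# Classed conditions so callers (and the pipeline's skip logic) can react to
# specific failure modes rather than matching error messages.

xs_error <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "xistscore_error"),
                      call = call))
}

xs_geometry_error     <- function(msg) xs_error(msg, "xs_geometry_error")
xs_parameter_error    <- function(msg) xs_error(msg, "xs_parameter_error")
xs_degenerate_error   <- function(msg) xs_error(msg, "xs_degenerate_error")
xs_segmentation_error <- function(msg) xs_error(msg, "xs_segmentation_error")
xs_no_peak_error      <- function(msg) xs_error(msg, "xs_no_peak_error")
xs_placement_error    <- function(msg) xs_error(msg, "xs_placement_error")
xs_no_chord_error     <- function(msg) xs_error(msg, "xs_no_chord_error")
xs_too_short_error    <- function(msg) xs_error(msg, "xs_too_short_error")
xs_no_signal_error    <- function(msg) xs_error(msg, "xs_no_signal_error")
xs_no_cloud_error     <- function(msg) xs_error(msg, "xs_no_cloud_error")
xs_undefined_z_error  <- function(msg) xs_error(msg, "xs_undefined_z_error")
xs_insufficient_data_error <- function(msg) xs_error(msg, "xs_insufficient_data_error")
xs_degenerate_table_error  <- function(msg) xs_error(msg, "xs_degenerate_table_error")
xs_key_mismatch_error <- function(msg) xs_error(msg, "xs_key_mismatch_error")
xs_config_error       <- function(msg) xs_error(msg, "xs_config_error")
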