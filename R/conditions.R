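#' @keywords internal
#' @noRd
stop_tl <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "targetlr_error"), call = call))
}

# Condition classes used across the package. Each maps one failure mode to a
# stable class so callers can test with tryCatch()/expect_error(class = ...):
#   empty_sequence_error, invalid_residue_error, undefined_score_error,
#   invalid_count_error, duplicate_id_error, unknown_node_error,
#   invalid_input_error, insufficient_universe_error, constant_feature_error,
#   shape_error, missing_labels_error, model_state_error, schema_error,
#   range_error, degenerate_labels_error, insufficient_data_error,
#   leakage_error, config_error
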