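# Classed error conditions so callers (and the CLI) can distinguish bad
# input from genuinely empty results.

guv_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "guv_error")))
}

stop_invalid_input <- function(msg) guv_stop(msg, "guv_invalid_input")
stop_no_placement <- function(msg) guv_stop(msg, "guv_no_placement")
stop_no_object <- function(msg) guv_stop(msg, "guv_no_object")
stop_out_of_range <- function(msg) guv_stop(msg, "guv_out_of_range")
stop_empty_input <- function(msg) guv_stop(msg, "guv_empty_input")
stop_io <- function(msg) guv_stop(msg, "guv_io_error")
stop_degenerate_trace <- function(msg) guv_stop(msg, "guv_degenerate_trace")
stop_ambiguous_surface <- function(msg) guv_stop(msg, "guv_ambiguous_surface")
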