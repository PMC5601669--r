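# Classed conditions so callers can branch on error kind rather than on
# message text. Every error raised by the package carries "mlatc_error".

mlatc_abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "mlatc_error"), call = call))
}

io_error         <- function(msg) mlatc_abort(msg, "mlatc_io_error")
format_error     <- function(msg) mlatc_abort(msg, "mlatc_format_error")
lookup_error     <- function(msg) mlatc_abort(msg, "mlatc_lookup_error")
config_error     <- function(msg) mlatc_abort(msg, "mlatc_config_error")
coverage_error   <- function(msg) mlatc_abort(msg, "mlatc_coverage_error")
input_error      <- function(msg) mlatc_abort(msg, "mlatc_input_error")
model_error      <- function(msg) mlatc_abort(msg, "mlatc_model_error")
evaluation_error <- function(msg) mlatc_abort(msg, "mlatc_evaluation_error")
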