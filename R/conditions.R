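# Classed conditions so callers (and the CLI) can distinguish user errors
# from internal ones.

ml_stop <- function(msg, class) {
  stop(structure(class = c(class, "midlinenet_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

ml_config_error <- function(msg) ml_stop(msg, "midlinenet_config_error")
ml_param_error <- function(msg) ml_stop(msg, "midlinenet_param_error")
ml_validation_error <- function(msg) ml_stop(msg, "midlinenet_validation_error")
ml_io_error <- function(msg) ml_stop(msg, "midlinenet_io_error")
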