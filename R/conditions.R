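# Classed conditions so callers can distinguish error families programmatically.

stop_expvat <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "expvat_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_format <- function(msg, ...) stop_expvat("expvat_format_error", msg, ...)
stop_data <- function(msg, ...) stop_expvat("expvat_data_error", msg, ...)
stop_insufficient <- function(msg, ...) stop_expvat("expvat_insufficient_data", msg, ...)
stop_domain <- function(msg, ...) stop_expvat("expvat_domain_error", msg, ...)
stop_fit <- function(msg, ...) stop_expvat("expvat_fit_error", msg, ...)
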