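# Structured error conditions. Every user-facing failure is one of these
# classes so callers (and the CLI) can react without parsing messages.

stop_rxcov <- function(message, class, call. = FALSE) {
  stop(errorCondition(message, class = c(class, "rxcov_error")))
}

stop_validation <- function(message) stop_rxcov(message, "rxcov_validation_error")
stop_domain <- function(message) stop_rxcov(message, "rxcov_domain_error")
stop_degenerate <- function(message) stop_rxcov(message, "rxcov_degenerate_error")
stop_insufficient <- function(message) stop_rxcov(message, "rxcov_insufficient_data_error")
stop_pairing <- function(message) stop_rxcov(message, "rxcov_pairing_error")
stop_config <- function(message) stop_rxcov(message, "rxcov_config_error")

warn_rxcov <- function(message) {
  warning(warningCondition(message, class = "rxcov_warning"))
}
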