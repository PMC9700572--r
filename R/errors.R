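# classed conditions so callers can distinguish failure modes programmatically;
# every class is prefixed "annulusFD_" and also inherits "annulusFD_error"
abort_afd <- function(msg, class) {
  stop(errorCondition(msg,
                      class = c(paste0("annulusFD_", class), "annulusFD_error")))
}

warn_afd <- function(msg, class) {
  warning(warningCondition(msg,
                           class = c(paste0("annulusFD_", class),
                                     "annulusFD_warning")))
}
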