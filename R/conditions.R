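# Classed conditions so callers/tests can distinguish contract violations
# (programming errors) from data problems.

abort_attnseg <- function(msg, class) {
  stop(structure(
    class = c(class, "attnseg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

validation_error <- function(msg) abort_attnseg(msg, "attnseg_validation_error")
contract_error   <- function(msg) abort_attnseg(msg, "attnseg_contract_error")
format_error     <- function(msg) abort_attnseg(msg, "attnseg_format_error")
data_error       <- function(msg) abort_attnseg(msg, "attnseg_data_error")
numerical_error  <- function(msg) abort_attnseg(msg, "attnseg_numerical_error")

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    validation_error(sprintf("'%s' must be a finite scalar number", name))
  if (positive && x <= 0)
    validation_error(sprintf("'%s' must be > 0", name))
  invisible(x)
}

MODALITIES <- c("t1", "t1ce", "t2", "flair")
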