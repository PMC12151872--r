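# Classed error helpers so callers can distinguish user-input problems
# from degenerate designs without matching message strings.

stop_input <- function(msg, class = "longescreen_input_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "longescreen_error")))
}

stop_degenerate <- function(msg) {
  stop_input(msg, class = "longescreen_degenerate_error")
}

stop_insufficient <- function(msg) {
  stop_input(msg, class = "longescreen_insufficient_data_error")
}

stop_config <- function(msg) {
  stop_input(msg, class = "longescreen_config_error")
}

stop_join <- function(msg) {
  stop_input(msg, class = "longescreen_join_error")
}

stop_schema <- function(msg) {
  stop_input(msg, class = "longescreen_schema_error")
}

check_flag <- function(x, nm) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_input(sprintf("`%s` must be TRUE or FALSE", nm))
  x
}

check_number <- function(x, nm, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input(sprintf("`%s` must be a single finite number", nm))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_input(sprintf("`%s` = %g is outside its allowed range", nm, x))
  x
}
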