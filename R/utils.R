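#' @importFrom rlang %||% abort warn
#' @importFrom stats sd var cor fft rnorm runif plogis optim pnorm dhyper
#' @importFrom utils head tail
NULL

# internal: stop with a classed condition so tests can assert on error class
stop_bci <- function(msg, class = "streambci_error") {
  rlang::abort(msg, class = class)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_bci(sprintf("`%s` must be a single finite number in [%g, %g].", name, lower, upper))
  }
  invisible(x)
}

match_stream <- function(x) {
  if (!is.character(x) || length(x) != 1L || !x %in% c("left", "right")) {
    stop_bci("stream/attended side must be \"left\" or \"right\".")
  }
  x
}

# sign convention used throughout: right = +1, left = -1
side_sign <- function(side) ifelse(side == "right", 1, -1)
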