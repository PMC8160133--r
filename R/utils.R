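# internal helpers shared across modules

# round to nearest integer, exact halves away from zero (R's round() is
# round-half-even; the reported absolute copies must use one fixed rule)
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

weighted_mean2 <- function(x, w) {
  sum(x * w) / sum(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cnh <- function(..., class = "cnh_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
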