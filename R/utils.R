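# Internal helpers: classed conditions and small utilities.

hf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "hospflow_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numeric formatting used everywhere a value ends up in a serialized log:
# fixed, locale-independent, trailing-zero free.
hf_num <- function(x) {
  s <- formatC(x, format = "fg", digits = 12)
  gsub(" ", "", s)
}

hf_is_id <- function(x) is.character(x) && length(x) == 1L && nzchar(x)
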