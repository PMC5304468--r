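#' @keywords internal
"_PACKAGE"

## Condition constructors. Input errors (bad variable names, malformed
## queries) and resource-limit errors (enumeration above the cap) are kept
## distinct so callers -- in particular the CLI -- can map them to exit codes.

stop_input <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("causalplanr_input_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_resource <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("causalplanr_resource_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## shared cache for per-space independence tables (see run_loop)
.cpr_cache <- new.env(parent = emptyenv())
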