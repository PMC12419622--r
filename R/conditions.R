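# Classed conditions so callers (and the CLI) can map failures to exit codes.

arc_error <- function(msg, class) {
  stop(structure(
    class = c(class, "arcmetrics_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

arc_input_error      <- function(msg) arc_error(msg, "arcmetrics_input_error")
arc_domain_error     <- function(msg) arc_error(msg, "arcmetrics_domain_error")
arc_geometry_error   <- function(msg) arc_error(msg, "arcmetrics_geometry_error")
arc_format_error     <- function(msg) arc_error(msg, "arcmetrics_format_error")
arc_malformed_plan   <- function(msg) arc_error(msg, "arcmetrics_malformed_plan")
arc_unsupported_plan <- function(msg) arc_error(msg, "arcmetrics_unsupported_plan")
arc_undefined_metric <- function(msg) arc_error(msg, "arcmetrics_undefined_metric")

# Run code with a private RNG state; never touches the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
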