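`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the previous RNG state so
#' callers' random streams are not disturbed. Used by every seeded entry
#' point in the package.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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

# Condition constructors. The CLI maps these onto exit codes
# (config -> 2, data -> 3, numerical -> 4).
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("sadln_config_error", "error")))
}
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("sadln_data_error", "error")))
}
stop_numerical <- function(...) {
  stop(errorCondition(paste0(...), class = c("sadln_numerical_error", "error")))
}

sadln_log <- function(...) {
  if (isTRUE(getOption("sadln.verbose", FALSE))) message(...)
}
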