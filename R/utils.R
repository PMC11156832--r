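# internal helpers shared across modules

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded operations never
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

#' Sample quantiles with linear interpolation between closest ranks
#' (type 7), the convention used throughout for box-plot style summaries.
#' @noRd
pctl <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

# quiet logger: collects one-line messages; used to build provenance logs
log_line <- function(log, ...) c(log, paste0(...))
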