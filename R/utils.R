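`%||%` <- function(a, b) if (is.null(a)) b else a

# Error helpers: conditions carry a class so callers (and the CLI) can map
# validation vs degenerate-analysis failures to distinct exit codes.
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("tipi_validation_error", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("tipi_degenerate_error", "error")))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("tipi_usage_error", "error")))
}

# Run `expr` with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards so generators do not perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

# Render-time rounding, matching conventional clinical-paper precision:
# p-values to 3 decimals, percentages to 1, odds ratios to 3.
fmt_p <- function(p) ifelse(is.na(p), "NA",
  ifelse(p < 0.0005, "<0.001", sprintf("%.3f", p)))
fmt_pct <- function(x) sprintf("%.1f", x)
fmt_or <- function(x) sprintf("%.3f", x)
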