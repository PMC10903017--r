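# Internal helpers shared across modules.

# Canonical amino-acid alphabet (20 letters); X tolerated for unknowns.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "-"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never clobber user-level streams.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# Classed conditions so callers can distinguish failure modes programmatically.
cz_stop <- function(class, ...) {
  stop(structure(class = c(class, "consenzyme_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_input <- function(...) cz_stop("consenzyme_input_error", ...)
stop_format <- function(...) cz_stop("consenzyme_format_error", ...)
stop_alphabet <- function(...) cz_stop("consenzyme_alphabet_error", ...)
stop_symbol <- function(...) cz_stop("consenzyme_symbol_error", ...)
stop_bounds <- function(...) cz_stop("consenzyme_bounds_error", ...)
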