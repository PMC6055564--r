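# internal helpers shared across modules

# classed error so callers can distinguish failure modes programmatically
pf_error <- function(message, class) {
  stop(structure(
    class = c(class, "ploidyfit_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run `expr` with a private RNG stream; the caller's .Random.seed is untouched
with_private_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  # pinned generator so fixtures reproduce across R versions and platforms
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}
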