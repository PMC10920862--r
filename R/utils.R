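# Save / restore global RNG state so seeded simulations do not disturb the
# caller's random stream.
save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state))
    assign(".Random.seed", state, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
  invisible(NULL)
}

# Format a number for CSV output: 6 significant digits, empty cell for NA.
fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", trimws(formatC(x, digits = 6, format = "g")))
  as.character(out)
}
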