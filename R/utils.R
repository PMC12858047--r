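# shared helpers: seeded evaluation and classed error conditions

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a bounded child seed from a master seed and a purpose label
derive_seed <- function(seed, what) {
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

ecg_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "ecgtune_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
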