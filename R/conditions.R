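# structured conditions: every error/warning raised by the package carries a
# subclass so callers (and tests) can dispatch on the failure mode rather
# than on message text.

cd_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "chrysodev_error"), call = call))
}

cd_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "chrysodev_warning")))
}

# evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched (no silent global side effects from simulators)
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    cd_stop("a single integer seed is required", "chrysodev_config_error")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}
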