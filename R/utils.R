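# evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# append a line to the run log when a log path is configured
log_line <- function(log_path, ...) {
  if (is.null(log_path)) return(invisible())
  cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  invisible()
}
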