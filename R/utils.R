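# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so seeded helpers do not perturb the
# session stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible sub-seed from a master seed and a stream index.
# Kept strictly below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 +
                as.numeric(stream) * 7919 + 1) %% 2147483629)
}

# Dimension / dimname agreement between two matrices sharing term order.
check_same_terms <- function(a, b, what_a, what_b) {
  if (!identical(dim(a), dim(b))) {
    stop(what_a, " and ", what_b, " have mismatched dimensions (",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"), ")")
  }
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    stop(what_a, " and ", what_b, " disagree on term order")
  }
  invisible(TRUE)
}
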