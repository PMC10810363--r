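# RNG scoping and seed derivation ------------------------------------------

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}

#' Derive per-task sub-seeds from a master seed
#'
#' One sub-seed is drawn per task from a RNG stream seeded with the master
#' seed, so each task's randomness is a pure function of (master seed, task
#' index) and results do not depend on scheduling or worker count.
#'
#' @param master_seed Integer master seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of `n` seeds in [1, 2^31 - 2].
#' @export
derive_seeds <- function(master_seed, n) {
  with_seed(as.integer(master_seed),
            sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# misc ----------------------------------------------------------------------

dataset_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# numeric formatting used by all serialized outputs: full precision,
# locale-independent, deterministic
num_chr <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE,
                                   trim = TRUE)
  }, character(1))
}
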