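# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All stochastic operations in the package funnel through this so that a
## seed argument fully determines the output without clobbering the session.
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
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

## Derive a per-stage seed from one master seed. Kept below 2^31 - 1.
## The splitting rule is documented in the methods vignette: each named
## stage has a fixed offset, so one master seed reproduces a whole run.
derive_seed <- function(master, stage) {
  offsets <- c(
    tree = 101L, study = 211L, alpha = 307L, beta = 401L,
    assembly = 503L, timedecay = 601L, permanova = 701L,
    mantel = 809L, convergence = 907L
  )
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(master) * 1009 + offsets[[stage]]) %% 2147483629)
}

## Lower-triangle pair index table for n samples (i < j).
pair_index <- function(n) {
  if (n < 2) return(matrix(integer(0), ncol = 2))
  idx <- utils::combn(n, 2)
  cbind(i = idx[1, ], j = idx[2, ])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
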