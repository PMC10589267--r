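#' Derive independent named RNG streams from one global seed
#'
#' Builds a set of named random-number streams that are deterministic
#' functions of `(global_seed, name)`. Each stream owns its own
#' `.Random.seed` state, so the draw pattern of one module never perturbs
#' another: consuming more numbers from the `"dataset"` stream leaves the
#' `"training"` stream untouched.
#'
#' @param global_seed integer scalar; the single experiment-level seed.
#' @param names character vector of stream names to create eagerly. Streams
#'   for other names are created lazily on first use.
#' @return an object of class `rng_tree`; use [with_stream()] to evaluate
#'   code under a stream.
#' @examples
#' tr <- seeded_rng_tree(7)
#' a <- with_stream(tr, "dataset", rnorm(3))
#' b <- with_stream(tr, "training", rnorm(3))
#' @export
seeded_rng_tree <- function(global_seed, names = character()) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L,
            is.finite(global_seed))
  tree <- new.env(parent = emptyenv())
  tree$global_seed <- as.integer(global_seed)
  tree$streams <- new.env(parent = emptyenv())
  class(tree) <- "rng_tree"
  for (nm in names) stream_state(tree, nm)
  tree
}

# deterministic 31-bit hash of (seed, name); keeps derived seeds < 2^31
stream_seed <- function(global_seed, name) {
  h <- as.double(global_seed) %% 2147483647
  for (ch in utf8ToInt(name)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

stream_state <- function(tree, name) {
  if (is.null(tree$streams[[name]])) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    set.seed(stream_seed(tree$global_seed, name))
    tree$streams[[name]] <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
  tree$streams[[name]]
}

#' Evaluate an expression under a named RNG stream
#'
#' Swaps the stream's state into the session RNG, evaluates `expr`, then
#' saves the advanced state back into the tree and restores the previous
#' session RNG state.
#'
#' @param tree an [seeded_rng_tree()] object.
#' @param name stream name.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_stream <- function(tree, name, expr) {
  stopifnot(inherits(tree, "rng_tree"))
  st <- stream_state(tree, name)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", st, envir = globalenv())
  on.exit({
    tree$streams[[name]] <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# run expr under set.seed(seed) without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
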