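#' @keywords internal
#' @importFrom dplyr .data
"_PACKAGE"

# Canonical class order used everywhere: confusion-matrix axes, probability
# columns, tie-breaking. Position 1 wins argmax ties.
OCT_CLASSES <- c("normal", "drusen", "cnv")

#' Canonical class labels
#'
#' Returns the three diagnostic classes in their canonical order
#' (`normal`, `drusen`, `cnv`). This order fixes probability-matrix columns,
#' confusion-matrix axes and argmax tie-breaking throughout the package.
#'
#' @return Character vector of length 3.
#' @export
oct_classes <- function() OCT_CLASSES

as_oct_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), OCT_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(OCT_CLASSES, collapse = ", "), ")",
         call. = FALSE)
  }
  factor(x, levels = OCT_CLASSES)
}

# Derive a reproducible sub-seed from a root seed and a stream name, so that
# independent randomness sources (cohort, split, subset, training) do not share
# a stream. Stays inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(name, " must be a single finite number in [", lower, ", ", upper, "]",
         call. = FALSE)
  }
  invisible(x)
}
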