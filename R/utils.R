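#' Derive a reproducible child seed
#'
#' Hashes a root seed together with arbitrary key components (condition
#' parameters, iteration index, method name, ...) into an integer seed below
#' 2^31. Used by the benchmark runner so that every (condition, iteration)
#' cell draws from an independently reproducible stream, regardless of the
#' order in which cells are executed.
#'
#' @param root_seed integer root seed.
#' @param ... key components; coerced to character and hashed.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "pearson", 3)
child_seed <- function(root_seed, ...) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1)
  parts <- vapply(list(...), function(x) {
    paste(format(x, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = ",")
  }, character(1))
  key <- paste(parts, collapse = "|")
  h <- as.double(abs(root_seed)) %% 2147483647
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# set.seed only when a seed was supplied
.maybe_seed <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)
}
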