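# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map2 imap
NULL

# Run code with a private RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a per-operation sub-seed from a master seed, kept inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

# Overflow-safe log of the mean of exp(x).
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

# session cache for permutation index matrices (keyed by n, B, seed);
# regenerating 10^6 permutations per network call would dominate runtime
.perm_cache <- new.env(parent = emptyenv())

cached_perms <- function(n, B, seed) {
  key <- paste(n, B, seed, sep = "_")
  got <- get0(key, envir = .perm_cache)
  if (!is.null(got)) return(got)
  val <- with_seed(seed, vapply(seq_len(B), function(i) sample.int(n),
                                integer(n)))
  if (length(ls(.perm_cache)) > 4) rm(list = ls(.perm_cache)[1], envir = .perm_cache)
  assign(key, val, envir = .perm_cache)
  val
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
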