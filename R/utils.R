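#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median quantile rnorm runif sd setNames kmeans dist
#' @importFrom utils write.table
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is left untouched. `seed = NULL` uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Spawn a reproducible child seed (< 2^31) from the current stream.
next_seed <- function() sample.int(.Machine$integer.max, 1L)

assert_that <- function(ok, msg) if (!isTRUE(ok)) abort(msg)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Format cycle-length estimates with their censoring state
#'
#' Right-censored estimates (labelling difference too small to resolve the
#' cycle length below the cap) are printed as `"> <cap> h"`.
#'
#' @param t_c_h Numeric vector of cycle-length estimates in hours.
#' @param censored Logical vector marking right-censored entries.
#' @param digits Digits used for uncensored values.
#' @return Character vector.
#' @export
#' @examples
#' format_cycle_length(c(8, 32), censored = c(FALSE, TRUE))
format_cycle_length <- function(t_c_h, censored, digits = 2) {
  ifelse(censored, sprintf("> %g h", t_c_h),
         sprintf("%.*f h", digits, t_c_h))
}
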