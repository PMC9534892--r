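#' @keywords internal
"_PACKAGE"

#' @importFrom stats rpois rbinom rnbinom runif median p.adjust pbinom pt sd
#'   setNames quantile rmultinom
#' @importFrom utils write.table read.table head tail
NULL

# Deterministic child-seed derivation from one root seed. Keeps every derived
# seed a valid 32-bit integer so the same root reproduces the whole tree.
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807 + 1) %%
               2147483629)
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_taqmap <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_taqmap("'%s' must be a single number", name)
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stop_taqmap("'%s' = %s is outside its allowed range", name, format(x))
  invisible(x)
}
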