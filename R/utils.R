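#' Derive a reproducible child seed
#'
#' Expands a single top-level seed into independent per-component seeds via a
#' deterministic label hash, so that each stage of a pipeline (task build,
#' agent simulation, fitting, recovery) can be re-run in isolation. The same
#' seed and labels always yield the same child seed.
#'
#' @param seed Integer top-level seed.
#' @param ... Character or numeric labels naming the component (e.g.
#'   `"walk"`, participant index, condition).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' ca_seed(1, "walk", 2)
#' @export
ca_seed <- function(seed, ...) {
  labs <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(labs)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate code under a temporary RNG seed, restoring global RNG state after.
# seed = NULL leaves the RNG alone (caller manages state).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Round half away from zero (symmetric around the negative start values),
# unlike base round()'s round-half-even.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
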