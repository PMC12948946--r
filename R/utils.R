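#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
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
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit seed derived from a master seed and a stage label, so
# toggling one pipeline stage never shifts another stage's random stream.
stage_seed <- function(master_seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(master_seed) * 48271 + h) %% 2147483647)
}

#' Significance stars
#'
#' Converts p-values to the star convention used throughout the package's
#' tabular output: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns`
#' otherwise. Missing p-values yield `NA`.
#'
#' @param p numeric vector of p-values.
#' @return character vector of the same length.
#' @export
significance_stars <- function(p) {
  out <- ifelse(is.na(p), NA_character_,
    ifelse(p < 0.001, "***",
      ifelse(p < 0.01, "**",
        ifelse(p < 0.05, "*", "ns"))))
  out
}

# shared input check
assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
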