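# Internal helpers shared across modules: affine scaling, seeded RNG,
# sub-seed derivation, and the fixed quartile convention.

#' Affine scaler between an original range and a target range
#'
#' Linear map used to condition nutrient and response values onto
#' `[-1, 1]` before tanh fitting, and to map fitted parameters back.
#' The composition `scaler_invert(scaler_apply(x))` is the identity.
#'
#' @param from numeric length-2, original `(min, max)`; must satisfy min < max.
#' @param to numeric length-2, target range (default `c(-1, 1)`).
#' @return An object of class `affine_scaler` with fields `from`, `to`,
#'   `slope`, `intercept`.
#' @keywords internal
new_scaler <- function(from, to = c(-1, 1)) {
  if (!is.numeric(from) || length(from) != 2 || !all(is.finite(from))) {
    abort("`from` must be two finite numbers.", class = "phasereq_error")
  }
  if (from[2] <= from[1]) {
    # degenerate axis (e.g. constant response): widen symmetrically so the
    # map stays invertible; fitted amplitude then shrinks toward zero.
    mid <- from[1]
    from <- c(mid - 1, mid + 1)
  }
  slope <- (to[2] - to[1]) / (from[2] - from[1])
  structure(
    list(from = from, to = to, slope = slope,
         intercept = to[1] - slope * from[1]),
    class = "affine_scaler"
  )
}

scaler_apply <- function(s, x) s$slope * x + s$intercept
scaler_invert <- function(s, z) (z - s$intercept) / s$slope

# Derive reproducible 32-bit sub-seeds from a master seed without
# disturbing the caller's RNG state.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Run `expr` under a fixed seed, restoring RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Quartiles by linear interpolation between order statistics ("type 7"),
# the convention fixed for every quantile in this package.
quartiles <- function(x) {
  unname(quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE))
}
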