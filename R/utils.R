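#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention of most
#' numerical environments' `round`, and the one under which all printed
#' 1-decimal percentage summaries in this package are reproducible exactly).
#' Base R's [round()] rounds ties to even (6.25 -> 6.2), which is unsuitable
#' for reproducing fixed-decimal summary tables.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 1).
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(6.25)   # 6.3
#' round_half_up(9.375)  # 9.4
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  # nudge by a relative epsilon so that values intended as exact ties are not
  # pushed below .5 by binary representation error
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' Derive a reproducible sub-seed from a master seed and a key
#'
#' Expands one user-facing seed into independent substreams for units,
#' connections and surrogate replicates, so that e.g. adding a replicate does
#' not perturb the randomness of the others. Stable across platforms
#' (integer arithmetic mod 2^31 - 1).
#'
#' @param seed integer master seed.
#' @param key character or integer identifying the substream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed %% m)
  codes <- utf8ToInt(paste0(as.character(key), collapse = ""))
  for (c in codes) h <- (h * 31 + c) %% m
  as.integer(h %% (m - 1) + 1)
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
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
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

REGIONS <- c("sDH", "dDH", "IG", "VH")

WITHIN_CATEGORIES <- c("sDH-sDH", "dDH-dDH", "IG-IG", "VH-VH")
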