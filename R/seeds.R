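#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package (connectivity, initial conditions,
#' background spike trains, stimulus realizations, analysis subsampling) is
#' driven by integer seeds derived deterministically from a single master
#' seed through this function, so that an entire experiment is reproducible
#' from one number and independent streams never collide.
#'
#' @param master integer master seed.
#' @param role character role label (e.g. "connectivity", "trial-bg").
#' @param index non-negative integer stream index within the role.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' deriveSeed(1, "trial-bg", 7)
deriveSeed <- function(master, role, index = 0) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(role))
  m <- 2147483647 # 2^31 - 1, prime
  h <- sum(utf8ToInt(role) * (seq_along(utf8ToInt(role)) * 131)) %% m
  x <- (abs(master) %% m)
  x <- (x * 48271) %% m
  x <- (x + h * 69621) %% m
  x <- (x * 16807 + index * 1013904223) %% m
  as.integer(x %% (m - 1) + 1)
}
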