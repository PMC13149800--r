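# Internal helpers shared across modules.

# Golden angle in degrees, as used for azimuthal increments of the
# spiral-phyllotaxis pattern.
GOLDEN_ANGLE_DEG <- 137.50776405003785

# mmHg -> Pa conversion used throughout the stiffness formulas.
MMHG_TO_PA <- 133.322

.assertScalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

.assertCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != floor(x))
    stop(sprintf("'%s' must be a positive integer", name), call. = FALSE)
  as.integer(x)
}

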