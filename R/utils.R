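# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed (restoring the caller's RNG state),
# or with the current stream when seed is NULL. All exported stochastic
# functions route their randomness through this.
withSeed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Mirror-pad a matrix by `r` pixels on every side (edge pixel duplicated),
# the border rule used by the image filters.
reflectPad <- function(mat, r) {
  nr <- nrow(mat); nc <- ncol(mat)
  if (r >= nr || r >= nc)
    stop("padding radius must be smaller than the image")
  ri <- c(r:1, 1:nr, nr:(nr - r + 1L))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1L))
  mat[ri, ci, drop = FALSE]
}

# Correlate an image with a small odd-sized kernel under reflective borders.
# Shift-and-add keeps this exact (no FFT round-off beyond double precision).
correlate2d <- function(img, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  stopifnot(nrow(kernel) == ncol(kernel), nrow(kernel) %% 2L == 1L)
  p <- reflectPad(img, kr)
  out <- matrix(0, nrow(img), ncol(img))
  for (dy in -kr:kr) for (dx in -kr:kr) {
    w <- kernel[dy + kr + 1L, dx + kr + 1L]
    if (w != 0)
      out <- out + w * p[(1L + kr + dy):(nrow(img) + kr + dy),
                         (1L + kr + dx):(ncol(img) + kr + dx), drop = FALSE]
  }
  out
}

checkScalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= lower) || (!strict && x < lower))
    stop(sprintf("'%s' must be a single finite number %s %g", name,
                 if (strict) ">" else ">=", lower))
  invisible(x)
}

checkConditionIndex <- function(protocol, conditionIndex) {
  if (length(conditionIndex) != 1L || is.na(conditionIndex) ||
      conditionIndex < 1L || conditionIndex > length(protocol@tauD))
    stop(sprintf("unknown condition index %s (protocol has %d conditions)",
                 paste(conditionIndex, collapse = ","),
                 length(protocol@tauD)))
  as.integer(conditionIndex)
}

# Columns required of the flat tables exchanged between stages.
fociSchema   <- c("condition_id", "frame", "x_px", "y_px",
                  "peak_filtered", "background_sd")
eventSchema  <- c("condition_id", "start_frame", "end_frame", "n_frames",
                  "x_px", "y_px", "dwell_s", "censored")
crtdSchema   <- c("condition_id", "tau_int_s", "tau_d_s", "t_s", "count")
dwellSchema  <- c("condition_id", "n_frames", "dwell_s", "censored")

checkSchema <- function(df, schema, what) {
  missing <- setdiff(schema, names(df))
  if (length(missing))
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")))
  invisible(df)
}
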