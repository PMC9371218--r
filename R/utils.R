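# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-item sub-seed; stays below 2^31 - 1 for any inputs.
derive_seed <- function(seed, index, salt = 0) {
  s <- (abs(as.double(seed)) %% 100003) * 20011 +
    as.double(index) * 101 + as.double(salt) * 7919
  as.integer(s %% 2147483629)
}

# A grayscale slice is a plain numeric/integer matrix with values in [0, 255].
check_gray_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L) {
    stop(sprintf("`%s` must be a non-empty numeric matrix", arg), call. = FALSE)
  }
  if (anyNA(image)) {
    stop(sprintf("`%s` contains missing values", arg), call. = FALSE)
  }
  rng <- range(image)
  if (rng[1] < 0 || rng[2] > 255) {
    stop(sprintf("`%s` intensities must lie in [0, 255]", arg), call. = FALSE)
  }
  invisible(image)
}

# Clip to [0, 255] and round to the stored 8-bit integer scale.
quantize_gray <- function(image) {
  image[image < 0] <- 0
  image[image > 255] <- 255
  storage.mode(image) <- "double"
  img <- round(image)
  storage.mode(img) <- "integer"
  img
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %s", name, min), call. = FALSE)
  }
  as.integer(x)
}
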