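# Internal helpers shared across modules.

# Deterministic derivation of sub-seeds from one top-level seed, so that a
# single --seed governs folds, model initialisation and the generator without
# the streams colliding. Splitmix-style integer hash, kept in [0, 2^31 - 1]
# because R seeds are 32-bit.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- (as.double(seed) * 2654435761 + stream * 40503 + 12345) %% 2147483647
  h <- (h * 48271) %% 2147483647
  as.integer(h)
}

# Population standard deviation (divide by n); sd of one value is 0.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Round half up to `digits` decimals (base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Percent formatted to one decimal, round-half-up (matches clinical reporting).
format_pct <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f%%"), round_half_up(100 * x, digits))
}

is_rgb_image <- function(img) {
  is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3
}

assert_rgb_image <- function(img) {
  if (!is_rgb_image(img)) {
    abort("expected an H x W x 3 RGB array with intensities in [0, 255]")
  }
  invisible(img)
}

assert_labelmap <- function(lm) {
  if (!is.matrix(lm) || any(lm < 0) || any(lm != round(lm))) {
    abort("expected an H x W matrix of non-negative integer labels (0 = background)")
  }
  invisible(lm)
}

# Tabulate instance areas of a label map; named integer vector (names = labels).
label_areas <- function(lm) {
  labs <- lm[lm > 0]
  if (length(labs) == 0) return(setNames(integer(0), character(0)))
  tab <- table(labs)
  setNames(as.integer(tab), names(tab))
}
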