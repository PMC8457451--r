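# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures are stored.

# Filled disk mask of radius r (pixel centers), inside a (2r+5)^2 frame.
disk_mask <- function(r) {
  n <- 2 * r + 5
  ctr <- (n + 1) / 2
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  matrix((g$row - ctr)^2 + (g$col - ctr)^2 <= r^2, n, n)
}

# Filled axis-aligned ellipse mask with semi-axes (a, b) = (rows, cols).
ellipse_mask <- function(a, b) {
  n <- 2 * max(a, b) + 5
  ctr <- (n + 1) / 2
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  matrix(((g$row - ctr) / a)^2 + ((g$col - ctr) / b)^2 <= 1, n, n)
}

# Label map with horizontal strip instances of the given pixel areas.
strip_labelmap <- function(areas, width = max(areas) + 2) {
  lm <- matrix(0L, length(areas) * 2, width)
  for (i in seq_along(areas)) {
    lm[i * 2 - 1, seq_len(areas[i])] <- i
  }
  lm
}

# Flat-colored RGB image of the given dimensions.
flat_image <- function(h, w, rgb = c(200, 180, 190)) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# Paint filled disks (list of c(row, col, radius)) onto an image + label map.
paint_disks <- function(h, w, disks, fg = c(90, 60, 130),
                        bg = c(235, 200, 215)) {
  img <- flat_image(h, w, bg)
  lm <- matrix(0L, h, w)
  g <- expand.grid(row = seq_len(h), col = seq_len(w))
  for (i in seq_along(disks)) {
    d <- disks[[i]]
    inside <- (g$row - d[1])^2 + (g$col - d[2])^2 <= d[3]^2
    lm[cbind(g$row[inside], g$col[inside])] <- i
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[cbind(g$row[inside], g$col[inside])] <- fg[ch]
      img[, , ch] <- pl
    }
  }
  list(img = img, lm = lm)
}

# Patient feature table drawn from two Gaussians in 72-D with a mean shift
# `delta` on every feature; n patients per class.
gaussian_patients <- function(n_per_class, delta, seed = 1) {
  set.seed(seed)
  feats <- patient_feature_names()
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * length(feats)), n, length(feats))
  X[seq_len(n_per_class), ] <- X[seq_len(n_per_class), ] + delta
  colnames(X) <- feats
  dplyr::bind_cols(
    tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      class_label = rep(c("PTC", "nonPTC"), each = n_per_class)
    ),
    tibble::as_tibble(X)
  )
}

# Small cached synthetic study shared by expensive tests.
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(generator_config(
        n_patients_per_class = 2, images_per_patient = 2, seed = 11
      ))
    }
    cache
  }
})
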