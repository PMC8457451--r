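test_that("grayscale conversion is the 709 luminance with unit weight sum", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(as.vector(to_grayscale(px(255, 255, 255))), 255)
  expect_equal(as.vector(to_grayscale(px(0, 0, 0))), 0)
  expect_equal(as.vector(to_grayscale(px(100, 100, 100))), 100)
})

test_that("ring zones partition the mask into equal thirds ordered by depth", {
  # 3x3 square: zones {3,3,3}; the central (deepest) pixel is center zone
  z <- ring_zones(matrix(TRUE, 3, 3))
  expect_equal(unname(table(z[z > 0])), c(3, 3, 3), ignore_attr = TRUE)
  expect_equal(z[2, 2], 3L)

  # zone sizes always differ pairwise by <= 1
  set.seed(3)
  for (r in c(4, 7, 10)) {
    m <- disk_mask(r)
    z <- ring_zones(m)
    sizes <- as.integer(table(factor(z[z > 0], levels = 1:3)))
    expect_lte(max(sizes) - min(sizes), 1)
    expect_equal(sum(sizes), sum(m))
  }

  # depth ordering on a disk: center deeper than middle deeper than border
  m <- disk_mask(10)
  z <- ring_zones(m)
  d <- nucleomorph:::padded_distmap(m * 1)
  expect_gt(mean(d[z == 3]), mean(d[z == 2]))
  expect_gt(mean(d[z == 2]), mean(d[z == 1]))

  expect_null(ring_zones(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)))
})

test_that("color features: constants, counts, and hand-computed entropy", {
  # constant-intensity nucleus: stds 0, ratios 1, entropy 0, contrast 0
  m <- disk_mask(5)
  crop <- array(80, dim = c(dim(m), 3))
  cf <- color_features(crop, m)
  expect_length(cf, 23)
  expect_named(cf, nucleus_feature_names("color"))
  expect_equal(unname(cf[c("std_r", "std_g", "std_b", "std_gray")]), rep(0, 4))
  expect_equal(unname(cf[grep("^ratio_", names(cf))]), rep(1, 8))
  expect_equal(unname(cf["shannon_entropy"]), 0)
  expect_equal(unname(cf["glcm_contrast"]), 0)
  expect_equal(unname(cf["glcm_correlation"]), 0)  # single-valued crop

  # 2x2 gray crop {0,0,255,255}: entropy 1 bit, mean gray 127.5
  crop2 <- array(c(0, 0, 255, 255), dim = c(2, 2, 1))[, , c(1, 1, 1), drop = FALSE]
  cf2 <- color_features(crop2, matrix(TRUE, 2, 2))
  expect_equal(unname(cf2["shannon_entropy"]), 1)
  expect_equal(unname(cf2["mean_gray"]), 127.5)
})

test_that("GLCM properties match the co-occurrence oracle", {
  # frozen from an independent reference implementation on this exact crop
  img <- matrix(((0:15 * 13) %% 7) * 30, 4, 4, byrow = TRUE)
  p <- nucleomorph:::glcm_props(img, matrix(TRUE, 4, 4))
  expect_equal(unname(p),
               c(9900, 90, 0.0003264884926375159, 0.27983213053127454,
                 -0.3062279900873875, 0.07831790123456789),
               tolerance = 1e-10)
})

test_that("shape features: disk, ellipse, and frozen perimeter oracle", {
  sf <- shape_features(disk_mask(10))
  expect_length(sf, 4)
  expect_named(sf, c("area", "perimeter", "eccentricity", "solidity"))
  expect_lt(sf[["eccentricity"]], 0.1)
  expect_gt(sf[["solidity"]], 0.95)
  expect_equal(sf[["area"]], sum(disk_mask(10)))

  # ellipse with semi-axes a = 2b: eccentricity sqrt(1 - 1/4) ~ 0.866
  sf2 <- shape_features(ellipse_mask(40, 20))
  expect_equal(sf2[["eccentricity"]], sqrt(3) / 2, tolerance = 0.02)

  # contour-weighted perimeter frozen against an independent implementation
  g <- expand.grid(r = -12:12, c = -12:12)
  disk25 <- matrix(g$r^2 + g$c^2 <= 100, 25, 25)
  plus <- matrix(FALSE, 7, 7); plus[4, ] <- TRUE; plus[, 4] <- TRUE
  Lsh <- matrix(FALSE, 6, 6); Lsh[, 1:2] <- TRUE; Lsh[5:6, ] <- TRUE
  expect_equal(nucleomorph:::perimeter_estimate(matrix(TRUE, 5, 5)), 16)
  expect_equal(nucleomorph:::perimeter_estimate(matrix(TRUE, 3, 7)), 16)
  expect_equal(nucleomorph:::perimeter_estimate(disk25), 65.94112549695429,
               tolerance = 1e-12)
  expect_equal(nucleomorph:::perimeter_estimate(plus), 8.82842712474619,
               tolerance = 1e-12)
  expect_equal(nucleomorph:::perimeter_estimate(Lsh), 17)

  # degenerate single pixel
  one <- matrix(c(TRUE), 1, 1)
  sf3 <- shape_features(one)
  expect_equal(sf3[["eccentricity"]], 0)
  expect_equal(sf3[["solidity"]], 1)
  expect_true(is.finite(sf3[["perimeter"]]))
})

test_that("mean radius follows the equivalent-disk formula", {
  expect_equal(mean_radius(pi), 1)
  expect_equal(mean_radius(c(pi, 4 * pi)), 1.5)
  set.seed(12)
  areas <- runif(100, 10, 400)
  oracle <- 0
  for (a in areas) oracle <- oracle + sqrt(a / pi)
  oracle <- oracle / length(areas)
  expect_equal(mean_radius(areas), oracle, tolerance = 1e-12)
  expect_true(is.na(mean_radius(numeric(0))))
})

test_that("crowding counts match a brute-force scan and are monotone", {
  # single nucleus: all counts zero
  cr1 <- crowding(matrix(c(5, 5), 1, 2), r_mean = 2)
  expect_true(all(cr1 == 0))

  # two centroids at distance 10 with r_mean 1: x9 misses, x15 catches
  cr2 <- crowding(rbind(c(0, 0), c(0, 10)), r_mean = 1)
  expect_equal(cr2$crowd_x9, c(0L, 0L))
  expect_equal(cr2$crowd_x15, c(1L, 1L))

  # O(n^2) oracle on random centroids + monotonicity in x
  set.seed(21)
  cen <- cbind(runif(60, 0, 200), runif(60, 0, 200))
  r_mean <- 4.2
  cr <- crowding(cen, r_mean)
  mult <- c(3, 5, 7, 9, 15, 20, 25, 30)
  for (i in seq_len(nrow(cen))) {
    for (k in seq_along(mult)) {
      cnt <- 0L
      for (j in seq_len(nrow(cen))) {
        if (j != i && sqrt(sum((cen[i, ] - cen[j, ])^2)) <= mult[k] * r_mean) {
          cnt <- cnt + 1L
        }
      }
      expect_identical(cr[[paste0("crowd_x", mult[k])]][i], cnt)
    }
    expect_true(all(diff(as.numeric(cr[i, ])) >= 0))
  }
})

test_that("nearest-neighbour distances match the exhaustive scan", {
  expect_equal(nn_distance(rbind(c(0, 0), c(3, 4))), c(5, 5))
  expect_equal(nn_distance(cbind(0, c(0, 1, 10))), c(1, 1, 9))
  expect_true(is.na(nn_distance(matrix(c(1, 1), 1, 2))))
  set.seed(8)
  cen <- cbind(runif(200, 0, 100), runif(200, 0, 100))
  nd <- nn_distance(cen)
  for (i in sample.int(200, 20)) {
    best <- Inf
    for (j in seq_len(200)) {
      if (j != i) best <- min(best, sqrt(sum((cen[i, ] - cen[j, ])^2)))
    }
    expect_equal(nd[i], best, tolerance = 1e-12)
  }
})

test_that("extract_features emits 36 canonical columns deterministically", {
  ds <- tiny_dataset()
  seg <- extract_nuclei(ds$images[[1]], filter_by_size(ds$labelmaps[[1]]))
  ft <- extract_features(seg)
  expect_equal(setdiff(names(ft), "nucleus_id"), nucleus_feature_names())
  expect_length(nucleus_feature_names("color"), 23)
  expect_length(nucleus_feature_names("shape"), 4)
  expect_length(nucleus_feature_names("spatial"), 9)
  expect_length(nucleus_feature_names(), 36)
  expect_identical(ft, extract_features(seg))  # bit-identical re-run

  # invariants on value ranges
  expect_true(all(ft$area > 0))
  expect_true(all(ft$eccentricity >= 0 & ft$eccentricity < 1))
  expect_true(all(ft$solidity > 0 & ft$solidity <= 1))
  expect_true(all(ft$nn_distance >= 0))

  # empty segmentation -> empty 36-column table
  blank <- extract_nuclei(flat_image(16, 16), matrix(0L, 16, 16))
  expect_equal(nrow(extract_features(blank)), 0)
  expect_equal(setdiff(names(extract_features(blank)), "nucleus_id"),
               nucleus_feature_names())
})

test_that("features are invariant to translation and 90-degree rotation", {
  disks <- list(c(15, 14, 6), c(30, 30, 7), c(14, 38, 5))
  fix <- paint_disks(52, 52, disks)
  set.seed(9)
  noise <- array(round(rnorm(52 * 52 * 3, 0, 5)), dim = c(52, 52, 3))
  img <- pmax(pmin(fix$img + noise, 255), 0)
  ft <- extract_features(extract_nuclei(img, fix$lm))

  # translation by (3, 5)
  h <- 60; w <- 60
  img_t <- flat_image(h, w); lm_t <- matrix(0L, h, w)
  img_t[3 + 1:52, 5 + 1:52, ] <- img
  lm_t[3 + 1:52, 5 + 1:52] <- fix$lm
  ft_t <- extract_features(extract_nuclei(img_t, lm_t))
  expect_equal(as.data.frame(ft_t[nucleus_feature_names()]),
               as.data.frame(ft[nucleus_feature_names()]), tolerance = 1e-9)

  # 90-degree rotation: area, solidity, entropy, crowding, nn unchanged;
  # GLCM unchanged because offsets average the 4 principal directions
  rot <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  img_r <- array(0, dim = c(52, 52, 3))
  for (ch in 1:3) img_r[, , ch] <- rot(img[, , ch])
  lm_r <- rot(fix$lm)
  ft_r <- extract_features(extract_nuclei(img_r, lm_r))
  inv <- c("area", "solidity", "shannon_entropy",
           paste0("crowd_x", c(3, 5, 7, 9, 15, 20, 25, 30)), "nn_distance",
           "glcm_contrast", "glcm_dissimilarity", "glcm_homogeneity",
           "glcm_energy", "glcm_correlation", "glcm_asm")
  expect_equal(as.data.frame(ft_r[order(ft_r$area), inv]),
               as.data.frame(ft[order(ft$area), inv]), tolerance = 1e-9)
})

test_that("zone color ratios are invariant to intensity scaling", {
  m <- disk_mask(8)
  set.seed(14)
  base <- array(round(runif(prod(dim(m)) * 3, 20, 80)), dim = c(dim(m), 3))
  cf1 <- color_features(base, m)
  cf3 <- color_features(base * 3, m)  # still within 8-bit range, exact
  ratios <- grep("^ratio_", nucleus_feature_names("color"), value = TRUE)
  expect_equal(unname(cf3[ratios]), unname(cf1[ratios]), tolerance = 1e-12)
})

test_that("synthetic classes separate on area and solidity", {
  cfg <- generator_config(n_patients_per_class = 1, images_per_patient = 4,
                          nuclei_per_image = c(14, 18), seed = 31)
  ds <- generate_dataset(cfg)
  nuc <- extract_dataset_features(ds)
  lab <- ds$manifest$class_label[match(nuc$patient_id, ds$manifest$patient_id)]
  expect_gte(min(table(lab)), 50)
  a <- stats::t.test(nuc$area[lab == "PTC"], nuc$area[lab == "nonPTC"])
  s <- stats::t.test(nuc$solidity[lab == "PTC"], nuc$solidity[lab == "nonPTC"])
  expect_lt(a$p.value, 0.01)
  expect_lt(s$p.value, 0.01)
  expect_gt(mean(nuc$area[lab == "PTC"]), mean(nuc$area[lab == "nonPTC"]))
  expect_lt(mean(nuc$solidity[lab == "PTC"]), mean(nuc$solidity[lab == "nonPTC"]))
})
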