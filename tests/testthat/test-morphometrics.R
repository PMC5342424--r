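# half-integer center keeps lattice points off the exact circle boundary
disk_mask <- function(r, cls = 1L, nr = 2 * r + 21, core = 0) {
  m <- matrix(0L, nr, nr)
  c0 <- (nr + 1) / 2 + 0.5
  m[rast_disk(nr, nr, c0, c0, r)] <- cls
  if (core > 0) m[rast_disk(nr, nr, c0, c0, core)] <- 2L
  m
}

rot90 <- function(m) t(m)[ncol(m):1, ]

test_that("slice features match analytic values for disks and squares", {
  m <- disk_mask(10)
  f <- slice_features(m)
  expect_equal(unname(f["enh_area"]), 314.16, tolerance = 0.02)
  expect_equal(unname(f["enh_region_count"]), 1)
  expect_equal(unname(f["nec_area"]), 0)
  expect_equal(unname(f["enh_area_prop"]), 1)
  expect_equal(unname(f["enh_equiv_radius"]), sqrt(sum(m == 1) / pi))

  # two disjoint 5x5 squares
  m2 <- matrix(0L, 30, 30)
  m2[3:7, 3:7] <- 1L
  m2[20:24, 20:24] <- 1L
  f2 <- slice_features(m2)
  expect_equal(unname(f2["enh_region_count"]), 2)
  expect_equal(unname(f2["enh_area"]), 50)
  expect_equal(unname(f2["enh_area_prop"]), 1)

  # empty class gives zeros, not errors
  expect_equal(unname(f2["nec_region_count"]), 0)
  expect_equal(unname(f2["nec_thickness"]), 0)
})

test_that("thickness equals twice the mean brute-force distance to the complement", {
  ring <- disk_mask(10, core = 6)
  f <- slice_features(ring)
  oracle <- 2 * mean(bf_distance_to_complement(ring == 1L))
  expect_equal(unname(f["enh_thickness"]), oracle, tolerance = 1e-12)
  # annulus of width 4: the mean interior depth is well below the full
  # width; the oracle value for this rasterization is ~2.9 px
  expect_equal(oracle, 2.9, tolerance = 0.05)
  solid <- disk_mask(10)
  fs <- slice_features(solid)
  expect_equal(unname(fs["enh_thickness"]),
               2 * mean(bf_distance_to_complement(solid == 1L)),
               tolerance = 1e-12)
})

test_that("primary region properties match circle, rectangle and ellipse geometry", {
  pr <- primary_region_props(disk_mask(20), 1L)
  expect_lt(pr$eccentricity, 0.05)
  expect_equal(pr$compactness, 1, tolerance = 0.1)
  expect_equal(pr$sphericity, 1, tolerance = 0.05)
  # hull over pixel corners adds a half-pixel rim around a curved region
  expect_gt(pr$solidity, 0.93)
  expect_lte(pr$solidity, 1)

  m <- matrix(0L, 40, 40)
  m[11:20, 11:30] <- 1L  # 10 rows x 20 cols
  pr <- primary_region_props(m, 1L)
  expect_equal(pr$bbox_area, 200)
  expect_equal(pr$solidity, 1, tolerance = 0.02)
  expect_lt(abs(pr$orientation), 0.05)
  expect_true(pr$minor_axis_length <= pr$major_axis_length)

  stk <- generate_mask_stack(list(list(shape = "ellipse",
                                       semi_axes = c(20, 10))),
                             dim = c(64, 64))
  pr <- primary_region_props(stk$slices[[1]], 1L)
  expect_equal(pr$major_axis_length / pr$minor_axis_length, 2,
               tolerance = 0.05)
  expect_equal(pr$eccentricity, sqrt(1 - 0.25), tolerance = 0.05)
  # exhaustive pixel-moment oracle for the axis lengths
  pix <- which(stk$slices[[1]] == 1L, arr.ind = TRUE)
  cv <- stats::cov(pix) * (nrow(pix) - 1) / nrow(pix) + diag(2) / 12
  ev <- sort(eigen(cv, symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(pr$major_axis_length, 4 * sqrt(ev[1]), tolerance = 1e-8)
  expect_equal(pr$minor_axis_length, 4 * sqrt(ev[2]), tolerance = 1e-8)

  expect_error(primary_region_props(m, 2L), "no pixels")
})

test_that("largest-region selection uses 8-connectivity with deterministic ties", {
  m <- matrix(0L, 10, 10)
  m[2, 2] <- 1L; m[3, 3] <- 1L; m[4, 4] <- 1L  # one diagonal chain
  m[8, 8] <- 1L
  f <- slice_features(m)
  expect_equal(unname(f["enh_region_count"]), 2)
  pr <- primary_region_props(m, 1L)
  expect_equal(pr$area, 3)
  # labeling count agrees with an independent igraph components oracle
  set.seed(4)
  for (i in 1:5) {
    bw <- matrix(runif(400) < 0.35, 20, 20)
    expect_equal(max(radiopsp:::label_components(bw)), igraph_label_count(bw))
  }
})

test_that("area, shape and count survive 90-degree rotation; scaling behaves geometrically", {
  stk <- generate_mask_stack(list(list(shape = "ellipse",
                                       semi_axes = c(14, 7),
                                       angle = 0.4)),
                             dim = c(64, 64))
  m <- stk$slices[[1]]
  mr <- rot90(m)
  f <- slice_features(m); fr <- slice_features(mr)
  for (nm in c("enh_area", "enh_region_count"))
    expect_equal(unname(f[nm]), unname(fr[nm]))
  p <- primary_region_props(m, 1L); pr <- primary_region_props(mr, 1L)
  expect_equal(p$solidity, pr$solidity, tolerance = 1e-6)
  expect_equal(p$eccentricity, pr$eccentricity, tolerance = 1e-6)
  expect_equal(p$perimeter, pr$perimeter, tolerance = 0.05 * p$perimeter)
  expect_equal(p$compactness, pr$compactness, tolerance = 0.05)

  small <- primary_region_props(disk_mask(8), 1L)
  big <- primary_region_props(disk_mask(16), 1L)
  expect_equal(big$area / small$area, 4, tolerance = 0.05)
  expect_equal(big$perimeter / small$perimeter, 2, tolerance = 0.05)
  expect_equal(big$eccentricity, small$eccentricity, tolerance = 0.05)
  expect_equal(big$sphericity, small$sphericity, tolerance = 0.05)
})

test_that("enhanced and necrotic area proportions always sum to one", {
  set.seed(9)
  for (i in 1:10) {
    m <- matrix(sample(0:2, 400, replace = TRUE, prob = c(0.6, 0.25, 0.15)),
                20, 20)
    f <- slice_features(m)
    total <- f["enh_area"] + f["nec_area"]
    if (total > 0)
      expect_equal(unname(f["enh_area_prop"] + f["nec_area_prop"]), 1)
  }
})

test_that("case aggregation matches a direct per-feature recomputation", {
  geom <- list(
    list(shape = "disk", radius = 6, center = c(20, 20)),
    list(shape = "disk", radius = 9, center = c(24, 24), core_radius = 4),
    list(shape = "disk", radius = 12, center = c(28, 28), core_radius = 6),
    list(shape = "ellipse", semi_axes = c(10, 5), center = c(30, 30)),
    list(shape = "multiblob", blobs = list(
      list(center = c(15, 15), radius = 4),
      list(center = c(40, 40), radius = 6))))
  stk <- generate_mask_stack(geom, dim = c(56, 56))
  per_slice <- t(sapply(stk$slices, slice_features))
  case <- aggregate_case(per_slice)
  # direct re-aggregation, feature by feature
  areas <- per_slice[, "enh_area"] + per_slice[, "nec_area"]
  L <- which.max(areas)
  for (nm in colnames(per_slice)) {
    expect_equal(unname(case[paste0("largest_", nm)]),
                 unname(per_slice[L, nm]))
    expect_equal(unname(case[paste0("mean_", nm)]),
                 mean(per_slice[, nm]))
    expect_equal(unname(case[paste0("max_", nm)]), max(per_slice[, nm]))
    expect_equal(unname(case[paste0("min_", nm)]), min(per_slice[, nm]))
    expect_equal(unname(case[paste0("sum_", nm)]), sum(per_slice[, nm]))
  }
  # single-slice case: all aggregates collapse onto the slice values
  one <- aggregate_case(per_slice[2, , drop = FALSE])
  for (nm in colnames(per_slice)) {
    expect_equal(unname(one[paste0("mean_", nm)]),
                 unname(per_slice[2, nm]))
    expect_equal(unname(one[paste0("max_", nm)]), unname(per_slice[2, nm]))
  }
  expect_identical(unname(case), unname(mask_stack_features(stk)))
})

test_that("the feature manifest enumerates the case vector exactly", {
  man <- feature_manifest()
  stk <- generate_mask_stack(list(list(shape = "disk", radius = 8)),
                             dim = c(32, 32))
  v <- mask_stack_features(stk)
  expect_identical(names(v), man$name)
  expect_false(any(duplicated(man$name)))
  expect_false(any(is.na(man$definition)))
})
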