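#' Morphological features from labeled tumor masks
#'
#' The morphometrics module quantifies 2D tumor masks labeled 0 (background),
#' 1 (contrast-enhanced rim) and 2 (necrotic core).  Per slice it measures,
#' for each tissue class, area, rim thickness, length, equivalent radius,
#' number of connected regions and area proportion, plus shape descriptors of
#' the largest ("primary") region of each class.  Per case the features of
#' the largest-tumor-area slice and the mean/max/min/sum over all slices are
#' concatenated into a fixed, documented feature vector (see
#' [feature_manifest()]).
#'
#' Conventions: 8-connectivity throughout; pixel centers on the integer
#' grid; perimeter is the chain-code length of the traced outer boundary
#' (diagonal steps weigh `sqrt(2)`); thickness is twice the mean Euclidean
#' distance from class pixels to the class complement; compactness is
#' normalized so a circle gives 1 (larger otherwise) and sphericity is its
#' reciprocal square root (at most 1 for solid shapes).
#'
#' @name morphometrics
NULL

# 8-connected component labeling (column-major label discovery order, so the
# first pixel of each component is its top-left-most in column-major order)
label_components <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  droff <- c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L)
  npx <- nr * nc
  todo <- which(bw)
  cur <- 0L
  for (p in todo) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    lab[p] <- cur
    frontier <- p
    while (length(frontier)) {
      rows <- ((frontier - 1L) %% nr) + 1L
      cand <- rep(frontier, each = 8L) + rep(off, times = length(frontier))
      crow <- rep(rows, each = 8L) + rep(droff, times = length(frontier))
      ok <- cand >= 1L & cand <= npx & crow >= 1L & crow <= nr
      cand <- unique(cand[ok])
      cand <- cand[bw[cand] & lab[cand] == 0L]
      lab[cand] <- cur
      frontier <- cand
    }
  }
  lab
}

# second-order central moments of a pixel set, pixels treated as unit
# squares (adds 1/12 to the diagonal); x = column, y = row
region_moments <- function(pix) {
  y <- pix[, 1]; x <- pix[, 2]
  mxx <- mean((x - mean(x))^2) + 1 / 12
  myy <- mean((y - mean(y))^2) + 1 / 12
  mxy <- mean((x - mean(x)) * (y - mean(y)))
  half <- sqrt((mxx - myy)^2 / 4 + mxy^2)
  l1 <- (mxx + myy) / 2 + half
  l2 <- (mxx + myy) / 2 - half
  list(major = 4 * sqrt(l1), minor = 4 * sqrt(max(l2, 0)),
       orientation = 0.5 * atan2(2 * mxy, mxx - myy),
       eccentricity = sqrt(max(0, 1 - l2 / l1)))
}

# chain-code perimeter of the outer boundary by Moore-neighbor tracing;
# diagonal steps weigh sqrt(2).  Isolated pixels get the unit-square
# perimeter 4.
trace_perimeter <- function(bw) {
  npix <- sum(bw)
  if (npix == 0L) return(0)
  if (npix == 1L) return(4)
  idx <- which(bw, arr.ind = TRUE)
  start <- idx[order(idx[, 1], idx[, 2])[1], ]
  dirs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  inside <- function(p) p[1] >= 1 && p[1] <= nrow(bw) &&
    p[2] >= 1 && p[2] <= ncol(bw) && bw[p[1], p[2]]
  cur <- start
  backtrack <- 1L
  per <- 0
  steps <- 0L
  limit <- 8L * npix + 8L
  repeat {
    found <- FALSE
    for (k in 0:7) {
      dd <- ((backtrack - 1L + k) %% 8L) + 1L
      p <- cur + dirs[dd, ]
      if (inside(p)) {
        per <- per + if (dd %% 2L == 0L) sqrt(2) else 1
        backtrack <- ((dd - 1L + 5L) %% 8L) + 1L
        cur <- p
        found <- TRUE
        break
      }
    }
    if (!found) return(4)  # no 8-neighbor: isolated pixel handled above
    steps <- steps + 1L
    if (all(cur == start) && steps > 1L) break
    if (steps > limit) break
  }
  per
}

# convex hull area over pixel corners (shoelace); >= pixel count for any
# pixel set, so solidity = area / hull_area <= 1
hull_area <- function(pix) {
  y <- pix[, 1]; x <- pix[, 2]
  cx <- c(x - 0.5, x - 0.5, x + 0.5, x + 0.5)
  cy <- c(y - 0.5, y + 0.5, y - 0.5, y + 0.5)
  h <- chull(cx, cy)
  hx <- cx[h]; hy <- cy[h]
  j <- c(seq_along(h)[-1], 1L)
  abs(sum(hx * hy[j] - hx[j] * hy)) / 2
}

check_mask_labels <- function(mask) {
  bad <- setdiff(unique(as.vector(mask)), c(0L, 1L, 2L))
  if (length(bad))
    stop("mask labels must be in {0, 1, 2}; found: ",
         paste(bad, collapse = ", "))
  invisible(mask)
}

class_prefix <- c("1" = "enh", "2" = "nec")

#' Per-slice class features of a labeled tumor mask
#'
#' Computes, for the enhanced (label 1) and necrotic (label 2) classes of one
#' mask slice: total area in px^2 and mm^2, thickness (twice the mean
#' Euclidean distance of class pixels to the class complement), length
#' (major-axis length of the class pixel union), equivalent radius
#' `sqrt(area/pi)`, 8-connected region count, and the class's proportion of
#' the total tumor (enhanced + necrotic) area; plus the shape descriptors of
#' the class's primary (largest) region from [primary_region_props()].
#' An empty class yields zeros for all of its features.
#'
#' @param mask integer matrix with values in \{0, 1, 2\}.
#' @param pixel_size pixel edge length in mm (used for the mm^2 areas only;
#'   all other features are in pixel units).
#' @return A named numeric vector; names and definitions are enumerated by
#'   [feature_manifest()].
#' @export
slice_features <- function(mask, pixel_size = 1) {
  check_mask_labels(mask)
  total <- sum(mask == 1L) + sum(mask == 2L)
  out <- c()
  for (cls in c(1L, 2L)) {
    pre <- class_prefix[[as.character(cls)]]
    bw <- mask == cls
    area <- sum(bw)
    if (area == 0L) {
      vals <- c(area = 0, area_mm2 = 0, thickness = 0, length = 0,
                equiv_radius = 0, region_count = 0, area_prop = 0)
      props <- rep(0, length(prop_names))
      names(props) <- prop_names
    } else {
      pix <- which(bw, arr.ind = TRUE)
      dm <- EBImage::imageData(EBImage::distmap(matrix(as.numeric(bw),
                                                       nrow(bw))))
      thick <- 2 * mean(dm[bw])
      mom <- region_moments(pix)
      lab <- label_components(bw)
      vals <- c(area = area, area_mm2 = area * pixel_size^2,
                thickness = thick, length = mom$major,
                equiv_radius = sqrt(area / pi),
                region_count = max(lab),
                area_prop = if (total > 0) area / total else 0)
      props <- unlist(primary_region_props(mask, cls, pixel_size))
    }
    names(vals) <- paste(pre, names(vals), sep = "_")
    names(props) <- paste(pre, "primary", prop_names, sep = "_")
    out <- c(out, vals, props)
  }
  out
}

prop_names <- c("area", "perimeter", "bbox_area", "major_axis_length",
                "minor_axis_length", "orientation", "solidity",
                "eccentricity", "compactness", "sphericity")

#' Shape descriptors of the primary (largest) region of a class
#'
#' Selects the largest 8-connected component of the requested class (ties
#' broken by the component containing the top-left-most pixel) and measures
#' its area, chain-code perimeter, bounding-box area, major/minor axis
#' lengths and orientation of the moment-equivalent ellipse, solidity
#' (area / convex-hull area over pixel corners), eccentricity, compactness
#' `perimeter^2 / (4 pi area)` and sphericity `2 sqrt(pi area) / perimeter`.
#'
#' @param mask integer matrix with values in \{0, 1, 2\}.
#' @param class_label 1 (enhanced) or 2 (necrotic).
#' @param pixel_size pixel edge length in mm (metadata; outputs are in pixel
#'   units).
#' @return A named list of the ten descriptors.
#' @export
primary_region_props <- function(mask, class_label, pixel_size = 1) {
  check_mask_labels(mask)
  bw <- mask == class_label
  if (!any(bw))
    stop(sprintf("class %d has no pixels in this slice", class_label))
  lab <- label_components(bw)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: component containing the smallest (top-left-most) linear index
    first_idx <- vapply(best, function(b) min(which(lab == b)), integer(1))
    best <- best[which.min(first_idx)]
  }
  comp <- lab == best
  pix <- which(comp, arr.ind = TRUE)
  area <- nrow(pix)
  per <- trace_perimeter(comp)
  mom <- region_moments(pix)
  bbox <- (diff(range(pix[, 1])) + 1) * (diff(range(pix[, 2])) + 1)
  list(area = area, perimeter = per, bbox_area = bbox,
       major_axis_length = mom$major, minor_axis_length = mom$minor,
       orientation = mom$orientation,
       solidity = area / hull_area(pix),
       eccentricity = mom$eccentricity,
       compactness = if (per > 0) per^2 / (4 * pi * area) else 0,
       sphericity = if (per > 0) 2 * sqrt(pi * area) / per else 0)
}

#' Aggregate per-slice features into a case feature vector
#'
#' Concatenates (i) the feature vector of the slice with the largest total
#' tumor (enhanced + necrotic) area, ties resolved toward the lowest slice
#' index, and (ii) the per-feature mean, maximum, minimum and sum over all
#' slices.  Feature names are prefixed `largest_`, `mean_`, `max_`, `min_`
#' and `sum_`.
#'
#' @param per_slice a matrix of per-slice feature vectors (slices in rows, as
#'   returned by [slice_features()]) or a list of such vectors.
#' @return A named numeric vector of length `5 *` the slice feature count.
#' @export
aggregate_case <- function(per_slice) {
  if (is.list(per_slice)) per_slice <- do.call(rbind, per_slice)
  if (is.null(dim(per_slice))) per_slice <- matrix(per_slice, nrow = 1,
                                                   dimnames = list(NULL, names(per_slice)))
  stopifnot(nrow(per_slice) >= 1L)
  tumor_area <- per_slice[, "enh_area"] + per_slice[, "nec_area"]
  largest <- which.max(tumor_area)  # which.max takes the first maximum
  out <- c(per_slice[largest, ],
           apply(per_slice, 2, mean), apply(per_slice, 2, max),
           apply(per_slice, 2, min), apply(per_slice, 2, sum))
  names(out) <- c(paste0("largest_", colnames(per_slice)),
                  paste0("mean_", colnames(per_slice)),
                  paste0("max_", colnames(per_slice)),
                  paste0("min_", colnames(per_slice)),
                  paste0("sum_", colnames(per_slice)))
  out
}

#' Case feature vector of a mask stack
#'
#' Runs [slice_features()] on every slice of a mask stack and aggregates the
#' result with [aggregate_case()].
#'
#' @param stack a [generate_mask_stack()] / [read_mask_stack()] result.
#' @return A named numeric vector (see [feature_manifest()]).
#' @export
mask_stack_features <- function(stack) {
  stopifnot(inherits(stack, "mask_stack"))
  per_slice <- t(vapply(stack$slices, slice_features,
                        numeric(length(manifest_slice_names())),
                        pixel_size = stack$pixel_size))
  aggregate_case(per_slice)
}

manifest_slice_names <- function() {
  nm <- c()
  for (pre in c("enh", "nec")) {
    nm <- c(nm,
            paste(pre, c("area", "area_mm2", "thickness", "length",
                         "equiv_radius", "region_count", "area_prop"),
                  sep = "_"),
            paste(pre, "primary", prop_names, sep = "_"))
  }
  nm
}

#' Feature enumeration manifest
#'
#' Enumerates every feature produced by [mask_stack_features()], with a
#' plain-language definition for each.  The slice-level block is measured on
#' the class pixel union ("length" and "equivalent radius" refer to the
#' union, not the primary region) and the `*_primary_*` block on the largest
#' connected region of the class.
#'
#' @return A data frame with columns `name` and `definition`.
#' @export
feature_manifest <- function() {
  cls_def <- c(
    area = "class area in pixels",
    area_mm2 = "class area in mm^2 (area * pixel_size^2)",
    thickness = "2 x mean Euclidean distance of class pixels to the class complement",
    length = "major-axis length of the class pixel union (moment ellipse)",
    equiv_radius = "radius of the circle with the class area, sqrt(area/pi)",
    region_count = "number of 8-connected components of the class",
    area_prop = "class area / total tumor (enhanced + necrotic) area")
  prop_def <- c(
    area = "primary-region area in pixels",
    perimeter = "chain-code length of the primary region's outer boundary",
    bbox_area = "area of the axis-aligned bounding box of the primary region",
    major_axis_length = "major-axis length of the moment-equivalent ellipse",
    minor_axis_length = "minor-axis length of the moment-equivalent ellipse",
    orientation = "major-axis angle in radians from the column axis, in (-pi/2, pi/2]",
    solidity = "area / convex-hull area (hull over pixel corners)",
    eccentricity = "eccentricity of the moment-equivalent ellipse",
    compactness = "perimeter^2 / (4 pi area); 1 for a circle",
    sphericity = "2 sqrt(pi area) / perimeter; 1 for a circle")
  slice <- data.frame(name = manifest_slice_names(), definition = NA_character_)
  for (pre in c("enh", "nec")) {
    cname <- if (pre == "enh") "enhanced" else "necrotic"
    slice$definition[match(paste(pre, names(cls_def), sep = "_"),
                           slice$name)] <-
      paste0("[", cname, "] ", cls_def)
    slice$definition[match(paste(pre, "primary", names(prop_def), sep = "_"),
                           slice$name)] <-
      paste0("[", cname, " primary region] ", prop_def)
  }
  agg <- c(largest = "value on the slice with the largest total tumor area",
           mean = "mean over all slices", max = "maximum over all slices",
           min = "minimum over all slices", sum = "sum over all slices")
  out <- do.call(rbind, lapply(names(agg), function(a) {
    data.frame(name = paste0(a, "_", slice$name),
               definition = paste0(slice$definition, "; ", agg[[a]]))
  }))
  rownames(out) <- NULL
  out
}

#' Write per-case features and the manifest
#'
#' Writes a samples-by-features TSV of case feature vectors together with a
#' JSON sidecar holding the [feature_manifest()].
#'
#' @param features a named list of case feature vectors (one per case) or a
#'   matrix with cases in rows.
#' @param path output TSV path; the manifest is written next to it with
#'   suffix `.manifest.json`.
#' @return The TSV path, invisibly.
#' @export
write_case_features <- function(features, path) {
  if (is.list(features)) features <- do.call(rbind, features)
  df <- data.frame(sample_id = rownames(features), features,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(feature_manifest(),
                       sub("\\.tsv$", ".manifest.json", path)
                       , dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}
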