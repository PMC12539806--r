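#' Construct a label volume
#'
#' A label volume is an ordered stack of 2-D integer label images (0 =
#' background) with physical calibration, the container for segmented EM
#' data. The optional `region` restricts analysis to an inclusive slice
#' range, mirroring the standardization of the neuropil region across
#' datasets (cell bodies excluded, fixed posterior boundary).
#'
#' @param slices list of integer matrices, all the same shape.
#' @param pixel_size x-y pixel size in nm (> 0).
#' @param z_spacing slice spacing in nm (> 0).
#' @param region optional inclusive slice range `c(first, last)` (1-based).
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(slices, pixel_size, z_spacing, region = NULL) {
  stop_if(!is.list(slices) || length(slices) == 0, "slices must be a non-empty list")
  shp <- dim(slices[[1]])
  for (i in seq_along(slices)) {
    stop_if(!is.matrix(slices[[i]]), sprintf("slice %d is not a matrix", i))
    stop_if(!identical(dim(slices[[i]]), shp),
            sprintf("slice %d shape differs from slice 1", i))
    stop_if(any(slices[[i]] < 0), sprintf("slice %d has negative labels", i))
    storage.mode(slices[[i]]) <- "integer"
  }
  stop_if(pixel_size <= 0, "pixel_size must be > 0")
  stop_if(z_spacing <= 0, "z_spacing must be > 0")
  if (!is.null(region)) {
    stop_if(length(region) != 2 || region[1] > region[2] ||
              region[1] < 1 || region[2] > length(slices),
            "region must be an inclusive slice range within the stack")
    region <- as.integer(region)
  }
  structure(list(slices = slices, pixel_size = pixel_size,
                 z_spacing = z_spacing, region = region),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("label_volume: %d slices of %dx%d px, %.3g nm/px, %.3g nm z\n",
              length(x$slices), nrow(x$slices[[1]]), ncol(x$slices[[1]]),
              x$pixel_size, x$z_spacing))
  if (!is.null(x$region))
    cat(sprintf("  region: slices %d..%d\n", x$region[1], x$region[2]))
  invisible(x)
}

region_indices <- function(vol) {
  if (is.null(vol$region)) seq_along(vol$slices)
  else seq(vol$region[1], vol$region[2])
}

#' Distance threshold for adjacency
#'
#' Stores the threshold both in nm and in pixels; the pixel value is derived
#' by round-half-up of `distance_nm / pixel_size` (datasets mix units, e.g. a
#' 45 nm threshold is 10 px at 4.5 nm/px).
#'
#' @param distance_nm threshold distance in nm (> 0).
#' @param pixel_size pixel size in nm used for the conversion.
#' @return an object of class `threshold_spec` with `distance_nm` and
#'   `distance_px`.
#' @export
threshold_spec <- function(distance_nm, pixel_size) {
  stop_if(distance_nm <= 0, "distance_nm must be > 0")
  stop_if(pixel_size <= 0, "pixel_size must be > 0")
  structure(list(distance_nm = distance_nm,
                 distance_px = as.integer(round_half_up(distance_nm / pixel_size))),
            class = "threshold_spec")
}

#' Euclidean dilation of a binary region
#'
#' Sets every pixel whose Euclidean distance (between pixel centers) to the
#' input region is `<= distance_px`; input pixels are retained. This is the
#' outline "expansion" used to capture contact overlap: isotropic dilation by
#' the threshold distance.
#'
#' @param mask logical (or 0/1) matrix.
#' @param distance_px nonnegative expansion distance in pixels.
#' @return logical matrix of the expanded region.
#' @export
expand_region <- function(mask, distance_px) {
  stop_if(distance_px < 0, "distance_px must be >= 0")
  mask <- mask != 0
  if (!any(mask)) {
    ctm_warn("CTM_EMPTY_MASK", "expand_region called on an empty mask")
    return(mask)
  }
  if (distance_px == 0) return(mask)
  d <- EBImage::distmap(1 - mask, metric = "euclidean")
  matrix(as.numeric(d) <= distance_px, nrow(mask), ncol(mask))
}

#' Directed contact counts between two labels on one slice
#'
#' The directed count a->b is the number of pixels of label `b` covered when
#' the region of label `a` is expanded by the threshold distance (and
#' symmetrically for b->a). The overlap mask is the union of the two directed
#' overlaps; stacked across slices it forms the 2-D contact regions from
#' which contact patches are meshed.
#'
#' @param slice integer label matrix.
#' @param label_a,label_b distinct labels.
#' @param threshold a [threshold_spec()] (or a bare pixel count).
#' @return list with `count_ab`, `count_ba` and logical `overlap`.
#' @export
pairwise_contact_slice <- function(slice, label_a, label_b, threshold) {
  stop_if(label_a == label_b, "label_a and label_b must differ")
  dpx <- if (inherits(threshold, "threshold_spec")) threshold$distance_px else threshold
  ma <- slice == label_a
  mb <- slice == label_b
  if (!any(ma) || !any(mb)) {
    return(list(count_ab = 0L, count_ba = 0L,
                overlap = matrix(FALSE, nrow(slice), ncol(slice))))
  }
  ea <- expand_region(ma, dpx)
  eb <- expand_region(mb, dpx)
  ov_ab <- ea & mb
  ov_ba <- eb & ma
  list(count_ab = sum(ov_ab), count_ba = sum(ov_ba),
       overlap = ov_ab | ov_ba)
}

# perimeter of a binary region in pixels: number of exposed pixel edges
# (4-neighborhood; image border counts as exposed)
mask_perimeter_px <- function(mask) {
  if (!any(mask)) return(0L)
  m <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1L
  inner <- m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
  up    <- m[1:nrow(mask),       2:(ncol(mask) + 1)]
  down  <- m[3:(nrow(mask) + 2), 2:(ncol(mask) + 1)]
  left  <- m[2:(nrow(mask) + 1), 1:ncol(mask)]
  right <- m[2:(nrow(mask) + 1), 3:(ncol(mask) + 2)]
  sum(inner & !up) + sum(inner & !down) + sum(inner & !left) + sum(inner & !right)
}

#' Compute the full adjacency matrix of a label volume
#'
#' For every co-occurring label pair the directed shared-pixel counts are
#' accumulated over the in-region slices; the symmetric matrix entry is the
#' arithmetic mean of the two directed totals (both directions are retained
#' in the contact records). Contact records also carry per-slice outline
#' (perimeter) lengths of the overlap region and the total contact area,
#' perimeter sum times z spacing, in nm^2.
#'
#' @param vol a [label_volume()].
#' @param threshold a [threshold_spec()].
#' @return list with `adjacency` (labeled symmetric matrix over all in-region
#'   labels) and `records` (list of contact records, one per unordered pair
#'   in contact; each has `pair`, `directed_pixels`, `overlap_slices`,
#'   `per_slice_outline_length_nm`, `total_area_nm2`).
#' @export
compute_adjacency_matrix <- function(vol, threshold) {
  stopifnot(inherits(vol, "label_volume"), inherits(threshold, "threshold_spec"))
  zs <- region_indices(vol)
  labels <- sort(unique(unlist(lapply(vol$slices[zs], function(s)
    unique(s[s != 0L])))))
  stop_if(length(labels) == 0, "volume has no nonzero labels in region")
  labs <- as.character(labels)
  n <- length(labels)
  directed <- matrix(0, n, n, dimnames = list(labs, labs)) # [a,b] = count a->b
  overlaps <- list()  # per unordered pair: list of per-slice masks, keyed "a|b"
  per_slice_len <- list()
  dpx <- threshold$distance_px
  for (z in zs) {
    sl <- vol$slices[[z]]
    present <- sort(unique(sl[sl != 0L]))
    if (length(present) < 1) next
    exp_masks <- lapply(present, function(l) expand_region(sl == l, dpx))
    names(exp_masks) <- as.character(present)
    if (length(present) >= 2) {
      for (ai in seq_along(present)) {
        a <- present[ai]
        ea <- exp_masks[[ai]]
        hit <- sl[ea]
        hit <- hit[hit != 0L & hit != a]
        if (length(hit)) {
          tab <- table(hit)
          directed[as.character(a), names(tab)] <-
            directed[as.character(a), names(tab)] + as.numeric(tab)
        }
      }
      # overlap masks + outline lengths per unordered pair present on slice
      for (ai in seq_len(length(present) - 1)) {
        for (bi in seq(ai + 1, length(present))) {
          a <- present[ai]; b <- present[bi]
          ov <- (exp_masks[[ai]] & (sl == b)) | (exp_masks[[bi]] & (sl == a))
          if (any(ov)) {
            key <- paste(a, b, sep = "|")
            overlaps[[key]] <- c(overlaps[[key]], structure(list(ov), names = z))
            per_slice_len[[key]] <- c(per_slice_len[[key]],
                                      mask_perimeter_px(ov) * vol$pixel_size)
          }
        }
      }
    }
  }
  adjacency <- (directed + t(directed)) / 2
  diag(adjacency) <- 0
  records <- lapply(names(overlaps), function(key) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1]]
    lens <- per_slice_len[[key]]
    list(pair = ab,
         directed_pixels = c(directed[ab[1], ab[2]], directed[ab[2], ab[1]]),
         overlap_slices = overlaps[[key]],
         per_slice_outline_length_nm = lens,
         total_area_nm2 = sum(lens) * vol$z_spacing)
  })
  names(records) <- names(overlaps)
  list(adjacency = adjacency, records = records)
}

#' Calibrate the per-dataset distance threshold
#'
#' Reproduces the cross-dataset calibration protocol: for each candidate
#' distance, every cell outline is expanded by that distance into its
#' directly contacting partners and the mean penetration depth (how far the
#' expansion reaches past the partner's near boundary, in nm) is measured;
#' the smallest candidate whose mean depth reaches `target_overlap_nm` is
#' returned. The reference (manually segmented) datasets used a 45 nm
#' expansion, which penetrates ~30 nm into directly contacting cells; other
#' datasets are calibrated to match that overlap.
#'
#' @param vol a [label_volume()].
#' @param reference_expansion_nm expansion used to define direct contact
#'   (default 45 nm).
#' @param target_overlap_nm overlap depth to match (default 30 nm).
#' @param candidates_nm ascending candidate distances in nm.
#' @return list with `distance_nm` (selected candidate), `mean_depth_nm`
#'   (its achieved depth) and `depths` (named vector over all candidates
#'   evaluated, in order, up to the selected one).
#' @export
calibrate_threshold <- function(vol, reference_expansion_nm = 45,
                                target_overlap_nm = 30, candidates_nm) {
  stopifnot(inherits(vol, "label_volume"))
  stop_if(is.unsorted(candidates_nm), "candidates_nm must be ascending")
  ref <- threshold_spec(reference_expansion_nm, vol$pixel_size)
  base <- compute_adjacency_matrix(vol, ref)
  contact_pairs <- base$adjacency
  pairs <- which(contact_pairs > 0 & upper.tri(contact_pairs), arr.ind = TRUE)
  stop_if(nrow(pairs) == 0, "no directly contacting pair in volume")
  labs <- rownames(contact_pairs)
  depths <- numeric(0)
  for (cand in candidates_nm) {
    cpx <- round_half_up(cand / vol$pixel_size)
    depth <- mean_penetration_depth(vol, labs[pairs[, 1]], labs[pairs[, 2]],
                                    cpx, cand)
    depths[as.character(cand)] <- depth
    if (depth >= target_overlap_nm - 1e-9) {
      return(list(distance_nm = cand, mean_depth_nm = depth, depths = depths))
    }
  }
  stop(sprintf(
    "no candidate reaches a %g nm overlap; achieved depths: %s",
    target_overlap_nm,
    paste(sprintf("%g nm -> %.2f nm", candidates_nm, depths), collapse = ", ")),
    call. = FALSE)
}

# mean over ordered contacting pairs of the maximum penetration depth: for
# pixels of B covered by the expansion of A at candidate distance c (px),
# depth = max over covered pixels of (c - distance-to-A) * pixel_size
mean_penetration_depth <- function(vol, lab_a, lab_b, cand_px, cand_nm) {
  zs <- region_indices(vol)
  ordered <- rbind(cbind(lab_a, lab_b), cbind(lab_b, lab_a))
  depth <- numeric(nrow(ordered))
  for (k in seq_len(nrow(ordered))) {
    a <- as.integer(ordered[k, 1]); b <- as.integer(ordered[k, 2])
    dmax <- 0
    for (z in zs) {
      sl <- vol$slices[[z]]
      ma <- sl == a
      mb <- sl == b
      if (!any(ma) || !any(mb)) next
      dmap <- as.matrix(EBImage::distmap(1 - ma, metric = "euclidean"))
      covered <- mb & dmap <= cand_px
      if (any(covered)) {
        pen <- (cand_px - dmap[covered]) * vol$pixel_size
        dmax <- max(dmax, pen)
      }
    }
    depth[k] <- dmax
  }
  mean(depth)
}

#' Per-contact statistics for a primary neuron
#'
#' For each contact partner of the primary neuron: total contact area (nm^2),
#' dense rank by area (1 = largest; ties share a rank), and the area as a
#' percentage of the neuron's surface and of the whole nerve-ring surface.
#'
#' @param records contact records from [compute_adjacency_matrix()].
#' @param primary_label the neuron whose contacts are summarized.
#' @param neuron_surface_nm2,ring_surface_nm2 reference surfaces (> 0).
#' @return data.frame with columns `partner`, `area_nm2`, `rank`,
#'   `pct_of_neuron`, `pct_of_ring`.
#' @export
contact_stats <- function(records, primary_label,
                          neuron_surface_nm2, ring_surface_nm2) {
  stop_if(neuron_surface_nm2 <= 0 || ring_surface_nm2 <= 0,
          "reference surfaces must be > 0")
  primary_label <- as.character(primary_label)
  mine <- Filter(function(r) primary_label %in% r$pair, records)
  stop_if(length(mine) == 0,
          sprintf("no contacts recorded for label %s", primary_label))
  partner <- vapply(mine, function(r) setdiff(r$pair, primary_label), character(1))
  area <- vapply(mine, function(r) r$total_area_nm2, numeric(1))
  data.frame(partner = partner,
             area_nm2 = area,
             rank = dense_rank_desc(area),
             pct_of_neuron = 100 * area / neuron_surface_nm2,
             pct_of_ring = 100 * area / ring_surface_nm2,
             row.names = NULL)
}

#' Volume and surface area of a labeled neuron
#'
#' Volume is the in-region voxel count times `pixel_size^2 * z_spacing`;
#' surface area is measured on the label's isosurface mesh (see
#' [isosurface()]).
#'
#' @param vol a [label_volume()].
#' @param label label id present in the volume.
#' @return list with `volume_nm3` and `surface_area_nm2`.
#' @export
neuron_stats <- function(vol, label) {
  stopifnot(inherits(vol, "label_volume"))
  zs <- region_indices(vol)
  masks <- lapply(vol$slices[zs], function(s) s == label)
  nvox <- sum(vapply(masks, sum, numeric(1)))
  stop_if(nvox == 0, sprintf("label %s absent from volume region", label))
  arr <- array(unlist(masks),
               dim = c(nrow(masks[[1]]), ncol(masks[[1]]), length(masks)))
  mesh <- isosurface(arr, pixel_size = vol$pixel_size, z_spacing = vol$z_spacing)
  list(volume_nm3 = nvox * vol$pixel_size^2 * vol$z_spacing,
       surface_area_nm2 = mesh_surface_area(mesh))
}
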