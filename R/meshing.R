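#' Triangle surface mesh
#'
#' @param vertices numeric N x 3 matrix of (x, y, z) coordinates in nm.
#' @param faces integer M x 3 matrix of 1-based vertex indices.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  stop_if(ncol(vertices) != 3, "vertices must be N x 3")
  stop_if(any(!is.finite(vertices)), "vertex coordinates must be finite")
  if (nrow(faces) > 0) {
    stop_if(ncol(faces) != 3, "faces must be M x 3")
    stop_if(min(faces) < 1 || max(faces) > nrow(vertices),
            "face indices out of range")
    degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
      faces[, 2] == faces[, 3]
    stop_if(any(degen), "degenerate faces (repeated vertex indices)")
  }
  storage.mode(faces) <- "integer"
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, area %.4g nm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_surface_area(x)))
  invisible(x)
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas (half cross-product norms), in nm^2.
#'
#' @param mesh a [surface_mesh()].
#' @return total area.
#' @export
mesh_surface_area <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(0)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Watertightness audit
#'
#' A closed triangulated surface has every undirected edge shared by exactly
#' two faces.
#'
#' @param mesh a [surface_mesh()].
#' @return TRUE/FALSE.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

# 6-tetrahedron decomposition of the unit cube around the 0-6 diagonal.
# Corner offsets are (row, col, slice) displacements; the induced face
# diagonals match between neighboring cubes, so the extracted surface is
# watertight.
.mt_corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                     c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
.mt_tets <- rbind(c(0, 1, 2, 6), c(0, 2, 3, 6), c(0, 3, 7, 6),
                  c(0, 7, 4, 6), c(0, 4, 5, 6), c(0, 5, 1, 6)) + 1L

# triangles (as pairs of tet-local corner indices whose edge midpoint is a
# vertex) for each of the 16 inside/outside patterns of a tetrahedron
.mt_case <- local({
  cases <- vector("list", 16)
  for (pat in 1:14) {
    inside <- which(bitwAnd(pat, c(1L, 2L, 4L, 8L)) > 0)
    outside <- setdiff(1:4, inside)
    tri <- if (length(inside) == 1) {
      a <- inside
      list(rbind(c(a, outside[1]), c(a, outside[2]), c(a, outside[3])))
    } else if (length(inside) == 3) {
      a <- outside
      list(rbind(c(a, inside[1]), c(a, inside[2]), c(a, inside[3])))
    } else { # 2 in, 2 out: quad split into two triangles
      a <- inside[1]; b <- inside[2]; c_ <- outside[1]; d <- outside[2]
      list(rbind(c(a, c_), c(a, d), c(b, d)),
           rbind(c(a, c_), c(b, d), c(b, c_)))
    }
    cases[[pat + 1]] <- tri
  }
  cases
})

#' Isosurface of a binary mask stack
#'
#' Extracts the level-0.5 surface of a binary volume by marching tetrahedra
#' (each grid cube split into six tetrahedra; with binary voxel values the
#' iso-vertices fall on voxel-center edge midpoints). The volume is padded
#' with background so the surface is closed, vertex coordinates are scaled
#' anisotropically to physical nm by (pixel_size, pixel_size, z_spacing),
#' and no smoothing of any kind is applied: re-running on the same mask is
#' bitwise identical.
#'
#' @param mask a 3-D logical/0-1 array (row, col, slice), a list of 2-D
#'   masks, or a [label_volume()] together with `label`.
#' @param pixel_size,z_spacing physical calibration in nm (taken from the
#'   volume when `mask` is a [label_volume()]).
#' @param downsample integer x-y block-reduction factor applied to the masks
#'   before triangulation (default 1 = off); a reduced pixel is foreground
#'   if any constituent pixel is. The effective pixel size is scaled by the
#'   factor.
#' @param label label id to extract when `mask` is a [label_volume()].
#' @return a [surface_mesh()]; vertices are (x, y, z) = (col, row, slice)
#'   scaled to nm.
#' @export
isosurface <- function(mask, pixel_size = NULL, z_spacing = NULL,
                       downsample = 1L, label = NULL) {
  if (inherits(mask, "label_volume")) {
    stop_if(is.null(label), "label required when meshing a label_volume")
    pixel_size <- mask$pixel_size
    z_spacing <- mask$z_spacing
    zs <- region_indices(mask)
    mask <- lapply(mask$slices[zs], function(s) s == label)
  }
  if (is.list(mask)) {
    mask <- array(unlist(mask),
                  dim = c(nrow(mask[[1]]), ncol(mask[[1]]), length(mask)))
  }
  stop_if(is.null(pixel_size) || is.null(z_spacing),
          "pixel_size and z_spacing required")
  stop_if(downsample < 1 || downsample != round(downsample),
          "downsample must be a positive integer")
  v <- (mask != 0) * 1L
  stop_if(sum(v) == 0, "empty mask")
  if (downsample > 1) {
    v <- downsample_xy(v, as.integer(downsample))
    pixel_size <- pixel_size * downsample
  }
  d <- dim(v)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  marching_tetrahedra(pad, c(pixel_size, pixel_size, z_spacing))
}

downsample_xy <- function(v, f) {
  d <- dim(v)
  nr <- ceiling(d[1] / f); nc <- ceiling(d[2] / f)
  out <- array(0L, c(nr, nc, d[3]))
  ri <- (seq_len(d[1]) - 1L) %/% f + 1L
  ci <- (seq_len(d[2]) - 1L) %/% f + 1L
  for (z in seq_len(d[3])) {
    agg <- t(rowsum(t(rowsum(v[, , z], ri)), ci))
    out[, , z] <- (agg > 0) * 1L
  }
  out
}

# core extractor on a padded binary array; spacing = (row, col, slice) steps
marching_tetrahedra <- function(pad, spacing) {
  d <- dim(pad)
  nd <- d - 1L
  corner_vals <- lapply(seq_len(8), function(ci) {
    o <- .mt_corners[ci, ]
    pad[(1 + o[1]):(nd[1] + o[1]), (1 + o[2]):(nd[2] + o[2]),
        (1 + o[3]):(nd[3] + o[3])]
  })
  total <- Reduce(`+`, corner_vals)
  mixed <- which(total > 0L & total < 8L)
  if (length(mixed) == 0) stop("no surface found", call. = FALSE)
  ijk <- arrayInd(mixed, nd)   # cube origin voxel index in padded array
  bits <- vapply(corner_vals, function(cv) cv[mixed], numeric(length(mixed)))
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1)
  tri_pos <- list()  # each entry: ntri x 9 matrix of index-space coordinates
  for (tt in seq_len(6)) {
    tc <- .mt_tets[tt, ]
    pat <- bits[, tc[1]] + 2 * bits[, tc[2]] + 4 * bits[, tc[3]] +
      8 * bits[, tc[4]]
    for (p in 1:14) {
      sel <- which(pat == p)
      if (length(sel) == 0) next
      for (tri in .mt_case[[p + 1]]) {
        # tri: 3 rows of (corner_i, corner_j) tet-local pairs
        coords <- matrix(0, length(sel), 9)
        for (vtx in 1:3) {
          ca <- .mt_corners[tc[tri[vtx, 1]], ]
          cb <- .mt_corners[tc[tri[vtx, 2]], ]
          mid <- (ca + cb) / 2
          coords[, (vtx - 1) * 3 + 1] <- ijk[sel, 1] + mid[1]
          coords[, (vtx - 1) * 3 + 2] <- ijk[sel, 2] + mid[2]
          coords[, (vtx - 1) * 3 + 3] <- ijk[sel, 3] + mid[3]
        }
        tri_pos[[length(tri_pos) + 1]] <- coords
      }
    }
  }
  allc <- do.call(rbind, tri_pos)
  ntri <- nrow(allc)
  pts <- rbind(allc[, 1:3], allc[, 4:6], allc[, 7:9])
  key <- paste(pts[, 1] * 2, pts[, 2] * 2, pts[, 3] * 2)
  uk <- unique(key)
  vid <- match(key, uk)
  first <- match(uk, key)
  verts_idx <- pts[first, , drop = FALSE]
  # index space (row, col, slice) -> physical (x, y, z); padded index 2 is
  # the first original voxel center at coordinate 0
  verts <- cbind((verts_idx[, 2] - 2) * spacing[2],
                 (verts_idx[, 1] - 2) * spacing[1],
                 (verts_idx[, 3] - 2) * spacing[3])
  faces <- cbind(vid[seq_len(ntri)],
                 vid[ntri + seq_len(ntri)],
                 vid[2 * ntri + seq_len(ntri)])
  surface_mesh(verts, faces)
}

#' Mesh a contact patch from per-slice overlap masks
#'
#' Stacks the 2-D contact overlap regions of a neuron pair into a volume and
#' extracts its isosurface. Very small overlaps that cannot be triangulated
#' yield `NULL` with a warning rather than an error: absence of a patch is a
#' recorded outcome.
#'
#' @param overlaps list of per-slice logical masks (as stored on the contact
#'   records of [compute_adjacency_matrix()]), or a contact record.
#' @param pixel_size,z_spacing physical calibration in nm.
#' @return a [surface_mesh()], or `NULL` when the overlap is empty/too small.
#' @export
contact_patch_mesh <- function(overlaps, pixel_size, z_spacing) {
  if (is.list(overlaps) && !is.null(overlaps$overlap_slices))
    overlaps <- overlaps$overlap_slices
  if (length(overlaps) == 0 || !any(vapply(overlaps, any, logical(1)))) {
    ctm_warn("CTM_TINY_PATCH",
             "contact overlap empty or too small to triangulate; no patch mesh")
    return(NULL)
  }
  mesh <- tryCatch(
    isosurface(overlaps, pixel_size = pixel_size, z_spacing = z_spacing),
    error = function(e) NULL)
  if (is.null(mesh) || nrow(mesh$faces) == 0) {
    ctm_warn("CTM_TINY_PATCH",
             "contact overlap too small to triangulate; no patch mesh")
    return(NULL)
  }
  mesh
}

#' Rigid rotation + scaling transform
#'
#' @param rotation 3 x 3 orthonormal matrix (checked to 1e-6).
#' @param scale positive scale factor.
#' @return an object of class `transform_spec`.
#' @export
transform_spec <- function(rotation = diag(3), scale = 1) {
  rotation <- as.matrix(rotation)
  stop_if(!all(dim(rotation) == c(3, 3)), "rotation must be 3 x 3")
  stop_if(max(abs(t(rotation) %*% rotation - diag(3))) > 1e-6,
          "rotation must be orthonormal (R'R = I within 1e-6)")
  stop_if(scale <= 0, "scale must be > 0")
  structure(list(rotation = rotation, scale = scale), class = "transform_spec")
}

#' Compose two transforms
#'
#' `compose_transform(T2, T1)` is the transform equivalent to applying `T1`
#' first, then `T2`.
#'
#' @param t2,t1 [transform_spec()] objects.
#' @return a [transform_spec()].
#' @export
compose_transform <- function(t2, t1) {
  transform_spec(rotation = t2$rotation %*% t1$rotation,
                 scale = t2$scale * t1$scale)
}

#' Apply a rotation + scaling to a mesh
#'
#' Every vertex becomes `scale * (rotation %*% v)`; faces are unchanged.
#' Used to align models from differently oriented specimens to a consensus
#' orientation and scale.
#'
#' @param mesh a [surface_mesh()].
#' @param transform a [transform_spec()].
#' @return transformed [surface_mesh()].
#' @export
apply_transform <- function(mesh, transform) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(transform, "transform_spec"))
  v <- transform$scale * (mesh$vertices %*% t(transform$rotation))
  surface_mesh(v, mesh$faces)
}

unit_block <- function() {
  v <- .mt_corners - 0.5
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(5, 7, 6), c(5, 8, 7),
             c(1, 6, 2), c(1, 5, 6), c(2, 7, 3), c(2, 6, 7),
             c(3, 8, 4), c(3, 7, 8), c(4, 5, 1), c(4, 8, 5))
  surface_mesh(v, f)
}

unit_sphere <- function(subdiv = 2L) {
  # octahedron refined and projected to the unit sphere
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (s in seq_len(subdiv)) {
    nf <- list(); nv <- v
    midkey <- new.env()
    midpt <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- midkey[[key]]
      if (!is.null(got)) return(got)
      m <- (nv[i, ] + nv[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- rbind(nv, m)
      midkey[[key]] <- nrow(nv)
      nrow(nv)
    }
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c_ <- f[t, 3]
      ab <- midpt(a, b); bc <- midpt(b, c_); ca <- midpt(c_, a)
      nf[[length(nf) + 1]] <- rbind(c(a, ab, ca), c(ab, b, bc),
                                    c(ca, bc, c_), c(ab, bc, ca))
    }
    v <- nv; f <- do.call(rbind, nf)
  }
  surface_mesh(v / 2, f)  # diameter 1
}

unit_star <- function() {
  # 6-spike octahedral star: small cube core with a pyramid on each face
  core <- unit_block()
  v <- core$vertices * 0.5
  f <- NULL
  tips <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1)) * 0.5
  face_sets <- list(c(2, 3, 7, 6), c(1, 5, 8, 4), c(3, 4, 8, 7),
                    c(1, 2, 6, 5), c(5, 6, 7, 8), c(1, 4, 3, 2))
  for (s in seq_len(6)) {
    tip_id <- nrow(v) + 1L
    v <- rbind(v, tips[s, ])
    q <- face_sets[[s]]
    f <- rbind(f, cbind(q, c(q[-1], q[1]), tip_id))
  }
  surface_mesh(v, f)
}

#' Synapse glyph meshes
#'
#' One glyph mesh per annotation: presynaptic sites are blocks, postsynaptic
#' sites spheres, and electrical synapses 6-spike octahedral stars. Each
#' glyph's centroid is placed at the annotated coordinate and its size is
#' `base_size_nm` times the annotation's scale factor.
#'
#' @param annotations data.frame with columns `partner_a`, `partner_b`,
#'   `kind` (`"pre"`, `"post"` or `"electrical"`), `x`, `y`, `z` (nm) and
#'   optionally `scale` (default 1).
#' @param base_size_nm nominal glyph diameter in nm (default 100).
#' @return list of [surface_mesh()] objects, one per annotation row.
#' @export
place_synapse_glyphs <- function(annotations, base_size_nm = 100) {
  stop_if(!all(c("kind", "x", "y", "z") %in% names(annotations)),
          "annotations need kind, x, y, z columns")
  bad <- setdiff(unique(annotations$kind), c("pre", "post", "electrical"))
  stop_if(length(bad) > 0,
          sprintf("unknown synapse kind(s): %s", paste(bad, collapse = ",")))
  if (is.null(annotations$scale)) annotations$scale <- 1
  protos <- list(pre = unit_block(), post = unit_sphere(),
                 electrical = unit_star())
  lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    proto <- protos[[a$kind]]
    size <- base_size_nm * a$scale
    v <- proto$vertices * size
    v <- sweep(v, 2, colMeans(v))                 # centroid at origin
    v <- sweep(v, 2, c(a$x, a$y, a$z), "+")       # then at the annotation
    surface_mesh(v, proto$faces)
  })
}

#' Write a mesh as Wavefront OBJ
#'
#' Emits `v` records (nm coordinates) and 1-based `f` records.
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  if (nrow(mesh$faces) > 0)
    writeLines(sprintf("f %d %d %d",
                       mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ mesh
#'
#' Parses `v` and `f` records (triangular faces; `f` entries may carry
#' `/texture/normal` suffixes, which are ignored). Malformed records are
#' reported with their line number.
#'
#' @param path OBJ file path.
#' @return a [surface_mesh()].
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vs <- list(); fs <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    parts <- strsplit(ln, "\\s+")[[1]]
    if (parts[1] == "v") {
      if (length(parts) < 4)
        stop(sprintf("parse error at line %d: malformed vertex record", i),
             call. = FALSE)
      xyz <- suppressWarnings(as.numeric(parts[2:4]))
      if (any(is.na(xyz)))
        stop(sprintf("parse error at line %d: non-numeric vertex", i),
             call. = FALSE)
      vs[[length(vs) + 1]] <- xyz
    } else if (parts[1] == "f") {
      if (length(parts) != 4)
        stop(sprintf("parse error at line %d: only triangular faces supported", i),
             call. = FALSE)
      idx <- suppressWarnings(as.integer(sub("/.*$", "", parts[2:4])))
      if (any(is.na(idx)))
        stop(sprintf("parse error at line %d: non-integer face index", i),
             call. = FALSE)
      fs[[length(fs) + 1]] <- idx
    }
  }
  stop_if(length(vs) == 0, "no vertices in OBJ file")
  surface_mesh(do.call(rbind, vs),
               if (length(fs)) do.call(rbind, fs) else matrix(integer(0), 0, 3))
}
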