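## Trajectory post-processing: minimum-image ion--site distances, the
## distance-criterion binding classification with occupancy and event
## segmentation, and voxelized density fields in molar units.

## Orthorhombic minimum-image displacement of points `P` (n x 3) from a
## single point `q`, under box `b` (length 3).
.min_image <- function(P, q, b) {
  d <- sweep(P, 2, q)
  for (k in 1:3) d[, k] <- d[, k] - b[k] * round(d[, k] / b[k])
  d
}

#' Minimum ion--site distance series
#'
#' Per frame and ion, the shortest distance to any site atom under the
#' orthorhombic minimum-image convention. Triclinic boxes are rejected.
#'
#' @param traj an [make_ion_traj()]-style `IonTrajectory` (fields `ions`
#'   T x N x 3, `sites` S x 3, `box` length-3).
#' @param ions optional ion indices (default all).
#' @param sites optional site-atom indices (default all).
#' @return T x N matrix of minimum distances (A).
#' @export
min_distance_series <- function(traj, ions = NULL, sites = NULL) {
  if (length(traj$box) != 3L || any(traj$box <= 0))
    stop_elevator("validation", "orthorhombic box (3 positive lengths) required")
  S <- traj$sites[if (is.null(sites)) seq_len(nrow(traj$sites)) else sites, ,
                  drop = FALSE]
  ii <- if (is.null(ions)) seq_len(dim(traj$ions)[2]) else ions
  if (nrow(S) == 0L || length(ii) == 0L)
    stop_elevator("empty_selection", "empty ion or site selection")
  T_ <- dim(traj$ions)[1]
  out <- matrix(NA_real_, T_, length(ii))
  for (f in seq_len(T_)) {
    P <- traj$ions[f, ii, , drop = TRUE]
    if (is.null(dim(P))) P <- matrix(P, ncol = 3L)
    for (s in seq_len(nrow(S))) {
      d <- sqrt(rowSums(.min_image(P, S[s, ], traj$box)^2))
      out[f, ] <- if (s == 1L) d else pmin(out[f, ], d)
    }
  }
  out
}

#' Distance-criterion binding classification
#'
#' An ion is bound when its minimum site distance is within the
#' threshold (default 3 A, the carboxyl-oxygen criterion). Returns per-
#' ion bound fractions, the site occupancy (fraction of frames with at
#' least one bound ion), and bound-event segments (entry/exit frames).
#'
#' @param distances T x N matrix from [min_distance_series()].
#' @param threshold binding distance (A), default 3.0.
#' @return Object of class `BindingSeries`: `bound` (T x N logical),
#'   `ion_fraction`, `occupancy`, `events` (ion, start, end, length),
#'   `threshold`.
#' @export
bound_mask <- function(distances, threshold = 3.0) {
  distances <- as.matrix(distances)
  bound <- distances <= threshold
  events <- data.frame()
  for (n in seq_len(ncol(bound))) {
    r <- rle(bound[, n])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    if (length(on))
      events <- rbind(events, data.frame(ion = n, start = starts[on],
                                         end = ends[on],
                                         length = r$lengths[on]))
  }
  structure(list(bound = bound,
                 ion_fraction = colMeans(bound),
                 occupancy = mean(rowSums(bound) > 0),
                 events = events, threshold = threshold),
            class = "BindingSeries")
}

#' @export
print.BindingSeries <- function(x, ...) {
  cat(sprintf("<BindingSeries> occupancy %.3f (threshold %.1f A, %d event(s))\n",
              x$occupancy, x$threshold, nrow(x$events)))
  invisible(x)
}

#' Voxelized density grid in molar units
#'
#' Histograms selected coordinates per frame on a regular grid
#' (half-open voxels: a coordinate exactly on a boundary belongs to the
#' higher-index voxel), averages counts over frames, and converts to
#' mol/L via c = <count> / (V_voxel * 1e-27 L/A^3 * N_A).
#'
#' @param traj an `IonTrajectory`.
#' @param spacing voxel edge (A), default 1.
#' @param bounds 2 x 3 matrix (min; max) in A; default the periodic box.
#' @return Object of class `DensityGrid`: `origin`, `spacing`, `dim`,
#'   `counts` (mean count per voxel per frame, 3d array),
#'   `concentration` (mol/L), `n_frames`, `mean_inside`.
#' @export
density_grid <- function(traj, spacing = 1, bounds = NULL) {
  if (spacing <= 0) stop_elevator("validation", "spacing must be > 0")
  if (is.null(bounds)) bounds <- rbind(c(0, 0, 0), traj$box)
  lo <- bounds[1, ]; hi <- bounds[2, ]
  if (any(hi <= lo)) stop_elevator("validation", "zero-volume bounds")
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing - 1e-9)))
  T_ <- dim(traj$ions)[1]
  counts <- numeric(prod(dims))
  inside_total <- 0
  for (f in seq_len(T_)) {
    P <- traj$ions[f, , , drop = TRUE]
    if (is.null(dim(P))) P <- matrix(P, ncol = 3L)
    ix <- floor(sweep(sweep(P, 2, lo), 2, rep(spacing, 3), `/`))
    ok <- ix[, 1] >= 0 & ix[, 1] < dims[1] &
          ix[, 2] >= 0 & ix[, 2] < dims[2] &
          ix[, 3] >= 0 & ix[, 3] < dims[3]
    ix <- ix[ok, , drop = FALSE]
    inside_total <- inside_total + nrow(ix)
    lin <- ix[, 1] + dims[1] * (ix[, 2] + dims[2] * ix[, 3]) + 1L
    tab <- tabulate(lin, nbins = prod(dims))
    counts <- counts + tab
  }
  counts <- counts / T_
  vvox <- spacing^3
  conc <- counts / (vvox * 1e-27 * AVOGADRO)
  structure(list(origin = lo, spacing = spacing, dim = dims,
                 counts = array(counts, dims),
                 concentration = array(conc, dims),
                 n_frames = T_, mean_inside = inside_total / T_),
            class = "DensityGrid")
}

#' @export
print.DensityGrid <- function(x, ...) {
  cat(sprintf("<DensityGrid> %s voxels @ %.2f A, mean %.4g mol/L\n",
              paste(x$dim, collapse = "x"), x$spacing,
              mean(x$concentration)))
  invisible(x)
}

#' Bulk concentration from a density grid
#'
#' Mean concentration over the voxels of a bulk region (whole grid by
#' default, or an axis-aligned slab), with a standard error over voxels.
#'
#' @param grid a [density_grid()].
#' @param region `NULL` for the whole grid, or a list with `min` and
#'   `max` length-3 vectors (A) delimiting a slab.
#' @return list with `mol_per_L`, `sem`, `n_voxels`.
#' @export
bulk_density <- function(grid, region = NULL) {
  conc <- grid$concentration
  if (!is.null(region)) {
    idx <- lapply(1:3, function(k) {
      centers <- grid$origin[k] + (seq_len(grid$dim[k]) - 0.5) * grid$spacing
      which(centers >= region$min[k] & centers <= region$max[k])
    })
    if (any(vapply(idx, length, 0L) == 0L))
      stop_elevator("empty_selection", "bulk region selects no voxels")
    conc <- conc[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  v <- as.numeric(conc)
  list(mol_per_L = mean(v),
       sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0,
       n_voxels = length(v))
}

#' Export a density grid in OpenDX format
#'
#' @param grid a [density_grid()].
#' @param path output `.dx` path.
#' @param field `"concentration"` (mol/L) or `"counts"`.
#' @export
write_dx <- function(grid, path, field = c("concentration", "counts")) {
  field <- match.arg(field)
  d <- grid$dim
  vals <- as.numeric(aperm(grid[[field]], c(3, 2, 1)))  # z fastest in DX
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g",
            grid$origin[1] + grid$spacing / 2,
            grid$origin[2] + grid$spacing / 2,
            grid$origin[3] + grid$spacing / 2),
    sprintf("delta %g 0 0", grid$spacing),
    sprintf("delta 0 %g 0", grid$spacing),
    sprintf("delta 0 0 %g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals))), con)
  full <- length(vals) %/% 3L
  if (full > 0L)
    writeLines(sprintf("%g %g %g",
                       vals[seq(1, by = 3, length.out = full)],
                       vals[seq(2, by = 3, length.out = full)],
                       vals[seq(3, by = 3, length.out = full)]), con)
  rem <- length(vals) - 3L * full
  if (rem > 0L)
    writeLines(paste(sprintf("%g", vals[(3L * full + 1L):length(vals)]),
                     collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field'), con)
  invisible(path)
}

#' Write an ion trajectory as a CSV frame table
#'
#' Columns: `frame`, `role` (ion/site), `index`, `x`, `y`, `z`,
#' `box_x`, `box_y`, `box_z`. Site atoms are written once under frame 0.
#'
#' @param traj an `IonTrajectory`.
#' @param path output CSV path.
#' @export
write_ion_traj_csv <- function(traj, path) {
  T_ <- dim(traj$ions)[1]; N <- dim(traj$ions)[2]
  site_df <- data.frame(frame = 0L, role = "site",
                        index = seq_len(nrow(traj$sites)),
                        x = traj$sites[, 1], y = traj$sites[, 2],
                        z = traj$sites[, 3])
  ion_df <- do.call(rbind, lapply(seq_len(T_), function(f)
    data.frame(frame = f, role = "ion", index = seq_len(N),
               x = traj$ions[f, , 1], y = traj$ions[f, , 2],
               z = traj$ions[f, , 3])))
  out <- rbind(site_df, ion_df)
  out$box_x <- traj$box[1]; out$box_y <- traj$box[2]; out$box_z <- traj$box[3]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read an ion trajectory from a CSV frame table
#' @param path CSV path written by [write_ion_traj_csv()].
#' @return An `IonTrajectory`.
#' @export
read_ion_traj_csv <- function(path) {
  tab <- read.csv(path)
  box <- as.numeric(tab[1, c("box_x", "box_y", "box_z")])
  sites <- as.matrix(tab[tab$role == "site", c("x", "y", "z")])
  iondf <- tab[tab$role == "ion", ]
  frames <- sort(unique(iondf$frame))
  N <- max(iondf$index)
  ions <- array(NA_real_, c(length(frames), N, 3L))
  for (f in seq_along(frames)) {
    fr <- iondf[iondf$frame == frames[f], ]
    fr <- fr[order(fr$index), ]
    ions[f, , ] <- as.matrix(fr[, c("x", "y", "z")])
  }
  structure(list(ions = ions, sites = sites, box = box, bound_ion = 1L),
            class = "IonTrajectory")
}
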