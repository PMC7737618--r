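## Structural-ensemble PCA: Kabsch superposition, matched-residue ensemble
## construction, coordinate covariance diagonalization, scalar projections
## of structures onto principal axes, and interpolation along an axis.

#' Kabsch least-squares superposition
#'
#' Optimal rigid superposition (rotation + translation, no reflection) of
#' a mobile C-alpha model onto a reference over a masked residue subset,
#' e.g. the scaffold/dimerization domain.
#'
#' @param mobile,reference [calpha_model()] objects with equal residue count.
#' @param mask logical vector (length M) of residues used for the fit;
#'   default all.
#' @return List with `model` (transformed mobile), `rmsd_mask`,
#'   `rmsd_all`, rotation `R` and translation parameters.
#' @export
kabsch_superpose <- function(mobile, reference, mask = NULL) {
  X <- mobile$xyz; Y <- reference$xyz
  if (nrow(X) != nrow(Y))
    stop_elevator("consistency", "mobile (%d) and reference (%d) differ in size",
                  nrow(X), nrow(Y))
  if (is.null(mask)) mask <- rep(TRUE, nrow(X))
  if (sum(mask) < 3L)
    stop_elevator("degenerate", "fit mask needs >= 3 residues")
  fit <- .kabsch(X[mask, , drop = FALSE], Y[mask, , drop = FALSE])
  Xt <- sweep(X, 2, fit$cx) %*% fit$R
  Xt <- sweep(Xt, 2, fit$cy, `+`)
  out <- calpha_model(mobile$residues, Xt)
  list(model = out,
       rmsd_mask = .rmsd(Xt[mask, , drop = FALSE], Y[mask, , drop = FALSE]),
       rmsd_all = .rmsd(Xt, Y),
       R = fit$R, center_mobile = fit$cx, center_reference = fit$cy)
}

.rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

.kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  ## degeneracy: fit points must not be collinear
  if (qr(Xc)$rank < 2L || qr(Yc)$rank < 2L)
    stop_elevator("degenerate", "fit-mask points are collinear or coincident")
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  list(R = R, cx = cx, cy = cy)
}

#' Build a superposed matched-residue ensemble
#'
#' Extracts the matched (conserved-core) residues of each structure via a
#' correspondence table and superposes every member onto the reference over
#' a fit domain (single-pass fit; an optional iterative mean-structure
#' refit is available but off by default).
#'
#' @param models named list of [calpha_model()] objects; names are
#'   structure ids matching the correspondence table.
#' @param correspondence a `CorrespondenceTable` (see [load_correspondence()]),
#'   or `NULL` for identity correspondence (all models share residues).
#' @param reference_id id of the reference structure (projection origin).
#' @param fit_mask logical vector over matched positions used for the
#'   superposition (e.g. the dimerization domain); default all.
#' @param iterate_mean if `TRUE`, refit members to the running mean until
#'   convergence.
#' @return Object of class `SuperposedEnsemble`: ids, `coords`
#'   (N x M x 3 array), `fit_mask`, `reference_id`, residue table of the
#'   reference, and the mean/s.d. of fit-mask rmsd to the reference.
#' @export
build_ensemble <- function(models, correspondence = NULL, reference_id,
                           fit_mask = NULL, iterate_mean = FALSE,
                           max_iter = 10L) {
  if (is.null(names(models)) || any(names(models) == ""))
    stop_elevator("schema", "models must be a named list")
  if (!reference_id %in% names(models))
    stop_elevator("validation", "reference '%s' not among models", reference_id)
  if (is.null(correspondence)) {
    M <- n_residues(models[[reference_id]])
    mats <- lapply(names(models), function(id) {
      if (n_residues(models[[id]]) != M)
        stop_elevator("validation",
                      "structure '%s' has %d residues; reference has %d",
                      id, n_residues(models[[id]]), M)
      models[[id]]$xyz
    })
    residues <- models[[reference_id]]$residues
  } else {
    miss <- setdiff(names(models), correspondence$ids)
    if (length(miss))
      stop_elevator("validation", "no correspondence entries for: %s",
                    paste(miss, collapse = ", "))
    mats <- lapply(names(models), function(id) {
      idx <- match_residues(models[[id]], correspondence$entries[[id]], id)
      models[[id]]$xyz[idx, , drop = FALSE]
    })
    ridx <- match_residues(models[[reference_id]],
                           correspondence$entries[[reference_id]],
                           reference_id)
    residues <- models[[reference_id]]$residues[ridx, , drop = FALSE]
  }
  names(mats) <- names(models)
  M <- nrow(mats[[1]])
  if (is.null(fit_mask)) fit_mask <- rep(TRUE, M)
  if (length(fit_mask) != M)
    stop_elevator("schema", "fit_mask length %d != matched size %d",
                  length(fit_mask), M)
  ref <- mats[[reference_id]]
  refm <- calpha_model(residues, ref)
  fitted <- lapply(names(mats), function(id) {
    kabsch_superpose(calpha_model(residues, mats[[id]]), refm, fit_mask)
  })
  names(fitted) <- names(mats)
  if (iterate_mean) {
    for (it in seq_len(max_iter)) {
      mean_xyz <- Reduce(`+`, lapply(fitted, function(f) f$model$xyz)) /
        length(fitted)
      meanm <- calpha_model(residues, mean_xyz)
      newfit <- lapply(names(mats), function(id)
        kabsch_superpose(calpha_model(residues, mats[[id]]), meanm, fit_mask))
      names(newfit) <- names(mats)
      shift <- max(vapply(names(mats), function(id)
        .rmsd(newfit[[id]]$model$xyz, fitted[[id]]$model$xyz), 0))
      fitted <- newfit
      if (shift < 1e-6) break
    }
  }
  coords <- array(NA_real_, dim = c(length(mats), M, 3L),
                  dimnames = list(names(mats), NULL, NULL))
  for (id in names(mats)) coords[id, , ] <- fitted[[id]]$model$xyz
  rmsds <- vapply(fitted, `[[`, 0, "rmsd_mask")
  structure(list(ids = names(mats), coords = coords, fit_mask = fit_mask,
                 reference_id = reference_id, residues = residues,
                 mean_fit_rmsd = mean(rmsds),
                 sd_fit_rmsd = if (length(rmsds) > 1L) sd(rmsds) else 0,
                 fit_rmsd = rmsds),
            class = "SuperposedEnsemble")
}

#' @export
print.SuperposedEnsemble <- function(x, ...) {
  cat(sprintf("<SuperposedEnsemble> %d structures x %d residues (ref %s)\n",
              length(x$ids), dim(x$coords)[2], x$reference_id))
  cat(sprintf("  fit rmsd %.2f +/- %.2f A over %d masked residues\n",
              x$mean_fit_rmsd, x$sd_fit_rmsd, sum(x$fit_mask)))
  invisible(x)
}

ensemble_matrix <- function(ens) {
  N <- dim(ens$coords)[1]; M <- dim(ens$coords)[2]
  t(vapply(seq_len(N), function(i) flatten_xyz(ens$coords[i, , ]),
           numeric(3L * M)))
}

#' Coordinate covariance PCA of a superposed ensemble
#'
#' Diagonalizes the 3M x 3M coordinate covariance matrix (population
#' normalization 1/N; variance fractions are invariant to this choice).
#' Computed through the SVD of the centered coordinate matrix. At most
#' N - 1 eigenvalues are nonzero. Eigenvector signs are fixed so that a
#' designated calibration structure (e.g. an outward-facing state)
#' projects positive on PC1; without one, the largest-magnitude component
#' of each axis is made positive.
#'
#' @param ensemble a `SuperposedEnsemble`.
#' @param calibrate_id optional structure id given a positive PC1
#'   projection relative to the ensemble reference.
#' @return Object of class `PCABasis`: `mean` (3M), `vectors`
#'   (K x 3M, orthonormal rows), `values` (descending, A^2), `varfrac`,
#'   plus the fit mask and reference coordinates for frame checks.
#' @export
covariance_pca <- function(ensemble, calibrate_id = NULL) {
  X <- ensemble_matrix(ensemble)
  N <- nrow(X)
  if (N < 2L)
    stop_elevator("insufficient_data", "PCA needs >= 2 structures, got %d", N)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc, nu = 0)
  K <- min(N - 1L, ncol(X))
  values <- (s$d^2 / N)[seq_len(K)]
  vectors <- t(s$v[, seq_len(K), drop = FALSE])
  ref <- flatten_xyz(ensemble$coords[ensemble$reference_id, , ])
  for (k in seq_len(K)) {
    flip <- if (!is.null(calibrate_id) && k == 1L) {
      if (!calibrate_id %in% ensemble$ids)
        stop_elevator("validation", "calibration structure '%s' not in ensemble",
                      calibrate_id)
      Tc <- flatten_xyz(ensemble$coords[calibrate_id, , ]) - ref
      sum(Tc * vectors[k, ]) < 0
    } else {
      v <- vectors[k, ]
      v[which.max(abs(v))] < 0
    }
    if (flip) vectors[k, ] <- -vectors[k, ]
  }
  total_var <- sum(Xc^2) / N
  structure(list(mean = mu, vectors = vectors, values = values,
                 varfrac = values / total_var, total_variance = total_var,
                 reference_id = ensemble$reference_id,
                 reference_coords = ref, fit_mask = ensemble$fit_mask),
            class = "PCABasis")
}

#' @export
print.PCABasis <- function(x, ...) {
  cat(sprintf("<PCABasis> %d components over %d coordinates\n",
              length(x$values), length(x$mean)))
  k <- seq_len(min(3L, length(x$values)))
  cat(sprintf("  PC%d: lambda %.3g A^2 (%.1f%% variance)\n",
              k, x$values[k], 100 * x$varfrac[k]), sep = "")
  invisible(x)
}

#' Scalar projection of a structure onto principal axes
#'
#' The projection of structure i on component k is the scalar product of
#' the displacement vector from the reference structure with the unit
#' eigenvector: p_ik = |T_i0| cos(angle(T_i0, PC_k)) = T_i0 . PC_k, with
#' T_i0 the 3M-vector between structure i and the chosen origin.
#'
#' @param model a [calpha_model()] already superposed in the basis frame
#'   (or an M x 3 matrix / 3M vector).
#' @param basis a `PCABasis`.
#' @param reference origin structure (defaults to the basis reference).
#' @param components integer vector of component indices.
#' @param max_frame_rmsd if finite, error when the fit-mask rmsd between
#'   `model` and the reference exceeds it (frame-mismatch guard).
#' @return Named numeric vector of projections (Angstrom).
#' @export
project <- function(model, basis, reference = NULL,
                    components = seq_along(basis$values),
                    max_frame_rmsd = Inf) {
  x <- .coerce_flat(model)
  r <- if (is.null(reference)) basis$reference_coords
       else .coerce_flat(reference)
  if (length(x) != length(basis$mean))
    stop_elevator("consistency", "coordinate length %d != basis size %d",
                  length(x), length(basis$mean))
  if (is.finite(max_frame_rmsd) && !is.null(basis$fit_mask)) {
    mask3 <- rep(basis$fit_mask, each = 3L)
    fr <- sqrt(mean(rowSums(
      (unflatten_xyz(x[mask3]) - unflatten_xyz(basis$reference_coords[mask3]))^2)))
    if (fr > max_frame_rmsd)
      stop_elevator("frame", "fit-mask rmsd %.3f A exceeds frame tolerance %.3f",
                    fr, max_frame_rmsd)
  }
  Tvec <- x - r
  p <- drop(basis$vectors[components, , drop = FALSE] %*% Tvec)
  names(p) <- paste0("PC", components)
  p
}

.coerce_flat <- function(m) {
  if (inherits(m, "CalphaModel")) flatten_xyz(m$xyz)
  else if (is.matrix(m)) flatten_xyz(m)
  else as.numeric(m)
}

#' Projection table for a set of structures
#'
#' @param ensemble a `SuperposedEnsemble`.
#' @param basis a `PCABasis` built from it.
#' @param components component indices.
#' @return data frame: structure id and one column per component.
#' @export
projection_table <- function(ensemble, basis,
                             components = seq_along(basis$values)) {
  rows <- lapply(ensemble$ids, function(id)
    project(ensemble$coords[id, , ], basis, components = components))
  out <- data.frame(id = ensemble$ids, do.call(rbind, rows),
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Interpolate structures along a principal component
#'
#' Frame a = mean + a * PC_k, reshaped to M x 3; writing the result with
#' [write_models()] yields a viewable pseudo-trajectory along the axis.
#'
#' @param basis a `PCABasis`.
#' @param residues residue table for the output models.
#' @param k component index.
#' @param amplitudes numeric vector of amplitudes (Angstrom).
#' @return List of [calpha_model()] frames.
#' @export
pc_interpolate <- function(basis, residues, k = 1L, amplitudes) {
  check_finite(amplitudes, "amplitudes")
  lapply(amplitudes, function(a)
    calpha_model(residues, unflatten_xyz(basis$mean + a * basis$vectors[k, ])))
}
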