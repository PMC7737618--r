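## C-alpha elastic network models: network construction (uniform-cutoff
## ANM and an MD-calibrated ED-ENM parameterization), anisotropic Hessian
## normal modes, per-residue fluctuation/hinge profiles, and overlaps of
## modes with transition difference vectors.

#' Elastic network parameters
#'
#' Two spring parameterizations over the C-alpha node set:
#' * `cutoff-ANM`: an edge joins every node pair within `cutoff` Angstrom,
#'   with uniform constant `k0`.
#' * `ED-ENM`: sequence-local pairs (separation s <= `span` within a
#'   chain) get k = `c_seq` / s^`seq_exponent`; all other pairs within
#'   `cutoff` get k = (`c_cart` / r0)^`cart_power`, decaying with the
#'   equilibrium distance.
#'
#' @param variant `"cutoff-ANM"` or `"ED-ENM"`.
#' @param cutoff distance cutoff R_c in Angstrom.
#' @param k0 uniform spring constant (energy/A^2), cutoff-ANM.
#' @param c_seq,seq_exponent sequence-local constant and exponent (ED-ENM).
#' @param c_cart,cart_power nonlocal distance constant (Angstrom) and
#'   inverse-power exponent (ED-ENM).
#' @param span sequence-local separation span (default 3).
#' @return Object of class `ENMParams`.
#' @export
enm_params <- function(variant = c("cutoff-ANM", "ED-ENM"), cutoff = 12,
                       k0 = 1, c_seq = 60, seq_exponent = 2,
                       c_cart = 6, cart_power = 6, span = 3L) {
  variant <- match.arg(variant)
  if (cutoff <= 0 || k0 <= 0 || c_seq <= 0 || c_cart <= 0)
    stop_elevator("validation", "ENM constants and cutoff must be positive")
  structure(list(variant = variant, cutoff = cutoff, k0 = k0,
                 c_seq = c_seq, seq_exponent = seq_exponent,
                 c_cart = c_cart, cart_power = cart_power,
                 span = as.integer(span)),
            class = "ENMParams")
}

#' Build an elastic network from a C-alpha model
#'
#' @param model a [calpha_model()].
#' @param params an [enm_params()].
#' @return Object of class `ElasticNetwork`: node coordinates and an edge
#'   table (i, j, spring constant k, equilibrium distance r0).
#' @export
build_network <- function(model, params = enm_params()) {
  X <- model$xyz
  M <- nrow(X)
  if (M < 2L) stop_elevator("validation", "network needs >= 2 nodes")
  D <- as.matrix(dist(X))
  idx <- which(upper.tri(D) & D <= params$cutoff, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]; r0 <- D[idx]
  if (params$variant == "cutoff-ANM") {
    k <- rep(params$k0, length(r0))
  } else {
    ch <- model$residues$chain
    s <- abs(j - i)
    local_ <- s <= params$span & ch[i] == ch[j]
    k <- (params$c_cart / r0)^params$cart_power
    k[local_] <- params$c_seq / s[local_]^params$seq_exponent
    ## sequence-local springs apply regardless of the Cartesian cutoff
    seq_pairs <- which(outer(seq_len(M), seq_len(M), function(a, b)
      b > a & (b - a) <= params$span) & outer(ch, ch, `==`), arr.ind = TRUE)
    extra <- seq_pairs[D[seq_pairs] > params$cutoff, , drop = FALSE]
    if (nrow(extra)) {
      se <- extra[, 2] - extra[, 1]
      i <- c(i, extra[, 1]); j <- c(j, extra[, 2])
      r0 <- c(r0, D[extra])
      k <- c(k, params$c_seq / se^params$seq_exponent)
    }
  }
  if (length(i) == 0L)
    stop_elevator("connectivity", "no edges: cutoff %.1f A too small",
                  params$cutoff)
  deg <- tabulate(c(i, j), nbins = M)
  if (any(deg == 0L))
    warn_elevator("connectivity", "%d isolated node(s), e.g. residue index %d",
                  sum(deg == 0L), which(deg == 0L)[1])
  ord <- order(i, j)
  structure(list(xyz = X,
                 edges = data.frame(i = i, j = j, k = k, r0 = r0)[ord, ],
                 params = params, residues = model$residues),
            class = "ElasticNetwork")
}

## Anisotropic network Hessian: off-diagonal 3x3 super-element for edge
## (i,j) is -(k/r0^2) d %o% d with d the equilibrium bond vector; diagonal
## blocks are minus the sum of the off-diagonal blocks in their row.
enm_hessian <- function(network) {
  X <- network$xyz
  M <- nrow(X)
  H <- matrix(0, 3L * M, 3L * M)
  e <- network$edges
  for (r in seq_len(nrow(e))) {
    i <- e$i[r]; j <- e$j[r]
    d <- X[j, ] - X[i, ]
    blk <- -(e$k[r] / e$r0[r]^2) * tcrossprod(d)
    ii <- (3L * (i - 1L) + 1L):(3L * i)
    jj <- (3L * (j - 1L) + 1L):(3L * j)
    H[ii, jj] <- H[ii, jj] + blk
    H[jj, ii] <- H[jj, ii] + blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  H
}

## Orthonormal rigid-body basis: 3 translations plus rotations about the
## centroid (2 for collinear node sets, else 3).
rigid_body_basis <- function(X) {
  M <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  collinear <- qr(Xc)$rank < 2L
  basis <- list(
    rep(c(1, 0, 0), M), rep(c(0, 1, 0), M), rep(c(0, 0, 1), M),
    flatten_xyz(cbind(-Xc[, 2], Xc[, 1], 0)),
    flatten_xyz(cbind(Xc[, 3], 0, -Xc[, 1])),
    flatten_xyz(cbind(0, -Xc[, 3], Xc[, 2]))
  )
  Q <- qr.Q(qr(do.call(cbind, basis)))
  n_rigid <- if (collinear) 5L else 6L
  Q[, seq_len(n_rigid), drop = FALSE]
}

#' Compute normal modes of an elastic network
#'
#' Diagonalizes the 3M x 3M anisotropic Hessian; the 6 near-zero
#' rigid-body modes (5 for collinear node sets) are discarded and the
#' lowest `n_modes` internal modes returned in ascending eigenvalue
#' order. When the spectral gap between rigid and internal modes is not
#' clean, the rigid-body subspace is projected out explicitly before
#' diagonalization.
#'
#' @param network an [build_network()] result.
#' @param n_modes number of internal modes to keep (default all).
#' @return Object of class `ModeSet`: `values` (ascending, energy/A^2),
#'   `vectors` (3M x n, orthonormal unit columns), `n_rigid_removed`.
#' @export
compute_modes <- function(network, n_modes = NULL) {
  H <- enm_hessian(network)
  M <- nrow(network$xyz)
  Q <- rigid_body_basis(network$xyz)
  n_rigid <- ncol(Q)
  eg <- eigen(H, symmetric = TRUE)
  lam <- rev(eg$values); vec <- eg$vectors[, rev(seq_along(eg$values))]
  lmax <- max(abs(lam))
  gap_ok <- length(lam) > n_rigid &&
    lam[n_rigid + 1L] > 1e6 * max(abs(lam[n_rigid]), lmax * 1e-300)
  if (!gap_ok) {
    ## near-degenerate: remove the rigid subspace explicitly
    P <- diag(3L * M) - tcrossprod(Q)
    eg <- eigen(P %*% H %*% P, symmetric = TRUE)
    lam <- rev(eg$values); vec <- eg$vectors[, rev(seq_along(eg$values))]
    lmax <- max(abs(lam))
  }
  near_zero <- sum(abs(lam) <= lmax * 1e-8)
  if (near_zero > n_rigid) {
    comp <- .connected_components(network)
    stop_elevator("connectivity",
                  "%d near-zero modes (expected %d): network has %d connected component(s)",
                  near_zero, n_rigid, comp)
  }
  keep <- seq.int(n_rigid + 1L, length(lam))
  if (!is.null(n_modes)) keep <- keep[seq_len(min(n_modes, length(keep)))]
  structure(list(values = lam[keep],
                 vectors = vec[, keep, drop = FALSE],
                 n_rigid_removed = n_rigid, n_nodes = M),
            class = "ModeSet")
}

.connected_components <- function(network) {
  M <- nrow(network$xyz)
  parent <- seq_len(M)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (r in seq_len(nrow(network$edges))) {
    a <- find(network$edges$i[r]); b <- find(network$edges$j[r])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(M), find, 0L)))
}

#' @export
print.ModeSet <- function(x, ...) {
  cat(sprintf("<ModeSet> %d internal modes over %d nodes (%d rigid removed)\n",
              length(x$values), x$n_nodes, x$n_rigid_removed))
  invisible(x)
}

#' Per-residue thermal fluctuations and hinge regions
#'
#' Mean-square fluctuation of residue i from the lowest K modes,
#' MSF_i = scale * sum_m |v_mi|^2 / lambda_m (relative units unless a
#' physical kT scale is supplied). Hinges are local minima of the
#' smoothed profile below a percentile threshold; rigid hinge minima
#' localize the pivots of elevator-like motions.
#'
#' @param modes a `ModeSet`.
#' @param K number of modes to sum (default 20, capped at available).
#' @param scale multiplicative temperature scale (default 1: relative).
#' @param smooth_window residue window for hinge smoothing (default 5).
#' @param hinge_percentile percentile threshold below which minima are
#'   flagged (default 25).
#' @return Object of class `FluctuationProfile`: data frame `profile`
#'   with msf and hinge flag per residue.
#' @export
residue_fluctuations <- function(modes, K = 20L, scale = 1,
                                 smooth_window = 5L, hinge_percentile = 25) {
  if (K < 1L) stop_elevator("validation", "K must be >= 1")
  K <- min(K, length(modes$values))
  M <- modes$n_nodes
  msf <- numeric(M)
  for (m in seq_len(K)) {
    v <- matrix(modes$vectors[, m], ncol = 3L, byrow = TRUE)
    msf <- msf + rowSums(v^2) / modes$values[m]
  }
  msf <- scale * msf
  sm <- .running_mean(msf, smooth_window)
  thr <- quantile(sm, hinge_percentile / 100)
  hinge <- vapply(seq_len(M), function(i) {
    lo <- max(1L, i - 1L); hi <- min(M, i + 1L)
    sm[i] <= min(sm[lo:hi]) && sm[i] <= thr
  }, TRUE)
  structure(list(profile = data.frame(residue = seq_len(M), msf = msf,
                                      smoothed = sm, hinge = hinge),
                 K = K), class = "FluctuationProfile")
}

.running_mean <- function(x, w) {
  h <- (w - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h):min(n, i + h)]), 0)
}

#' Overlap of a mode with a transition vector
#'
#' The involvement of unit mode v in conformational change d:
#' overlap = |v . d| / ||d||, in `[0, 1]`.
#'
#' @param v 3M unit vector (or a column index into a `ModeSet`).
#' @param d 3M displacement vector (nonzero).
#' @return scalar overlap.
#' @export
mode_overlap <- function(v, d) {
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop_elevator("validation", "transition vector is zero")
  abs(sum(v * d)) / nd
}

#' Cumulative overlap of a mode subset with a transition vector
#'
#' Root-sum-square of individual overlaps; bounded by 1 (Bessel) and
#' equal to 1 over a complete basis (Parseval).
#'
#' @param modes a `ModeSet` (or 3M x n matrix of orthonormal columns).
#' @param d 3M displacement vector.
#' @param subset mode indices (default all).
#' @return scalar cumulative overlap in `[0, 1]`.
#' @export
cumulative_overlap <- function(modes, d, subset = NULL) {
  V <- if (inherits(modes, "ModeSet")) modes$vectors else modes
  if (is.null(subset)) subset <- seq_len(ncol(V))
  ov <- vapply(subset, function(m) mode_overlap(V[, m], d), 0)
  sqrt(sum(ov^2))
}

#' Overlap table of every mode with a transition vector
#'
#' @inheritParams cumulative_overlap
#' @return data frame: mode index, eigenvalue, overlap, cumulative overlap.
#' @export
overlap_table <- function(modes, d) {
  ov <- vapply(seq_len(ncol(modes$vectors)), function(m)
    mode_overlap(modes$vectors[, m], d), 0)
  data.frame(mode = seq_along(ov), value = modes$values, overlap = ov,
             cumulative = sqrt(cumsum(ov^2)))
}
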