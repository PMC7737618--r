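## Transition pathways by iterative elastic-network normal-mode analysis,
## with coverage and elevator-shift metrics quantifying progress along the
## inward/outward conformational axis.

#' Generate a transition pathway by iterative ENM-NMA
#'
#' Starting from one conformation, normal modes are computed at the
#' current frame, the modes of highest overlap with the remaining
#' direction (difference to the target, or an explicit axis) are
#' combined weighted by their overlaps, the structure is displaced by a
#' fixed rms step along that combination, and local geometry is
#' re-idealized by restoring the successive C-alpha distances of the
#' start structure (one pass, N- to C-terminal, within each chain).
#' Iteration stops at a target coverage, a maximum iteration count, or a
#' stall (best overlap below `overlap_floor`). The generator is fully
#' deterministic.
#'
#' @param start a [calpha_model()].
#' @param target a [calpha_model()] sharing `start`'s residue set, or
#'   `NULL` when driving along an explicit `axis`.
#' @param axis optional 3M unit vector (e.g. PC1 of a [covariance_pca()]
#'   basis) used to monitor projections (and to drive when no target).
#' @param params [enm_params()] for the per-frame networks.
#' @param step_rmsd rms displacement per step (A).
#' @param mode_pool number of lowest internal modes considered.
#' @param modes_per_step number of highest-overlap modes combined.
#' @param stop_coverage stop when coverage reaches this fraction
#'   (target mode only).
#' @param max_iter maximum iterations.
#' @param target_projection stop threshold on the axis projection
#'   (axis mode only).
#' @param overlap_floor stall threshold on the best single-mode overlap.
#' @param refresh_modes recompute modes every step (self-consistent ENM);
#'   `FALSE` freezes the initial mode set.
#' @param reidealize restore successive C-alpha distances after each step.
#' @return Object of class `TransitionPath`: `frames` (list of models,
#'   frame 1 = start), `log` (iteration, projection, rmsd to target,
#'   coverage, best overlap, step amplitude), and the stop reason.
#' @export
generate_pathway <- function(start, target = NULL, axis = NULL,
                             params = enm_params(), step_rmsd = 0.5,
                             mode_pool = 20L, modes_per_step = 3L,
                             stop_coverage = 0.98, max_iter = 100L,
                             target_projection = NULL,
                             overlap_floor = 0.05,
                             refresh_modes = TRUE, reidealize = TRUE) {
  if (is.null(target) && is.null(axis))
    stop_elevator("validation", "need a target structure or an axis")
  x0 <- flatten_xyz(start$xyz)
  M <- n_residues(start)
  xt <- if (!is.null(target)) {
    if (n_residues(target) != M)
      stop_elevator("consistency", "target size differs from start")
    flatten_xyz(target$xyz)
  }
  pc1 <- if (!is.null(axis)) unit_vector(as.numeric(axis))
         else unit_vector(xt - x0)
  p_target <- if (!is.null(target)) sum((xt - x0) * pc1) else target_projection
  frames <- list(start)
  x <- x0
  modes <- NULL
  log <- data.frame()
  stop_reason <- "max_iter"
  ## reference bond lengths per chain for re-idealization
  ch <- start$residues$chain
  succ <- which(ch[-1] == ch[-M])          # bonds (i, i+1) within a chain
  bond0 <- sqrt(rowSums((start$xyz[succ + 1L, , drop = FALSE] -
                         start$xyz[succ, , drop = FALSE])^2))
  for (it in seq_len(max_iter)) {
    if (!is.null(target)) {
      ## keep the evolving frame rigid-minimal w.r.t. the target, so the
      ## remaining difference is expressible by internal modes
      cur <- kabsch_superpose(calpha_model(start$residues, unflatten_xyz(x)),
                              target)$model
      x <- flatten_xyz(cur$xyz)
      remaining <- xt - x
    } else remaining <- pc1
    ## internal modes cannot carry rigid-body content: remove it
    Q <- rigid_body_basis(unflatten_xyz(x))
    remaining <- remaining - Q %*% crossprod(Q, remaining)
    remaining <- as.numeric(remaining)
    rem_norm <- sqrt(sum(remaining^2))
    if (rem_norm < 1e-8) { stop_reason <- "converged"; break }
    if (is.null(modes) || refresh_modes) {
      net <- build_network(calpha_model(start$residues, unflatten_xyz(x)),
                           params)
      modes <- compute_modes(net, n_modes = mode_pool)
    }
    ov <- vapply(seq_len(ncol(modes$vectors)), function(m)
      mode_overlap(modes$vectors[, m], remaining), 0)
    if (max(ov) < overlap_floor) { stop_reason <- "stall"; break }
    sel <- order(ov, decreasing = TRUE)[seq_len(min(modes_per_step, length(ov)))]
    ## overlap-weighted combination = projection of the remaining
    ## direction onto the selected mode subspace
    dvec <- drop(modes$vectors[, sel, drop = FALSE] %*%
                   crossprod(modes$vectors[, sel, drop = FALSE], remaining))
    dn <- sqrt(sum(dvec^2))
    if (dn < 1e-12) { stop_reason <- "stall"; break }
    amp <- min(step_rmsd, rem_norm / sqrt(M)) * sqrt(M) / dn
    x_new <- x + amp * dvec
    check_finite(x_new, "pathway coordinates")
    if (reidealize) x_new <- .restore_bonds(x_new, succ, bond0)
    x <- x_new
    frame <- calpha_model(start$residues, unflatten_xyz(x))
    frames[[length(frames) + 1L]] <- frame
    proj <- sum((x - x0) * pc1)
    cov <- if (!is.null(p_target) && p_target != 0) proj / p_target else NA_real_
    log <- rbind(log, data.frame(
      iteration = it, projection = proj,
      rmsd_to_target = if (!is.null(target))
        .rmsd(unflatten_xyz(x), unflatten_xyz(xt)) else NA_real_,
      coverage = cov, best_overlap = max(ov),
      modes = paste(sel, collapse = "+"),
      amplitude = amp * dn / sqrt(M)))
    if (!is.null(p_target) && !is.na(cov) && cov >= stop_coverage) {
      stop_reason <- "coverage"; break
    }
  }
  structure(list(frames = frames, log = log, stop_reason = stop_reason,
                 axis = pc1, start = start, target = target),
            class = "TransitionPath")
}

## One N->C pass restoring successive C-alpha virtual-bond lengths to the
## start structure's values (keeps the chain physical at CA resolution).
.restore_bonds <- function(xflat, succ, bond0) {
  X <- unflatten_xyz(xflat)
  for (b in seq_along(succ)) {
    i <- succ[b]
    d <- X[i + 1L, ] - X[i, ]
    dn <- sqrt(sum(d^2))
    if (dn > 0) X[i + 1L, ] <- X[i, ] + d * (bond0[b] / dn)
  }
  flatten_xyz(X)
}

#' @export
print.TransitionPath <- function(x, ...) {
  cat(sprintf("<TransitionPath> %d frames (stop: %s)\n",
              length(x$frames), x$stop_reason))
  if (nrow(x$log))
    cat(sprintf("  final projection %.2f A, coverage %.3f\n",
                tail(x$log$projection, 1), tail(x$log$coverage, 1)))
  invisible(x)
}

#' Coverage of a conformational transition
#'
#' Primary definition: ratio of PC1 projections, p(model) / p(target),
#' both taken with the start structure as origin. The alternative
#' rmsd-based definition 1 - rmsd(model, target) / rmsd(start, target)
#' is selectable because the achieved-transition fraction is otherwise
#' convention-dependent.
#'
#' @param model,start,target [calpha_model()]s in a common frame.
#' @param basis optional `PCABasis` supplying PC1 (default: the
#'   normalized start-to-target difference).
#' @param method `"projection"` or `"rmsd"`.
#' @return coverage fraction (0 at start, 1 at target).
#' @export
coverage <- function(model, start, target, basis = NULL,
                     method = c("projection", "rmsd")) {
  method <- match.arg(method)
  if (.rmsd(start$xyz, target$xyz) == 0)
    stop_elevator("validation", "start equals target")
  if (method == "rmsd")
    return(1 - .rmsd(model$xyz, target$xyz) / .rmsd(start$xyz, target$xyz))
  x0 <- flatten_xyz(start$xyz)
  pc1 <- if (!is.null(basis)) basis$vectors[1, ]
         else unit_vector(flatten_xyz(target$xyz) - x0)
  pt <- sum((flatten_xyz(target$xyz) - x0) * pc1)
  if (abs(pt) < 1e-12)
    stop_elevator("validation", "target has zero projection on the axis")
  sum((flatten_xyz(model$xyz) - x0) * pc1) / pt
}

#' Elevator shift between two conformations
#'
#' Superposes state B onto state A over the scaffold (dimerization
#' domain), then decomposes the displacement of the binding-site
#' C-alpha centroid into its component along the membrane normal (the
#' elevator shift) and the in-plane remainder. Because the membrane
#' normal is a laboratory-frame vector, an optional `frame` structure
#' re-anchors A (and with it the whole comparison) to the frame in which
#' the normal was defined, making the metric invariant under joint rigid
#' transforms of both inputs.
#'
#' @param model_a,model_b [calpha_model()]s sharing a residue set.
#' @param domains a [domain_definition()] with `dimer_domain` and a
#'   binding site.
#' @param frame optional [calpha_model()] defining the reference frame.
#' @return Object of class `ElevatorMetrics`: `shift` (A, >= 0),
#'   `in_plane` (A), `displacement` (3-vector), scaffold rmsd.
#' @export
elevator_shift <- function(model_a, model_b, domains, frame = NULL) {
  if (is.null(domains$binding_site) || nrow(domains$binding_site) == 0L)
    stop_elevator("validation", "binding_site is empty")
  if (!is.null(frame)) {
    fmask <- domain_mask(frame, domains, "dimer_domain")
    model_a <- kabsch_superpose(model_a, frame, fmask)$model
  }
  mask <- domain_mask(model_a, domains, "dimer_domain")
  fit <- kabsch_superpose(model_b, model_a, mask)
  bmask <- domain_mask(model_a, domains, "binding_site")
  ca <- colMeans(model_a$xyz[bmask, , drop = FALSE])
  cb <- colMeans(fit$model$xyz[bmask, , drop = FALSE])
  delta <- cb - ca
  n <- domains$membrane_normal
  along <- sum(delta * n)
  in_plane <- delta - along * n
  structure(list(shift = abs(along), in_plane = sqrt(sum(in_plane^2)),
                 displacement = delta, scaffold_rmsd = fit$rmsd_mask),
            class = "ElevatorMetrics")
}

#' @export
print.ElevatorMetrics <- function(x, ...) {
  cat(sprintf("<ElevatorMetrics> shift %.2f A along normal, %.2f A in-plane (scaffold rmsd %.2f A)\n",
              x$shift, x$in_plane, x$scaffold_rmsd))
  invisible(x)
}

#' Write a pathway step log as CSV
#' @param path a `TransitionPath`.
#' @param file output CSV path.
#' @export
write_pathway_log <- function(path, file) {
  write.csv(path$log, file, row.names = FALSE)
  invisible(file)
}
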