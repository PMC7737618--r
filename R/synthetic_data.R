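## Synthetic-data generators with known ground truth: two-state elevator
## C-alpha architectures, noisy structural ensembles, ion trajectories at a
## stated bulk concentration with a controllable bound fraction, dose-
## response kinetics, and sigmoidal melting curves. All generators are
## pure functions of (spec, seed); global RNG state is never touched.

#' Toy elevator specification
#'
#' Geometry of a minimal two-state elevator transporter: a fixed
#' scaffold bundle (standing in for the dimerization domain) and a
#' compact core bundle that is rigidly translated along the membrane
#' normal (+z) and optionally rotated about it in the second state.
#' Helices use canonical alpha-helical parameters (rise 1.5 A/residue,
#' radius 2.3 A, ~3.6 residues/turn), giving successive C-alpha
#' distances near 3.8 A within each helix.
#'
#' @param n_scaffold,n_core residue counts (>= 10 each).
#' @param shift elevator displacement d (A) of the core along +z in state B.
#' @param rotation rotation (degrees) of the core about +z in state B.
#' @param binding_site indices into the core (1-based) defining the
#'   ion-binding site.
#' @param separation distance (A) between the interface helix columns of
#'   the scaffold and core bundles.
#' @return Object of class `ToyElevatorSpec`.
#' @export
toy_elevator_spec <- function(n_scaffold = 60L, n_core = 40L, shift = 5,
                              rotation = 0, binding_site = NULL,
                              separation = 14) {
  if (n_scaffold < 10L || n_core < 10L)
    stop_elevator("validation", "scaffold and core need >= 10 residues each")
  if (shift < 0) stop_elevator("validation", "shift must be >= 0")
  if (is.null(binding_site))
    binding_site <- unique(pmax(1L, round(n_core / 2) + (-1L:1L)))
  structure(list(n_scaffold = as.integer(n_scaffold),
                 n_core = as.integer(n_core), shift = shift,
                 rotation = rotation, binding_site = as.integer(binding_site),
                 separation = separation),
            class = "ToyElevatorSpec")
}

## Ideal alpha-helix C-alpha trace along +z.
.helix <- function(n, rise = 1.5, radius = 2.3, per_turn = 3.6,
                   origin = c(0, 0, 0)) {
  i <- seq_len(n) - 1L
  th <- 2 * pi * i / per_turn
  cbind(origin[1] + radius * cos(th),
        origin[2] + radius * sin(th),
        origin[3] + rise * i)
}

## Antiparallel helix bundle of ~helix_len-residue helices, mirror-
## symmetric about the y = 0 plane (so shear modes of different symmetry
## do not mix), growing away from the inter-domain interface along
## `away` (+1 or -1 in x).
.bundle <- function(n, x0, away, helix_len = 20L, dx = 5, dy = 4.3) {
  offs <- list(c(0, -dy / 2), c(0, dy / 2), c(away * dx, 0),
               c(away * dx, -dy), c(away * dx, dy), c(2 * away * dx, 0))
  out <- NULL
  left <- n
  h <- 0L
  while (left > 0L) {
    h <- h + 1L
    nn <- min(helix_len, left)
    left <- left - nn
    o <- offs[[(h - 1L) %% length(offs) + 1L]]
    H <- .helix(nn, origin = c(x0 + o[1], o[2], 0))
    if (h %% 2L == 0L) H[, 3] <- max(H[, 3]) + min(H[, 3]) - H[, 3]
    out <- rbind(out, H)
  }
  out
}

#' Generate a two-state toy elevator
#'
#' State B equals state A with the core domain rigid-body moved (d along
#' the membrane normal, theta about it); the scaffold is identical in
#' both. The returned domain definition labels the scaffold as
#' `dimer_domain`, the core as `core_domain`, and the chosen core
#' residues as the binding site.
#'
#' @param spec a [toy_elevator_spec()].
#' @return List with `state_a`, `state_b` ([calpha_model()]s, chains A =
#'   scaffold / B = core) and `domains` (a [domain_definition()]).
#' @export
make_toy_elevator <- function(spec = toy_elevator_spec()) {
  ## compact antiparallel bundles: internally stiff domains joined by a
  ## sparse spring interface, so relative domain sliding is a soft mode
  scaf <- .bundle(spec$n_scaffold, 0, away = -1L)
  core <- .bundle(spec$n_core, spec$separation, away = +1L)
  residues <- data.frame(
    chain = rep(c("A", "B"), c(spec$n_scaffold, spec$n_core)),
    resno = c(seq_len(spec$n_scaffold), seq_len(spec$n_core)),
    resname = "ALA", stringsAsFactors = FALSE)
  state_a <- calpha_model(residues, rbind(scaf, core))
  axis_pt <- colMeans(core)   # rotate about the core's own axis
  R <- rotation_about_axis(c(0, 0, 1), spec$rotation)
  core_b <- sweep(sweep(core, 2, axis_pt) %*% t(R), 2, axis_pt, `+`)
  core_b[, 3] <- core_b[, 3] + spec$shift
  state_b <- calpha_model(residues, rbind(scaf, core_b))
  domains <- domain_definition(
    list(dimer_domain = data.frame(chain = "A", resno = seq_len(spec$n_scaffold)),
         core_domain = data.frame(chain = "B", resno = seq_len(spec$n_core))),
    binding_site = data.frame(chain = "B", resno = spec$binding_site),
    membrane_normal = c(0, 0, 1))
  list(state_a = state_a, state_b = state_b, domains = domains, spec = spec)
}

#' Generate a noisy structural ensemble from discrete states
#'
#' Each member is one of the input states plus isotropic Gaussian
#' coordinate noise; the correspondence is the identity (all states share
#' a residue set). Reproducible by seed.
#'
#' @param states list of [calpha_model()] objects sharing one residue set.
#' @param n_per_state members drawn per state (recycled).
#' @param sigma noise s.d. per Cartesian coordinate (A).
#' @param seed integer seed.
#' @return List with `models` (named list; ids `<state>_<replicate>`),
#'   `correspondence` (a `CorrespondenceTable`), and `state_of` (named
#'   character vector mapping member id to source state).
#' @export
make_ensemble <- function(states, n_per_state = 4L, sigma = 0.2, seed = 1L) {
  if (sigma < 0) stop_elevator("validation", "sigma must be >= 0")
  if (is.null(names(states)))
    names(states) <- paste0("state", seq_along(states))
  n_per_state <- rep_len(n_per_state, length(states))
  with_seed(seed, {
    models <- list(); state_of <- character()
    for (s in seq_along(states)) {
      st <- states[[s]]
      for (r in seq_len(n_per_state[s])) {
        id <- sprintf("%s_%d", names(states)[s], r)
        noise <- matrix(rnorm(length(st$xyz), sd = sigma), ncol = 3L)
        models[[id]] <- calpha_model(st$residues, st$xyz + noise)
        state_of[id] <- names(states)[s]
      }
    }
    res <- states[[1]]$residues
    entries <- rep(list(data.frame(chain = res$chain, resno = res$resno,
                                   stringsAsFactors = FALSE)),
                   length(models))
    names(entries) <- names(models)
    corr <- structure(list(ids = names(models), entries = entries),
                      class = "CorrespondenceTable")
    list(models = models, correspondence = corr, state_of = state_of)
  })
}

#' Generate a synthetic ion trajectory
#'
#' Ideal-gas ions uniform in an orthorhombic periodic box at a stated
#' bulk concentration (ion count = round(c * N_A * V)); one designated
#' ion is placed within the binding threshold of the site in a `phi`
#' fraction of frames, in contiguous blocks so that event segmentation is
#' exercised.
#'
#' @param concentration_mM bulk concentration (mM), > 0.
#' @param box length-3 box vector (A).
#' @param n_frames number of frames.
#' @param site matrix of site-atom coordinates (rows; A), or `NULL` for
#'   the box centre.
#' @param phi bound fraction in `[0, 1]`.
#' @param threshold binding distance criterion (A; bound placements are
#'   drawn inside 0.8 * threshold of a site atom).
#' @param seed integer seed.
#' @return Object of class `IonTrajectory`: `ions` (T x N x 3 array),
#'   `sites` (S x 3), `box`, `bound_ion` (index of the designated ion)
#'   and metadata.
#' @export
make_ion_traj <- function(concentration_mM = 150, box = c(100, 100, 100),
                          n_frames = 500L, site = NULL, phi = 0,
                          threshold = 3, seed = 1L) {
  if (concentration_mM <= 0)
    stop_elevator("validation", "concentration must be > 0")
  if (phi < 0 || phi > 1) stop_elevator("validation", "phi must be in [0,1]")
  V <- prod(box)                                   # A^3
  n_ions <- round(concentration_mM / 1000 * AVOGADRO * V * 1e-27)
  if (n_ions == 0L)
    stop_elevator("validation",
                  "concentration %.3g mM in a %.0f A^3 box gives 0 ions; use a larger box",
                  concentration_mM, V)
  if (is.null(site)) site <- matrix(box / 2, nrow = 1L)
  site <- as.matrix(site)
  with_seed(seed, {
    ions <- array(runif(n_frames * n_ions * 3L), dim = c(n_frames, n_ions, 3L))
    for (d in 1:3) ions[, , d] <- ions[, , d] * box[d]
    n_bound <- round(phi * n_frames)
    bound_frames <- integer(0)
    if (n_bound > 0L) {
      ## contiguous blocks: split the bound frames into two runs when long
      ## enough, placed deterministically within the trajectory
      if (n_bound >= 4L && n_bound < n_frames) {
        l1 <- ceiling(n_bound / 2); l2 <- n_bound - l1
        s1 <- 1L
        s2 <- min(n_frames - l2 + 1L, s1 + l1 + max(1L, (n_frames - n_bound) %/% 2L))
        bound_frames <- c(seq.int(s1, length.out = l1),
                          seq.int(s2, length.out = l2))
      } else bound_frames <- seq_len(n_bound)
      for (f in bound_frames) {
        a <- site[sample.int(nrow(site), 1L), ]
        repeat {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          r <- 0.8 * threshold * runif(1)^(1 / 3)
          p <- a + r * u
          if (all(p >= 0 & p < box)) break
        }
        ions[f, 1L, ] <- p
      }
      ## ensure the designated ion is away from the site in unbound frames
      for (f in setdiff(seq_len(n_frames), bound_frames)) {
        while (min(sqrt(colSums((t(site) - ions[f, 1L, ])^2))) <= threshold) {
          ions[f, 1L, ] <- runif(3) * box
        }
      }
    }
    structure(list(ions = ions, sites = site, box = as.numeric(box),
                   bound_ion = 1L, bound_frames = sort(bound_frames),
                   concentration_mM = concentration_mM, seed = seed),
              class = "IonTrajectory")
  })
}

#' @export
print.IonTrajectory <- function(x, ...) {
  cat(sprintf("<IonTrajectory> %d frames x %d ions, box %s A\n",
              dim(x$ions)[1], dim(x$ions)[2],
              paste(x$box, collapse = " x ")))
  invisible(x)
}

#' Generate Michaelis-Menten dose-response replicates
#'
#' v = V_max * S / (K_M + S) with multiplicative Gaussian noise.
#'
#' @param km,vmax ground-truth parameters (K_M in mM).
#' @param concentrations substrate concentrations (mM).
#' @param noise fractional noise s.d. (e.g. 0.05 for 5 percent).
#' @param replicates replicate count.
#' @param seed integer seed.
#' @return List with `concentrations` and `responses` (length(conc) x
#'   replicates matrix).
#' @export
make_kinetics <- function(km = 20.5, vmax = 100,
                          concentrations = c(2.5, 5, 10, 20, 40, 80, 160),
                          noise = 0.05, replicates = 3L, seed = 1L) {
  if (km <= 0 || vmax <= 0) stop_elevator("validation", "km, vmax must be > 0")
  v <- vmax * concentrations / (km + concentrations)
  with_seed(seed, {
    eps <- matrix(rnorm(length(v) * replicates, mean = 1, sd = noise),
                  nrow = length(v))
    list(concentrations = concentrations, responses = v * eps)
  })
}

#' Generate a sigmoidal melting curve
#'
#' Four-parameter logistic y = d + (a - d) / (1 + (T / T_m)^b) with
#' additive Gaussian noise scaled to the plateau span; `a` is the
#' low-temperature plateau.
#'
#' @param tm melting temperature (degrees C).
#' @param slope Hill-type slope b (> 0 for a decreasing melt).
#' @param plateaus length-2 vector c(low-T plateau, high-T plateau).
#' @param temperatures measurement temperatures (degrees C).
#' @param noise fractional noise s.d.
#' @param seed integer seed.
#' @return data frame with `temp_C` and `signal`.
#' @export
make_melt <- function(tm = 52, slope = 14, plateaus = c(100, 0),
                      temperatures = seq(25, 90, by = 2.5),
                      noise = 0.02, seed = 1L) {
  if (tm <= 0) stop_elevator("validation", "tm must be > 0")
  y <- plateaus[2] + (plateaus[1] - plateaus[2]) /
    (1 + (temperatures / tm)^slope)
  with_seed(seed, {
    eps <- rnorm(length(y), mean = 0, sd = noise * max(abs(plateaus)))
    data.frame(temp_C = temperatures, signal = y + eps)
  })
}
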