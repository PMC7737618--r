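## Solvent-accessible surface areas (Shrake-Rupley), buried interface
## areas between structural groups, and conservation-filtered inter-domain
## contact / hydrophobic-gate analysis.

## van der Waals radii (A). PISA's exact parameterization is not public;
## comparisons against its reported areas carry a +/-15% tolerance.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

#' Default hydrophobic residue set
#' @export
HYDROPHOBIC_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE",
                          "TRP", "PRO")

## Deterministic golden-section spiral on the unit sphere.
sphere_points <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolling-probe SASA by the sphere-point method with a fixed
#' deterministic spiral point set.
#'
#' @param model an [atom_model()] (or a data frame of atoms).
#' @param probe probe radius (A), default 1.4 (water).
#' @param n_points sample points per atom, default 960.
#' @param radii named vdW radius table by element; defaults to the
#'   built-in table (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20 A).
#' @return Object of class `SasaResult`: `atom_area` (A^2 per atom),
#'   `residue_area` (per residue), `total`.
#' @export
sasa <- function(model, probe = 1.4, n_points = 960L, radii = VDW_RADII) {
  at <- if (inherits(model, "AtomModel")) model$atoms else model
  el <- toupper(trimws(at$element))
  r <- radii[el]
  if (anyNA(r)) {
    bad <- unique(el[is.na(r)])
    stop_elevator("unknown_element",
                  "no vdW radius for element(s): %s (supply via `radii`)",
                  paste(bad, collapse = ", "))
  }
  X <- cbind(at$x, at$y, at$z)
  n <- nrow(X)
  R <- unname(r) + probe
  pts <- sphere_points(n_points)
  ## neighbor lists from one pairwise distance matrix (models here are
  ## small; interfaces of a few thousand atoms remain tractable)
  D2 <- as.matrix(dist(X))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(D2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    p <- sweep(pts * R[i], 2, X[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- (p[, 1] - X[j, 1])^2 + (p[, 2] - X[j, 2])^2 + (p[, 3] - X[j, 3])^2
      exposed <- exposed & d2 > R[j]^2
      if (!any(exposed)) break
    }
    area[i] <- 4 * pi * R[i]^2 * sum(exposed) / n_points
  }
  rkey <- paste(at$chain, at$resno, if (!is.null(at$ins)) at$ins else "")
  residue_area <- tapply(area, factor(rkey, levels = unique(rkey)), sum)
  structure(list(atom_area = area, residue_area = residue_area,
                 total = sum(area), probe = probe, n_points = n_points),
            class = "SasaResult")
}

#' Buried (interface) surface area between two residue groups
#'
#' BSA = (SASA(A alone) + SASA(B alone) - SASA(A and B together)) / 2,
#' the interface-area convention reported by PISA; set
#' `convention = "total"` for the unhalved total buried area.
#'
#' @param model an [atom_model()].
#' @param group_a,group_b disjoint residue sets: data frames with
#'   `chain`, `resno` columns (or character vectors of chain ids).
#' @param convention `"interface"` (half-sum, default) or `"total"`.
#' @inheritParams sasa
#' @return buried area in A^2.
#' @export
buried_area <- function(model, group_a, group_b,
                        convention = c("interface", "total"),
                        probe = 1.4, n_points = 960L, radii = VDW_RADII) {
  convention <- match.arg(convention)
  at <- model$atoms
  sel <- function(g) {
    if (is.character(g)) return(at$chain %in% g)
    paste(at$chain, at$resno) %in% paste(g$chain, g$resno)
  }
  a <- sel(group_a); b <- sel(group_b)
  if (any(a & b))
    stop_elevator("validation", "groups overlap (%d shared atoms)", sum(a & b))
  if (!any(a) || !any(b))
    stop_elevator("empty_selection", "a group selects no atoms")
  s <- function(mask) sasa(at[mask, , drop = FALSE], probe, n_points, radii)$total
  bsa <- s(a) + s(b) - s(a | b)
  if (convention == "interface") bsa / 2 else bsa
}

#' Conservation-filtered inter-domain contact network
#'
#' Edges join residues of the core and dimerization domains whose minimum
#' heavy-atom distance is within the cutoff and whose conservation grades
#' (ConSurf-style, 1 variable - 9 conserved) both reach the floor.
#' Residues missing from the conservation table get grade 0 and are
#' excluded.
#'
#' @param model an [atom_model()].
#' @param domains a [domain_definition()] with `core_domain` and
#'   `dimer_domain`.
#' @param conservation data frame `chain`, `resno`, `grade` (or a CSV
#'   path).
#' @param cutoff heavy-atom distance cutoff (A), default 4.5.
#' @param min_grade conservation floor, default 8.
#' @return Object of class `ContactNetwork`: `edges` (residue pair, min
#'   distance, domain pair), `residues` (annotations incl. grade,
#'   hydrophobicity, position along the membrane normal), and the
#'   binding-site centroid coordinate along the normal (if defined).
#' @export
interdomain_contacts <- function(model, domains, conservation,
                                 cutoff = 4.5, min_grade = 8) {
  if (is.character(conservation)) conservation <- read.csv(conservation)
  if (!all(c("chain", "resno", "grade") %in% names(conservation)))
    stop_elevator("schema", "conservation table needs chain, resno, grade")
  at <- model$atoms
  heavy <- at[toupper(trimws(at$element)) != "H", , drop = FALSE]
  rkey <- paste(heavy$chain, heavy$resno)
  grade_of <- function(keys) {
    g <- conservation$grade[match(keys, paste(conservation$chain,
                                              conservation$resno))]
    ifelse(is.na(g), 0, g)
  }
  pick <- function(name) {
    d <- domains$domains[[name]]
    if (is.null(d)) stop_elevator("validation", "domain '%s' missing", name)
    keys <- unique(rkey[rkey %in% paste(d$chain, d$resno)])
    keys[grade_of(keys) >= min_grade]
  }
  core_keys <- pick("core_domain")
  dimer_keys <- pick("dimer_domain")
  n <- domains$membrane_normal
  edges <- data.frame(residue_a = character(0), residue_b = character(0),
                      distance = numeric(0), pair = character(0))
  for (ck in core_keys) {
    A <- as.matrix(heavy[rkey == ck, c("x", "y", "z")])
    for (dk in dimer_keys) {
      B <- as.matrix(heavy[rkey == dk, c("x", "y", "z")])
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
      dmin <- sqrt(max(0, min(d2)))
      if (dmin <= cutoff)
        edges <- rbind(edges, data.frame(
          residue_a = ck, residue_b = dk, distance = dmin,
          pair = "core_domain:dimer_domain"))
    }
  }
  involved <- unique(c(edges$residue_a, edges$residue_b))
  resinfo <- unique(data.frame(key = rkey, resname = heavy$resname,
                               stringsAsFactors = FALSE))
  annot <- data.frame(key = c(core_keys, dimer_keys))
  annot$domain <- rep(c("core_domain", "dimer_domain"),
                      c(length(core_keys), length(dimer_keys)))
  annot$resname <- resinfo$resname[match(annot$key, resinfo$key)]
  annot$grade <- grade_of(annot$key)
  annot$hydrophobic <- annot$resname %in% HYDROPHOBIC_RESIDUES
  annot$normal_coord <- vapply(annot$key, function(k) {
    xyz <- as.matrix(heavy[rkey == k, c("x", "y", "z")])
    sum(colMeans(xyz) * n)
  }, 0)
  site_coord <- if (!is.null(domains$binding_site)) {
    bs <- paste(domains$binding_site$chain, domains$binding_site$resno)
    m <- rkey %in% bs
    if (any(m)) sum(colMeans(as.matrix(heavy[m, c("x", "y", "z")])) * n)
    else NA_real_
  } else NA_real_
  structure(list(edges = edges, residues = annot, cutoff = cutoff,
                 min_grade = min_grade, site_normal_coord = site_coord),
            class = "ContactNetwork")
}

#' Hydrophobic gate residues of a contact network
#'
#' Residues participating in at least one inter-domain contact whose
#' residue type is hydrophobic, grouped by their position along the
#' membrane normal relative to the binding-site centroid ("above" the
#' site = extracellular side, "below" = intracellular side).
#'
#' @param network a [interdomain_contacts()] result.
#' @param hydrophobic residue-name set, default
#'   [HYDROPHOBIC_RESIDUES].
#' @return data frame of gate residues with domain, grade and side.
#' @export
gate_residues <- function(network, hydrophobic = HYDROPHOBIC_RESIDUES) {
  involved <- unique(c(network$edges$residue_a, network$edges$residue_b))
  res <- network$residues
  gates <- res[res$key %in% involved & res$resname %in% hydrophobic, ,
               drop = FALSE]
  if (nrow(gates) == 0L) {
    gates$side <- character(0)
    rownames(gates) <- NULL
    return(gates)
  }
  gates$side <- if (is.na(network$site_normal_coord)) NA_character_ else
    ifelse(gates$normal_coord >= network$site_normal_coord,
           "extracellular", "intracellular")
  rownames(gates) <- NULL
  gates
}
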