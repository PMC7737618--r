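## End-to-end analysis runner: from deposited (or synthetic) structures,
## a residue correspondence and a domain definition to the headline
## elevator metrics — ensemble fit statistics, PC1 variance fraction,
## ENM pathway coverage, elevator shift, and interface areas.

#' Run the full elevator analysis on a structure set
#'
#' Composes the pipeline stages: read structures, extract C-alpha
#' traces, build the superposed matched-residue ensemble (fit over the
#' reference's dimerization domain), covariance PCA, iterative ENM
#' pathway from the reference toward an outward-state member, elevator
#' shift of the binding site, and core/dimer buried interface area of
#' the reference.
#'
#' @param structures named character vector of structure file paths
#'   (names are structure ids) or a named list of [calpha_model()]s.
#' @param correspondence a `CorrespondenceTable`, a TSV path, or `NULL`
#'   (identity).
#' @param domains a [domain_definition()] or YAML path, defined on the
#'   reference structure's numbering.
#' @param reference_id projection origin (the inward structure).
#' @param outward_id ensemble member defining the outward state.
#' @param calibrate_id structure given a positive PC1 sign (default
#'   `outward_id`).
#' @param enm [enm_params()] for pathway generation.
#' @param bsa_model optional [atom_model()] of the reference for the
#'   interface-area step (skipped when `NULL`).
#' @param ... further arguments passed to [generate_pathway()].
#' @return list with the ensemble, basis, projection table, pathway,
#'   and scalar metrics (`mean_fit_rmsd`, `sd_fit_rmsd`, `varfrac1`,
#'   `coverage`, `elevator_shift_A`, `bsa_core_dimer_A2`).
#' @export
run_elevator_analysis <- function(structures, correspondence = NULL,
                                  domains, reference_id, outward_id,
                                  calibrate_id = outward_id,
                                  enm = enm_params(), bsa_model = NULL,
                                  ...) {
  models <- if (is.character(structures)) {
    out <- lapply(structures, function(p) extract_calpha(read_structure(p)))
    names(out) <- names(structures)
    out
  } else structures
  if (is.character(correspondence))
    correspondence <- load_correspondence(correspondence)
  if (is.character(domains)) domains <- load_domain_definition(domains)
  refm <- models[[reference_id]]
  ens0 <- build_ensemble(models, correspondence, reference_id)
  refmatched <- calpha_model(ens0$residues,
                             ens0$coords[reference_id, , ])
  fit_mask <- domain_mask(refmatched, domains, "dimer_domain")
  ens <- build_ensemble(models, correspondence, reference_id, fit_mask)
  basis <- covariance_pca(ens, calibrate_id = calibrate_id)
  proj <- projection_table(ens, basis,
                           components = seq_len(min(3L, length(basis$values))))
  start <- calpha_model(ens$residues, ens$coords[reference_id, , ])
  target <- calpha_model(ens$residues, ens$coords[outward_id, , ])
  path <- generate_pathway(start, target = target, axis = basis$vectors[1, ],
                           params = enm, ...)
  endpoint <- path$frames[[length(path$frames)]]
  cov <- coverage(endpoint, start, target, basis = basis)
  shift <- elevator_shift(start, endpoint, domains)
  bsa <- if (!is.null(bsa_model))
    buried_area(bsa_model, domains$domains$core_domain,
                domains$domains$dimer_domain) else NA_real_
  list(ensemble = ens, basis = basis, projections = proj, pathway = path,
       mean_fit_rmsd = ens$mean_fit_rmsd, sd_fit_rmsd = ens$sd_fit_rmsd,
       varfrac1 = basis$varfrac[1], coverage = cov,
       elevator_shift_A = shift$shift, bsa_core_dimer_A2 = bsa)
}
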