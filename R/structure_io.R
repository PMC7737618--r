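## Structure input/output: atomic models, C-alpha models, multi-model PDB
## writing, and the configuration objects (domain definitions, residue
## correspondences) consumed by the analysis stages.

#' Atomic structure model
#'
#' A light container for one model of an atomic structure: a data frame of
#' atoms (chain, residue number, insertion code, residue name, atom name,
#' element, altloc, occupancy, Cartesian coordinates in Angstrom) plus the
#' model id it was read from. Residue numbering follows the author
#' numbering found in the file; no renumbering is performed.
#'
#' @param atoms data frame with columns `chain`, `resno`, `ins`, `resname`,
#'   `atom`, `element`, `altloc`, `occ`, `x`, `y`, `z`.
#' @param model integer model id.
#' @return An object of class `AtomModel`.
#' @export
atom_model <- function(atoms, model = 1L) {
  req <- c("chain", "resno", "ins", "resname", "atom", "element",
           "altloc", "occ", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop_elevator("schema", "atoms table lacks columns: %s",
                  paste(miss, collapse = ", "))
  check_finite(c(atoms$x, atoms$y, atoms$z), "atom coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom)
  if (anyDuplicated(key))
    stop_elevator("schema", "duplicate (chain, residue, atom) triple: %s",
                  key[anyDuplicated(key)][1])
  structure(list(atoms = atoms, model = as.integer(model)),
            class = "AtomModel")
}

#' @export
print.AtomModel <- function(x, ...) {
  cat(sprintf("<AtomModel> %d atoms, %d residues, chains: %s (model %d)\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$ins))),
              paste(unique(x$atoms$chain), collapse = ","), x$model))
  invisible(x)
}

#' C-alpha structure model
#'
#' One coordinate row per residue; the node set for elastic network and
#' principal component analyses. Residue ordering is stable: chains in the
#' order read, ascending residue number within a chain.
#'
#' @param residues data frame with columns `chain`, `resno`, `resname`
#'   (and optionally `ins`).
#' @param xyz numeric M x 3 matrix of coordinates (Angstrom).
#' @return An object of class `CalphaModel`.
#' @export
calpha_model <- function(residues, xyz) {
  if (!all(c("chain", "resno", "resname") %in% names(residues)))
    stop_elevator("schema", "residues needs chain, resno, resname columns")
  if (is.null(residues$ins)) residues$ins <- ""
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(residues) || ncol(xyz) != 3L)
    stop_elevator("schema", "xyz must be an M x 3 matrix matching residues")
  check_finite(xyz, "coordinates")
  dimnames(xyz) <- NULL
  structure(list(residues = residues, xyz = xyz), class = "CalphaModel")
}

#' @export
print.CalphaModel <- function(x, ...) {
  cat(sprintf("<CalphaModel> %d residues, chains: %s\n", nrow(x$xyz),
              paste(unique(x$residues$chain), collapse = ",")))
  invisible(x)
}

n_residues <- function(m) nrow(m$xyz)

residue_keys <- function(m) {
  with(m$residues, paste0(chain, ":", resno, ins))
}

#' Read an atomic structure
#'
#' Reads one model from a PDB or mmCIF file. Alternate locations are
#' resolved to the highest-occupancy conformer (ties broken by altloc
#' letter order); hydrogens are retained if present.
#'
#' @param path file path (`.pdb`, `.ent`, `.cif`, `.mmcif`).
#' @param model 1-based model index.
#' @param chains optional character vector of chain ids to keep.
#' @return An [atom_model()].
#' @export
read_structure <- function(path, model = 1L, chains = NULL) {
  if (!file.exists(path))
    stop_elevator("io", "file not found: %s", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- withCallingHandlers(
    tryCatch(
      if (is_cif) bio3d::read.cif(path, multi = TRUE, verbose = FALSE)
      else bio3d::read.pdb(path, multi = TRUE, verbose = FALSE,
                           hex = FALSE, rm.alt = FALSE),
      error = function(e) stop_elevator(
        "format", "cannot parse %s as %s: %s", path,
        if (is_cif) "mmCIF" else "PDB", conditionMessage(e))),
    ## NA residue numbers are expected for hybrid-36 fields and patched below
    warning = function(w) {
      if (grepl("resno", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    stop_elevator("format", "no atom records found in %s", path)
  nmod <- max(1L, nrow(pdb$xyz))
  if (model < 1L || model > nmod)
    stop_elevator("io", "model %d not present in %s (%d model(s))",
                  model, path, nmod)
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  resno <- at$resno
  if (anyNA(resno) && !is_cif)
    resno <- .patch_hybrid36_resno(path, model, resno)
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = as.integer(resno),
    ins = ifelse(is.na(at$insert), "", at$insert),
    resname = at$resid,
    atom = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     toupper(substr(trimws(at$elety), 1L, 1L)), at$elesy),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    occ = ifelse(is.na(at$o), 1, at$o),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop_elevator("empty_selection", "no atoms selected from %s", path)
  atoms <- .resolve_altloc(atoms)
  rownames(atoms) <- NULL
  atom_model(atoms, model)
}

## Keep, per (chain, resno, ins, atom) group, the highest-occupancy altloc;
## ties broken by altloc letter order ('' sorts first).
.resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, atoms$altloc)
  keep <- !duplicated(key[ord])
  atoms[sort(ord[keep]), , drop = FALSE]
}

## Fallback for residue numbers > 9999 written in hybrid-36: bio3d returns
## NA for non-decimal fields; re-scan the fixed columns of the model block.
.patch_hybrid36_resno <- function(path, model, resno) {
  lines <- readLines(path, warn = FALSE)
  nmodel <- sum(grepl("^MODEL", lines))
  blocks <- if (nmodel == 0L) list(lines) else {
    starts <- grep("^MODEL", lines)
    ends <- grep("^ENDMDL", lines)
    Map(function(s, e) lines[s:e], starts, ends)
  }
  rec <- grep("^(ATOM  |HETATM)", blocks[[min(model, length(blocks))]],
              value = TRUE)
  if (length(rec) != length(resno)) return(resno)  # cannot align; leave as-is
  na <- which(is.na(resno))
  for (i in na) resno[i] <- hy36decode(substr(rec[i], 23L, 26L))
  resno
}

#' Extract the C-alpha trace
#'
#' One CA atom per residue; residues lacking a CA are dropped with a
#' warning naming them (glycines are kept: there is no CB requirement).
#'
#' @param model an [atom_model()].
#' @return A [calpha_model()].
#' @export
extract_calpha <- function(model) {
  at <- model$atoms
  rkey <- paste(at$chain, at$resno, at$ins, sep = "\r")
  ca <- at[trimws(at$atom) == "CA" & toupper(at$element) != "CA", , drop = FALSE]
  ## (element filter guards against calcium ions named CA)
  if (nrow(ca) == 0L)
    stop_elevator("empty_selection", "model contains no C-alpha atoms")
  cakey <- paste(ca$chain, ca$resno, ca$ins, sep = "\r")
  dropped <- setdiff(unique(rkey), cakey)
  if (length(dropped)) {
    lab <- vapply(strsplit(dropped, "\r"), function(p)
      paste0(p[1], ":", p[2], if (length(p) > 2) p[3] else ""), "")
    warn_elevator("missing_ca", "dropping %d residue(s) without CA: %s",
                  length(dropped), paste(lab, collapse = ", "))
  }
  ## stable ordering: chains in order of first appearance, ascending
  ## residue number (then insertion code) within chain
  chain_order <- match(ca$chain, unique(at$chain))
  ord <- order(chain_order, ca$resno, ca$ins)
  ca <- ca[ord, , drop = FALSE]
  calpha_model(
    residues = data.frame(chain = ca$chain, resno = ca$resno,
                          resname = ca$resname, ins = ca$ins,
                          stringsAsFactors = FALSE),
    xyz = cbind(ca$x, ca$y, ca$z)
  )
}

#' Write models as a multi-model PDB file
#'
#' Writes an ordered list of structures (all sharing one residue set) with
#' MODEL/ENDMDL records. Coordinates round-trip through [read_structure()]
#' to within 0.001 Angstrom (PDB fixed-column precision); residue numbers
#' beyond 9999 and serials beyond 99999 use hybrid-36 encoding.
#'
#' @param path output file path.
#' @param models a single model or list of [calpha_model()] / [atom_model()]
#'   objects with identical residue sets.
#' @export
write_models <- function(path, models) {
  if (inherits(models, c("CalphaModel", "AtomModel"))) models <- list(models)
  if (length(models) == 0L)
    stop_elevator("io", "no models to write")
  tabs <- lapply(models, .atom_table)
  id0 <- tabs[[1]][c("chain", "resno", "ins", "resname", "atom")]
  for (i in seq_along(tabs)[-1]) {
    if (!identical(tabs[[i]][c("chain", "resno", "ins", "resname", "atom")], id0))
      stop_elevator("consistency",
                    "model %d has a different residue/atom set than model 1", i)
  }
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(tabs) > 1L
  for (m in seq_along(tabs)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(.format_atom_records(tabs[[m]]), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

.atom_table <- function(m) {
  if (inherits(m, "AtomModel")) return(m$atoms)
  if (inherits(m, "CalphaModel")) {
    r <- m$residues
    return(data.frame(chain = r$chain, resno = r$resno,
                      ins = if (is.null(r$ins)) "" else r$ins,
                      resname = r$resname, atom = "CA", element = "C",
                      altloc = "", occ = 1,
                      x = m$xyz[, 1], y = m$xyz[, 2], z = m$xyz[, 3],
                      stringsAsFactors = FALSE))
  }
  stop_elevator("schema", "models must be AtomModel or CalphaModel objects")
}

.format_atom_records <- function(at) {
  serial <- vapply(seq_len(nrow(at)), hy36encode, "", width = 5L)
  resno <- vapply(at$resno, hy36encode, "", width = 4L)
  name <- vapply(trimws(at$atom), function(a)
    if (nchar(a) >= 4L) substr(a, 1, 4) else sprintf(" %-3s", a), "")
  sprintf("ATOM  %s %s%1s%-3s %1s%s%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, substr(at$altloc, 1, 1),
          substr(at$resname, 1, 3), substr(at$chain, 1, 1), resno,
          substr(at$ins, 1, 1), at$x, at$y, at$z, at$occ, 0,
          toupper(substr(at$element, 1, 2)))
}

## ---------------------------------------------------------------------
## Domain definitions and residue correspondences
## ---------------------------------------------------------------------

#' Domain definition
#'
#' Named residue sets (scaffold/dimerization domain, mobile core domain,
#' ion-binding site, optional bulk region) plus the membrane normal along
#' which elevator displacements are measured (unit vector; defaults to +z,
#' the membrane frame of the deposited coordinates).
#'
#' @param domains named list of data frames with columns `chain`, `resno`.
#' @param binding_site data frame with columns `chain`, `resno`.
#' @param membrane_normal numeric length-3 vector (normalized internally).
#' @return An object of class `DomainDefinition`.
#' @export
domain_definition <- function(domains, binding_site = NULL,
                              membrane_normal = c(0, 0, 1)) {
  stopifnot(is.list(domains), !is.null(names(domains)))
  domains <- lapply(domains, function(d) {
    d <- as.data.frame(d)[c("chain", "resno")]
    d$resno <- as.integer(d$resno)
    d
  })
  if (all(c("dimer_domain", "core_domain") %in% names(domains))) {
    a <- domains$dimer_domain; b <- domains$core_domain
    ov <- merge(a, b)
    if (nrow(ov))
      stop_elevator("validation",
                    "dimer_domain and core_domain overlap at: %s",
                    paste(paste0(ov$chain, ":", ov$resno), collapse = ", "))
  }
  if (!is.null(binding_site)) {
    binding_site <- as.data.frame(binding_site)[c("chain", "resno")]
    binding_site$resno <- as.integer(binding_site$resno)
  }
  structure(list(domains = domains, binding_site = binding_site,
                 membrane_normal = unit_vector(as.numeric(membrane_normal))),
            class = "DomainDefinition")
}

#' Load a domain definition from YAML
#'
#' Schema: `domains: {name: {chain: [[start, end], ...]}}`, optional
#' `binding_site: {chain: [resno | [start, end], ...]}` and
#' `membrane_normal: [x, y, z]`. Unknown top-level keys are rejected.
#'
#' @param path YAML file path.
#' @return A [domain_definition()].
#' @export
load_domain_definition <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop_elevator("format", "cannot parse YAML %s: %s", path,
                  conditionMessage(e)))
  known <- c("domains", "binding_site", "membrane_normal")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop_elevator("validation", "unknown key(s) in %s: %s", path,
                  paste(extra, collapse = ", "))
  if (is.null(cfg$domains))
    stop_elevator("validation", "missing required key 'domains' in %s", path)
  domains <- lapply(cfg$domains, .expand_chain_ranges)
  bs <- if (!is.null(cfg$binding_site)) .expand_chain_ranges(cfg$binding_site)
  mn <- if (!is.null(cfg$membrane_normal)) as.numeric(cfg$membrane_normal)
        else c(0, 0, 1)
  domain_definition(domains, bs, mn)
}

.expand_chain_ranges <- function(per_chain) {
  out <- lapply(names(per_chain), function(ch) {
    resnos <- unlist(lapply(per_chain[[ch]], function(r) {
      r <- as.integer(unlist(r))
      if (length(r) == 1L) r else seq(r[1], r[2])
    }))
    data.frame(chain = ch, resno = resnos, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a domain definition to YAML
#' @param def a [domain_definition()].
#' @param path output path.
#' @export
write_domain_definition <- function(def, path) {
  pack <- function(df) {
    out <- lapply(split(df$resno, df$chain), function(r) {
      r <- sort(unique(r))
      brk <- c(0L, which(diff(r) != 1L), length(r))
      lapply(seq_len(length(brk) - 1L), function(i)
        c(r[brk[i] + 1L], r[brk[i + 1L]]))
    })
    out
  }
  cfg <- list(domains = lapply(def$domains, pack))
  if (!is.null(def$binding_site)) cfg$binding_site <- pack(def$binding_site)
  cfg$membrane_normal <- as.numeric(def$membrane_normal)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Residue mask for a named domain
#'
#' Logical vector over a C-alpha model's residues selecting a named
#' domain (or the binding site via `name = "binding_site"`).
#'
#' @param model a [calpha_model()].
#' @param def a [domain_definition()].
#' @param name domain name.
#' @return logical vector of length M.
#' @export
domain_mask <- function(model, def, name) {
  set <- if (identical(name, "binding_site")) def$binding_site
         else def$domains[[name]]
  if (is.null(set))
    stop_elevator("validation", "domain '%s' not defined", name)
  keys <- paste(model$residues$chain, model$residues$resno)
  mask <- keys %in% paste(set$chain, set$resno)
  if (!any(mask))
    stop_elevator("empty_selection", "domain '%s' matches no residues", name)
  mask
}

#' Load a residue correspondence table
#'
#' TSV with one column per structure id and one row per matched core
#' position; cells are `chain:resnum`. Every row must have exactly one
#' entry per structure and no residue may appear in two rows.
#'
#' @param path TSV file path.
#' @return An object of class `CorrespondenceTable`: a list with `ids` and
#'   `entries` (per structure, a data frame of chain/resno aligned by row).
#' @export
load_correspondence <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2L)
    stop_elevator("validation", "correspondence table needs >= 2 structures")
  entries <- lapply(names(tab), function(id) {
    cells <- trimws(tab[[id]])
    bad <- which(is.na(cells) | cells == "" | !grepl("^[^:]+:-?[0-9]+$", cells))
    if (length(bad))
      stop_elevator("validation",
                    "correspondence row %d, structure '%s': missing/malformed cell",
                    bad[1], id)
    if (anyDuplicated(cells))
      stop_elevator("validation",
                    "structure '%s': residue %s appears in two rows", id,
                    cells[anyDuplicated(cells)][1])
    parts <- strsplit(cells, ":", fixed = TRUE)
    data.frame(chain = vapply(parts, `[`, "", 1L),
               resno = as.integer(vapply(parts, `[`, "", 2L)),
               stringsAsFactors = FALSE)
  })
  names(entries) <- names(tab)
  structure(list(ids = names(tab), entries = entries),
            class = "CorrespondenceTable")
}

#' Write a correspondence table
#' @param corr a `CorrespondenceTable`.
#' @param path output TSV path.
#' @export
write_correspondence <- function(corr, path) {
  cols <- lapply(corr$entries, function(e) paste0(e$chain, ":", e$resno))
  tab <- as.data.frame(cols, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @importFrom utils write.table
NULL

## Row indices into `model`'s residues for one structure's correspondence
## entries, in table order; errors naming the structure if any is missing.
match_residues <- function(model, entries, id = "?") {
  keys <- paste(model$residues$chain, model$residues$resno)
  idx <- match(paste(entries$chain, entries$resno), keys)
  if (anyNA(idx)) {
    miss <- entries[is.na(idx), ][1, ]
    stop_elevator("validation",
                  "structure '%s': residue %s:%d in correspondence not found",
                  id, miss$chain, miss$resno)
  }
  idx
}
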