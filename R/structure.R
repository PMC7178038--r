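# Lightweight coordinate containers: a structure model is a data frame of
# atoms (name, element, residue number/name, chain, x/y/z in angstrom); an
# ensemble is a list of models sharing the same atom identities. PDB and
# mmCIF parsing is delegated to bio3d.

BACKBONE_ATOMS <- c("N", "CA", "C")

#' Construct a structure model from an atom table
#'
#' @param atoms data frame with columns `atom`, `element`, `resno`, `resid`,
#'   `chain`, `x`, `y`, `z` (angstrom, author residue numbering).
#' @param model_id identifier stored alongside the atoms (default 1).
#' @return An object of class `structure_model` (a data frame).
#' @export
structure_model <- function(atoms, model_id = 1L) {
  needed <- c("atom", "element", "resno", "resid", "chain", "x", "y", "z")
  miss <- setdiff(needed, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("coordinates must be finite", call. = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue number, atom name) entries", call. = FALSE)
  out <- as.data.frame(atoms[needed])
  attr(out, "model_id") <- model_id
  class(out) <- c("structure_model", "data.frame")
  out
}

#' Bundle structure models into an ensemble
#'
#' @param models list of [structure_model()] objects with identical backbone
#'   atom sets.
#' @param source optional source tag (e.g. a PDB id).
#' @return An object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(models, source = NULL) {
  if (length(models) < 1L) stop("no models supplied", call. = FALSE)
  key <- function(m) {
    bb <- m[m$atom %in% BACKBONE_ATOMS, ]
    paste(bb$chain, bb$resno, bb$atom, collapse = "|")
  }
  keys <- vapply(models, key, character(1))
  if (length(unique(keys)) != 1L)
    stop("models do not share the same backbone atom set", call. = FALSE)
  structure(list(models = models, source = source),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("structure_ensemble: %d models, %d atoms in model 1%s\n",
              length(x$models), nrow(x$models[[1L]]),
              if (is.null(x$source)) "" else paste0(" (", x$source, ")")))
  invisible(x)
}

# element symbol from a PDB atom name when the element column is absent
.element_from_name <- function(name) {
  stripped <- sub("^[0-9']*", "", name)
  ifelse(grepl("^H", stripped), "H", substr(stripped, 1L, 1L))
}

#' Read a structure file into models
#'
#' Reads PDB (or mmCIF, by extension) files through bio3d and returns either
#' a single [structure_model()] or a [structure_ensemble()] for multi-model
#' (NMR) entries.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param model model number to extract, or `NULL` (default) for all models.
#' @return A `structure_model` (single model) or `structure_ensemble`.
#' @export
read_structure <- function(path, model = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path, multi = TRUE)
  else bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  elem <- if ("elesym" %in% names(at) && !all(is.na(at$elesym)) &&
              !all(at$elesym == "")) at$elesym
  else .element_from_name(at$elety)
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  xyz <- pdb$xyz
  n_models <- nrow(as.matrix(xyz))
  build <- function(i) {
    m <- matrix(as.matrix(xyz)[i, ], ncol = 3L, byrow = TRUE)
    structure_model(data.frame(atom = at$elety, element = elem,
                               resno = at$resno, resid = at$resid,
                               chain = chain,
                               x = m[, 1L], y = m[, 2L], z = m[, 3L],
                               stringsAsFactors = FALSE), model_id = i)
  }
  if (!is.null(model)) {
    if (model < 1L || model > n_models)
      stop("model ", model, " not present (file has ", n_models, ")",
           call. = FALSE)
    return(build(model))
  }
  if (n_models == 1L) return(build(1L))
  structure_ensemble(lapply(seq_len(n_models), build),
                     source = basename(path))
}

#' Download a PDB entry (requires network access)
#'
#' Thin wrapper over [bio3d::get.pdb()] that returns the local file path.
#' Deposited reference entries for this analysis family include the NMR
#' ensembles and crystal structures of bacterial acyl carrier proteins.
#'
#' @param id 4-character PDB accession.
#' @param dir download directory (default `tempdir()`).
#' @param timeout download timeout in seconds (default 30).
#' @return Path to the downloaded PDB file.
#' @export
fetch_pdb <- function(id, dir = tempdir(), timeout = 30) {
  old <- options(timeout = timeout)
  on.exit(options(old), add = TRUE)
  path <- suppressWarnings(bio3d::get.pdb(id, path = dir, verbose = FALSE))
  if (!file.exists(path) || file.size(path) == 0)
    stop("could not download PDB entry ", id, call. = FALSE)
  path
}

# Match atoms of two models by (chain, resno, atom) over a selection and
# return aligned coordinate matrices.
.matched_coords <- function(a, b, selection = "backbone") {
  sel <- function(m) {
    keep <- switch(
      selection,
      backbone = m$atom %in% BACKBONE_ATOMS,
      calpha = m$atom == "CA",
      heavy = m$element != "H",
      all = rep(TRUE, nrow(m)),
      m$atom %in% selection)
    m[keep, , drop = FALSE]
  }
  a <- sel(a); b <- sel(b)
  ka <- paste(a$chain, a$resno, a$atom)
  kb <- paste(b$chain, b$resno, b$atom)
  common <- intersect(ka, kb)
  if (length(common) < 3L)
    stop("fewer than 3 matched atoms in the selection", call. = FALSE)
  ia <- match(common, ka); ib <- match(common, kb)
  list(A = as.matrix(a[ia, c("x", "y", "z")]),
       B = as.matrix(b[ib, c("x", "y", "z")]),
       keys = common)
}
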