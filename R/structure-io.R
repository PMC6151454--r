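#' @importFrom stats sd rnorm runif setNames lm coef predict approx aggregate
#' @importFrom utils read.table write.table
NULL

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a structure ensemble
#'
#' An ensemble is the package's central structure container: a flat atom
#' table shared by all models plus an `n_models x 3N` coordinate matrix
#' (bio3d-style `xyz` layout, Angstrom units). Every model has identical
#' chain/residue/atom composition; author residue numbering is preserved.
#'
#' @param atoms data.frame with columns `type` ("ATOM"/"HETATM"), `elety`
#'   (atom name), `resid` (3-letter residue name), `chain`, `resno`
#'   (author numbering), `elesy` (element symbol, may be `NA`).
#' @param xyz numeric matrix, one row per model, `3 * nrow(atoms)` columns
#'   in x1,y1,z1,x2,... order.
#' @param id character identifier.
#' @return object of class `"ensemble"`.
#' @export
structure_ensemble <- function(atoms, xyz, id = "structure") {
  required <- c("type", "elety", "resid", "chain", "resno", "elesy")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(atoms)) {
    stop("xyz has ", ncol(xyz), " columns; expected ", 3L * nrow(atoms))
  }
  if (nrow(xyz) < 1L) stop("ensemble needs at least one model")
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  if (any(is.na(atoms$elety)) || any(!nzchar(atoms$elety))) {
    stop("empty atom names")
  }
  # atom names must be unique within a residue
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) {
    stop("duplicate atom name within a residue: ", key[anyDuplicated(key)])
  }
  atoms$resno <- as.integer(atoms$resno)
  structure(list(id = id, atoms = atoms, xyz = xyz),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble '%s': %d model(s), %d atoms, chains %s>\n",
              x$id, n_models(x), nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Number of models in an ensemble
#' @param ensemble an `"ensemble"` object.
#' @export
n_models <- function(ensemble) nrow(ensemble$xyz)

#' Coordinates of one model as an N x 3 matrix
#' @param ensemble an `"ensemble"` object.
#' @param model 1-based model index.
#' @export
model_coords <- function(ensemble, model = 1L) {
  if (model < 1L || model > n_models(ensemble)) {
    stop("model index ", model, " out of range 1..", n_models(ensemble))
  }
  matrix(ensemble$xyz[model, ], ncol = 3L, byrow = TRUE)
}

is_hydrogen <- function(elety, elesy = NA) {
  # name convention: first alphabetic character after leading digits
  by_name <- substr(toupper(sub("^[0-9]*", "", elety)), 1L, 1L) == "H"
  has_elem <- !is.na(elesy) & nzchar(trimws(as.character(elesy)))
  ifelse(has_elem, toupper(trimws(as.character(elesy))) == "H", by_name)
}

#' Parse a (possibly multi-model) PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] that enforces the ensemble
#' contract: one model per MODEL record (a single model when none are
#' present), identical composition across models, author residue
#' numbering preserved, alternate locations resolved to the
#' highest-occupancy conformer (ties broken in favour of altLoc 'A').
#' Calcium ions and other HETATM records are retained and selectable.
#' Files using insertion codes are rejected.
#'
#' @param path path to a PDB file.
#' @param id identifier for the ensemble; default the file base name.
#' @return an `"ensemble"` object.
#' @export
parse_structure <- function(path, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # malformed-line scan: coordinates must parse as numbers
  atom_idx <- which(is_atom)
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54L) stop("malformed ATOM line ", i, ": too short")
    xyz_txt <- c(substr(ln, 31L, 38L), substr(ln, 39L, 46L),
                 substr(ln, 47L, 54L))
    v <- suppressWarnings(as.numeric(xyz_txt))
    if (any(is.na(v))) stop("malformed ATOM line ", i,
                            ": unparseable coordinates")
    if (nchar(ln) >= 27L && substr(ln, 27L, 27L) != " ") {
      stop("insertion codes unsupported (line ", i, ")")
    }
  }

  # composition scan across MODEL blocks
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 1L) {
    counts <- integer(length(model_starts))
    ends <- c(model_starts[-1L], length(lines) + 1L)
    for (k in seq_along(model_starts)) {
      counts[k] <- sum(atom_idx > model_starts[k] & atom_idx < ends[k])
    }
    if (length(unique(counts)) != 1L) {
      stop("inconsistent model composition: atom counts ",
           paste(counts, collapse = ", "))
    }
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)

  # resolve alternate locations to highest occupancy, ties -> 'A'
  alt <- at$alt
  if (any(!is.na(alt))) {
    key <- paste(at$chain, at$resno, at$elety)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      occ <- at$o[idx]
      occ[is.na(occ)] <- 0
      best <- idx[occ == max(occ)]
      if (length(best) > 1L) {
        a <- alt[best]
        best <- if (any(a == "A", na.rm = TRUE)) {
          best[which(a == "A")[1L]]
        } else best[order(a)[1L]]
      }
      keep[setdiff(idx, best[1L])] <- FALSE
    }
    at <- at[keep, , drop = FALSE]
    xyz <- xyz[, as.vector(rbind(3L * which(keep) - 2L,
                                 3L * which(keep) - 1L,
                                 3L * which(keep))), drop = FALSE]
  }

  chain <- at$chain
  chain[is.na(chain)] <- " "
  atoms <- data.frame(type = at$type, elety = at$elety, resid = at$resid,
                      chain = chain, resno = as.integer(at$resno),
                      elesy = at$elesy, stringsAsFactors = FALSE)
  structure_ensemble(atoms, xyz,
                     id = if (is.null(id)) {
                       sub("\\.[^.]*$", "", basename(path))
                     } else id)
}

#' Write an ensemble to a PDB file
#'
#' Emits one MODEL/ENDMDL block per model (via [bio3d::write.pdb()]);
#' the file re-parses to an ensemble with identical labels and
#' coordinates within the fixed-width PDB precision of 1e-3 Angstrom.
#'
#' @param ensemble an `"ensemble"` object.
#' @param path output file path.
#' @export
write_structure <- function(ensemble, path) {
  at <- ensemble$atoms
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = ensemble$xyz,
                     type = at$type, resno = at$resno, resid = at$resid,
                     eleno = seq_len(nrow(at)), elety = at$elety,
                     chain = ifelse(at$chain == " ", "", at$chain),
                     o = rep(1, nrow(at)), b = rep(0, nrow(at)),
                     elesy = ifelse(is.na(at$elesy), "", at$elesy))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Atom selection specification
#'
#' @param chain chain identifier.
#' @param range inclusive residue-number range `c(start, end)` in author
#'   numbering, or `NULL` for all residues of the chain.
#' @param atoms `"all"`, `"backbone"` (N, CA, C, O), `"heavy"`
#'   (all non-hydrogen), or an explicit character vector of atom names.
#' @param include_het keep HETATM records (e.g. the bound calcium ions)?
#'   Default `FALSE`: RMSD-type selections exclude heteroatoms.
#' @return object of class `"selection_spec"`.
#' @export
selection_spec <- function(chain, range = NULL, atoms = "all",
                           include_het = FALSE) {
  if (!is.null(range)) {
    if (length(range) != 2L || range[1L] > range[2L]) {
      stop("range must be c(start, end) with start <= end")
    }
  }
  structure(list(chain = chain, range = range, atoms = atoms,
                 include_het = include_het),
            class = "selection_spec")
}

#' Select atoms from one model of an ensemble
#'
#' Returns a coordinate set (labels plus an N x 3 matrix) in
#' deterministic order: chain, then residue number, then atom name.
#' Atom names listed in the spec but absent from a residue in range are
#' skipped with a warning.
#'
#' @param ensemble an `"ensemble"`.
#' @param spec a [selection_spec()].
#' @param model 1-based model index.
#' @return object of class `"coordset"`: `list(labels, coords)`.
#' @export
select_atoms <- function(ensemble, spec, model = 1L) {
  at <- ensemble$atoms
  idx <- at$chain == spec$chain
  if (!spec$include_het) idx <- idx & at$type == "ATOM"
  if (!is.null(spec$range)) {
    idx <- idx & at$resno >= spec$range[1L] & at$resno <= spec$range[2L]
  }
  mode <- spec$atoms
  if (identical(mode, "backbone")) {
    idx <- idx & at$elety %in% BACKBONE_ATOMS
  } else if (identical(mode, "heavy")) {
    idx <- idx & !is_hydrogen(at$elety, at$elesy)
  } else if (!identical(mode, "all")) {
    idx <- idx & at$elety %in% mode
    # warn about residues in range lacking a requested atom
    in_range <- at$chain == spec$chain &
      (if (is.null(spec$range)) TRUE
       else at$resno >= spec$range[1L] & at$resno <= spec$range[2L])
    for (rn in unique(at$resno[in_range])) {
      have <- at$elety[in_range & at$resno == rn]
      lack <- setdiff(mode, have)
      if (length(lack) > 0L && length(intersect(mode, have)) < length(mode)) {
        warning("residue ", rn, " lacks atom(s): ",
                paste(lack, collapse = ","), call. = FALSE)
      }
    }
  }
  if (!any(idx)) stop("empty selection")
  co <- model_coords(ensemble, model)[idx, , drop = FALSE]
  labels <- data.frame(chain = at$chain[idx], resno = at$resno[idx],
                       elety = at$elety[idx], stringsAsFactors = FALSE)
  ord <- order(labels$chain, labels$resno, labels$elety, method = "radix")
  coordset(labels[ord, , drop = FALSE], co[ord, , drop = FALSE])
}

#' Construct a coordinate set
#' @param labels data.frame with columns chain, resno, elety.
#' @param coords N x 3 numeric matrix, Angstrom.
#' @export
coordset <- function(labels, coords) {
  coords <- as.matrix(coords)
  if (nrow(labels) != nrow(coords)) stop("labels/coords length mismatch")
  rownames(labels) <- NULL
  structure(list(labels = labels, coords = coords), class = "coordset")
}

#' @export
print.coordset <- function(x, ...) {
  cat(sprintf("<coordset: %d atoms>\n", nrow(x$coords)))
  invisible(x)
}

as_coords <- function(x) {
  if (inherits(x, "coordset")) x$coords else as.matrix(x)
}
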