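#' Molecular model container
#'
#' An ordered collection of atoms (coordinates in Å, partial charges in e,
#' Lennard-Jones parameters) representing a protein, a cofactor set, or a
#' toy rigid body.  Atoms live in a data frame; named selections map labels
#' (e.g. `"cofactor:NiFe"`) to atom indices.
#'
#' @param atoms data frame with columns `atom_name`, `element`,
#'   `residue_name`, `residue_number`, `chain_id`, `x`, `y`, `z`, `charge`,
#'   `lj_epsilon` (kcal/mol, >= 0), `lj_rmin_half` (Å, >= 0), `tags`
#'   (semicolon-separated labels).  Missing columns are filled with neutral
#'   defaults; coordinates are mandatory.
#' @param name model identifier.
#' @param net_charge declared net charge in e; defaults to the sum of atom
#'   charges.
#' @param selections named list of integer atom-index vectors.
#' @return an object of class `molecular_model`.
#' @export
molecular_model <- function(atoms, name = "model", net_charge = NULL,
                            selections = list()) {
  stopifnot(is.data.frame(atoms), all(c("x", "y", "z") %in% names(atoms)))
  n <- nrow(atoms)
  if (n == 0L) stop("empty structure: a molecular model needs at least one atom")
  defaults <- list(atom_name = "X", element = "", residue_name = "UNK",
                   residue_number = 1L, chain_id = "A", charge = 0,
                   lj_epsilon = 0, lj_rmin_half = 0, tags = "")
  for (col in names(defaults)) {
    if (is.null(atoms[[col]])) atoms[[col]] <- rep(defaults[[col]], n)
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(atoms$lj_epsilon < 0) || any(atoms$lj_rmin_half < 0))
    stop("Lennard-Jones parameters must be non-negative")
  if (length(selections)) {
    ok <- vapply(selections, function(i)
      length(i) > 0 && all(i >= 1L & i <= n), logical(1))
    if (!all(ok)) stop("selections reference invalid atom indices")
  }
  if (is.null(net_charge)) net_charge <- sum(atoms$charge)
  structure(list(name = name, atoms = atoms, net_charge = net_charge,
                 selections = selections),
            class = "molecular_model")
}

#' Number of atoms in a model
#' @param model a `molecular_model`.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Extract or replace atomic coordinates
#'
#' @param model a `molecular_model` (or SAM `surface_model`).
#' @return `coords()` returns an n x 3 numeric matrix in Å.
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' @rdname coords
#' @param value an n x 3 matrix of replacement coordinates.
#' @export
`coords<-` <- function(model, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(model$atoms), ncol(value) == 3)
  model$atoms$x <- value[, 1]
  model$atoms$y <- value[, 2]
  model$atoms$z <- value[, 3]
  model
}

#' Centre of geometry of a model (mean of atom coordinates)
#' @param model a `molecular_model`.
#' @return length-3 numeric vector in Å.
#' @export
center_of_geometry <- function(model) colMeans(coords(model))

#' Centre of mass of a model
#'
#' Uses standard atomic masses looked up from the element column; atoms with
#' unknown or empty element get unit mass, so a model without element
#' information falls back to the centre of geometry.
#' @param model a `molecular_model`.
#' @return length-3 numeric vector in Å.
#' @export
center_of_mass <- function(model) {
  m <- atom_masses(model)
  drop(m %*% coords(model)) / sum(m)
}

atom_masses <- function(model) {
  ele <- toupper(trimws(model$atoms$element))
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974, FE = 55.845, NI = 58.693, AU = 196.967,
           MG = 24.305, ZN = 65.38, "NA" = 22.990, CL = 35.45, K = 39.098)
  m <- unname(tab[ele])
  m[is.na(m)] <- 1
  m
}

#' Look up a named atom selection
#' @param model a `molecular_model`.
#' @param label selection label.
#' @return integer vector of atom indices.
#' @keywords internal
get_selection <- function(model, label) {
  idx <- model$selections[[label]]
  if (is.null(idx)) stop("unknown selection: '", label, "'")
  idx
}

#' @export
print.molecular_model <- function(x, ...) {
  cat(sprintf("<molecular_model '%s': %d atoms, net charge %+.3f e>\n",
              x$name, n_atoms(x), x$net_charge))
  if (length(x$selections))
    cat("  selections:", paste(names(x$selections), collapse = ", "), "\n")
  invisible(x)
}

# Does a tag string contain a given label?
has_tag <- function(tags, label) {
  vapply(strsplit(tags, ";", fixed = TRUE),
         function(t) label %in% t, logical(1))
}

add_tag <- function(tags, label) {
  ifelse(tags == "", label, paste(tags, label, sep = ";"))
}
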