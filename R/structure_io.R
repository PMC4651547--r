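#' Read a molecular structure from PDB or PQR
#'
#' Wraps [bio3d::read.pdb()] / [bio3d::read.pqr()].  Atom order is preserved
#' and coordinates stay in Å.  For PDB input partial charges are zero until
#' [parameterize()] is applied; PQR input carries per-atom charges and radii
#' (the radius is stored as `lj_rmin_half` so a PQR file round-trips).
#' HETATM records are retained and tagged `"hetero"`.  Where alternate
#' locations are present only the first (blank or "A") is kept, with a
#' warning.
#'
#' @param path path to a structure file.
#' @param format `"pdb"`, `"pqr"` or `"auto"` (by file extension; default).
#' @param multi if `TRUE` and the file holds several MODEL blocks, return a
#'   list of `molecular_model`s (one per frame) instead of the first model.
#' @return a [molecular_model()] (or list of them when `multi = TRUE`).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "pqr"),
                           multi = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pqr$", path, ignore.case = TRUE)) "pqr" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  check_structure_lines(path)
  pdb <- tryCatch(
    if (format == "pqr") bio3d::read.pqr(path)
    else bio3d::read.pdb(path, multi = multi, verbose = FALSE),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    stop("empty structure: no ATOM/HETATM records in ", path)

  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  if (!all(keep)) {
    warning(sum(!keep), " alternate-location atoms dropped (first altloc kept)")
  }
  charge <- if (format == "pqr") at$o else rep(0, nrow(at))
  radius <- if (format == "pqr") at$b else rep(0, nrow(at))
  atoms <- data.frame(
    atom_name = at$elety,
    element = ifelse(is.na(at$elesy), guess_element(at$elety), at$elesy),
    residue_name = at$resid,
    residue_number = at$resno,
    chain_id = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    charge = ifelse(is.na(charge), 0, charge),
    lj_epsilon = 0,
    lj_rmin_half = ifelse(is.na(radius), 0, radius),
    tags = ifelse(at$type == "HETATM", "hetero", ""),
    stringsAsFactors = FALSE)
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  name <- sub("\\.(pdb|pqr)$", "", basename(path), ignore.case = TRUE)

  nframes <- if (multi && is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (multi && nframes > 1L) {
    xyz <- pdb$xyz[, rep(keep, each = 3L), drop = FALSE]
    lapply(seq_len(nframes), function(f) {
      m <- molecular_model(atoms, name = sprintf("%s#%d", name, f))
      coords(m) <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      m
    })
  } else {
    molecular_model(atoms, name = name)
  }
}

# Cheap pre-scan so malformed coordinate fields are reported with their line.
check_structure_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) >= 54) {
      xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54))))
      if (anyNA(xyz))
        stop("malformed coordinate record at line ", i, ": ", trimws(ln))
    }
  }
  invisible(TRUE)
}

guess_element <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  two <- substr(nm, 1, 2)
  known2 <- c("FE", "NI", "AU", "ZN", "MG", "CL", "NA", "BR")
  ifelse(two %in% known2, two, substr(sub("^[0-9]+", "", nm), 1, 1))
}

#' Write a molecular structure to PDB or PQR
#'
#' A list of models is written as a multi-MODEL PDB (one MODEL/ENDMDL block
#' per pose); each individual model is emitted by [bio3d::write.pdb()] /
#' [bio3d::write.pqr()] so the column layout follows wwPDB v3.3.  For PQR
#' output the charge column is the in-memory `charge` and the radius column
#' is `lj_rmin_half`.
#'
#' @param model a [molecular_model()] or a list of them (pose ensemble;
#'   PDB only).
#' @param path output file path.
#' @param format `"pdb"` or `"pqr"`.
#' @return invisibly, `path`.
#' @export
write_structure <- function(model, path, format = c("pdb", "pqr")) {
  format <- match.arg(format)
  if (inherits(model, "molecular_model")) {
    write_one_structure(model, path, format)
  } else if (is.list(model) && all(vapply(model, inherits, logical(1),
                                          "molecular_model"))) {
    if (format != "pdb") stop("multi-model output is PDB only")
    blocks <- lapply(seq_along(model), function(i) {
      tmp <- tempfile(fileext = ".pdb")
      on.exit(unlink(tmp), add = TRUE)
      write_one_structure(model[[i]], tmp, "pdb")
      body <- grep("^(ATOM|HETATM|TER)", readLines(tmp, warn = FALSE),
                   value = TRUE)
      c(sprintf("MODEL     %4d", i), body, "ENDMDL")
    })
    writeLines(c(unlist(blocks), "END"), path)
  } else {
    stop("'model' must be a molecular_model or a list of them")
  }
  invisible(path)
}

write_one_structure <- function(model, path, format) {
  a <- model$atoms
  het <- has_tag(a$tags, "hetero")
  args <- list(file = path,
               xyz = as.numeric(t(coords(model))),
               resno = a$residue_number, resid = a$residue_name,
               eleno = seq_len(nrow(a)), elety = a$atom_name,
               chain = a$chain_id)
  ok <- tryCatch({
    if (format == "pqr") {
      args$o <- a$charge; args$b <- a$lj_rmin_half
      do.call(bio3d::write.pqr, args)
    } else {
      args$o <- rep(1, nrow(a)); args$b <- rep(0, nrow(a))
      args$type <- ifelse(het, "HETATM", "ATOM")
      args$elesy <- a$element
      do.call(bio3d::write.pdb, args)
    }
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  invisible(ok)
}
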