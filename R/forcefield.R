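#' The packaged residue-level charge / Lennard-Jones table
#'
#' A deliberately minimal, deterministic parameter set for coarse
#' electrostatic screening: heavy atoms only, with each implicit hydrogen's
#' charge folded into its parent heavy atom.  Per-residue charges sum to the
#' formal charge at pH 7 (Asp/Glu -1, Lys/Arg +1, His neutral, others 0),
#' carried by the terminal side-chain heteroatoms.  Every residue has a
#' wildcard (`atom_name == "*"`) fallback row; atoms matching no row at all
#' receive `default_entry`.
#'
#' @param path optional path to an alternative CSV with columns
#'   `residue_name, atom_name, charge, lj_epsilon, lj_rmin_half`.
#' @param default_entry parameters for atoms with no table match.
#' @return an object of class `forcefield_table` with elements `entries`
#'   (data frame), `default_entry` and `provenance`.
#' @export
default_forcefield <- function(path = NULL,
                               default_entry = list(charge = 0,
                                                    lj_epsilon = 0.07,
                                                    lj_rmin_half = 2.0)) {
  if (is.null(path)) {
    path <- system.file("extdata", "residue_charges.csv", package = "samscan")
  }
  entries <- utils::read.csv(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  need <- c("residue_name", "atom_name", "charge", "lj_epsilon",
            "lj_rmin_half")
  stopifnot(all(need %in% names(entries)))
  structure(list(entries = entries, default_entry = default_entry,
                 provenance = path),
            class = "forcefield_table")
}

#' @export
print.forcefield_table <- function(x, ...) {
  cat(sprintf("<forcefield_table: %d entries, %d residues>\n",
              nrow(x$entries), length(unique(x$entries$residue_name))))
  invisible(x)
}

#' Assign charges and Lennard-Jones parameters to a model
#'
#' Lookup order per atom: exact `(residue_name, atom_name)` entry, then the
#' residue's wildcard entry, then `default_entry` (counted and reported).
#' HETATM-tagged atoms (cofactors such as the \[NiFe\] site or FeS clusters)
#' are matched only against `hetero_charges`; without it they fall to
#' `default_entry` with a warning, since no standard table carries their
#' charges.  Free chain termini are optionally charged (+1 e on the
#' N-terminal N, -1 e on the C-terminal OXT, or O when OXT is absent).
#' The declared net charge is recomputed.  Re-applying the same table is a
#' no-op: charges are assigned, never incremented.
#'
#' @param model a [molecular_model()].
#' @param table a [default_forcefield()] table.
#' @param termini `"charged"` (default) or `"neutral"`.
#' @param hetero_charges optional data frame `residue_name, atom_name,
#'   charge` (and optionally `lj_epsilon`, `lj_rmin_half`) for tagged
#'   HETATM groups.
#' @return the parameterized model; `attr(, "parameterization")` reports the
#'   number and indices of default-parameterized atoms.
#' @export
parameterize <- function(model, table = default_forcefield(),
                         termini = c("charged", "neutral"),
                         hetero_charges = NULL) {
  stopifnot(inherits(model, "molecular_model"),
            inherits(table, "forcefield_table"))
  termini <- match.arg(termini)
  a <- model$atoms
  n <- nrow(a)
  ent <- table$entries
  de <- table$default_entry
  key_exact <- paste(ent$residue_name, ent$atom_name, sep = "\r")
  key_wild <- ent$residue_name[ent$atom_name == "*"]
  wild_rows <- which(ent$atom_name == "*")

  het <- has_tag(a$tags, "hetero")
  hkey <- if (!is.null(hetero_charges))
    paste(hetero_charges$residue_name, hetero_charges$atom_name, sep = "\r")

  charge <- numeric(n)
  eps <- numeric(n)
  rmin <- numeric(n)
  defaulted <- logical(n)
  for (i in seq_len(n)) {
    if (het[i]) {
      j <- if (!is.null(hetero_charges))
        match(paste(a$residue_name[i], a$atom_name[i], sep = "\r"), hkey)
      else NA_integer_
      if (!is.na(j)) {
        charge[i] <- hetero_charges$charge[j]
        eps[i] <- hetero_charges$lj_epsilon[j] %||% de$lj_epsilon
        rmin[i] <- hetero_charges$lj_rmin_half[j] %||% de$lj_rmin_half
      } else {
        charge[i] <- de$charge; eps[i] <- de$lj_epsilon
        rmin[i] <- de$lj_rmin_half; defaulted[i] <- TRUE
      }
      next
    }
    j <- match(paste(a$residue_name[i], a$atom_name[i], sep = "\r"), key_exact)
    if (is.na(j)) {
      w <- match(a$residue_name[i], key_wild)
      j <- if (is.na(w)) NA_integer_ else wild_rows[w]
    }
    if (!is.na(j)) {
      charge[i] <- ent$charge[j]; eps[i] <- ent$lj_epsilon[j]
      rmin[i] <- ent$lj_rmin_half[j]
    } else {
      charge[i] <- de$charge; eps[i] <- de$lj_epsilon
      rmin[i] <- de$lj_rmin_half; defaulted[i] <- TRUE
    }
  }

  if (any(defaulted & het) && is.null(hetero_charges))
    warning(sum(defaulted & het),
            " HETATM atoms parameterized with the default entry ",
            "(no hetero_charges supplied); cofactor charges default to ",
            de$charge)

  if (termini == "charged") {
    for (ch in unique(a$chain_id[!het])) {
      in_ch <- which(a$chain_id == ch & !het)
      rmin_res <- min(a$residue_number[in_ch])
      rmax_res <- max(a$residue_number[in_ch])
      nt <- in_ch[a$residue_number[in_ch] == rmin_res &
                    a$atom_name[in_ch] == "N"]
      if (length(nt)) charge[nt[1]] <- charge[nt[1]] + 1
      ct <- in_ch[a$residue_number[in_ch] == rmax_res &
                    a$atom_name[in_ch] == "OXT"]
      if (!length(ct))
        ct <- in_ch[a$residue_number[in_ch] == rmax_res &
                      a$atom_name[in_ch] == "O"]
      if (length(ct)) charge[ct[1]] <- charge[ct[1]] - 1
    }
  }

  a$charge <- charge
  a$lj_epsilon <- eps
  a$lj_rmin_half <- rmin
  model$atoms <- a
  model$net_charge <- sum(charge)
  attr(model, "parameterization") <-
    list(n_defaulted = sum(defaulted), defaulted_indices = which(defaulted))
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
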