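#' Append an ideal alpha-helical C-terminal extension
#'
#' Models a C-terminal stretch that is unresolved in the crystal structure
#' (here: the small subunit's hydrophobic tail carrying the Strep-tag II
#' peptide) as a Calpha-only trace on an ideal alpha helix: radius 2.3 Å,
#' rise 1.5 Å per residue, twist 100 degrees per residue.  The helix axis
#' continues the anchor residue's local chain direction (Calpha of the
#' anchor minus Calpha of the preceding residue in the same chain; +z if no
#' predecessor exists).  Appended atoms are named `CA`, numbered after the
#' anchor, tagged `"modeled"`, and parameterizable like any residue.
#'
#' @param model a [molecular_model()].
#' @param sequence one-letter amino-acid string (e.g. `"SAWSHPQFEK"`);
#'   empty string is a no-op.
#' @param anchor list with `chain_id` and `residue_number` of the anchor
#'   residue (which must have a CA atom), or `NULL` for the last residue of
#'   the last chain.
#' @return the extended model.
#' @export
append_cterm_helix <- function(model, sequence, anchor = NULL) {
  stopifnot(inherits(model, "molecular_model"))
  sequence <- gsub("\\s", "", sequence)
  if (nchar(sequence) == 0L) return(model)
  a <- model$atoms
  if (is.null(anchor)) {
    last_chain <- a$chain_id[nrow(a)]
    anchor <- list(chain_id = last_chain,
                   residue_number = max(a$residue_number[a$chain_id == last_chain]))
  }
  in_res <- a$chain_id == anchor$chain_id &
    a$residue_number == anchor$residue_number
  ca <- which(in_res & a$atom_name == "CA")
  if (!length(ca)) stop("anchor residue ", anchor$residue_number,
                        " in chain ", anchor$chain_id, " has no CA atom")
  p_anchor <- as.numeric(a[ca[1], c("x", "y", "z")])

  prev <- which(a$chain_id == anchor$chain_id &
                  a$residue_number == anchor$residue_number - 1L &
                  a$atom_name == "CA")
  axis <- if (length(prev)) {
    d <- p_anchor - as.numeric(a[prev[1], c("x", "y", "z")])
    d / sqrt(sum(d^2))
  } else c(0, 0, 1)

  # orthonormal frame (u, v) perpendicular to the axis
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])

  radius <- 2.3
  rise <- 1.5
  twist <- 100 * pi / 180
  nres <- nchar(sequence)
  aa1 <- strsplit(sequence, "")[[1]]
  aa3 <- bio3d::aa123(aa1)
  # anchor sits on the cylinder at turn 0 so the helix continues the chain
  origin <- p_anchor - radius * u
  t_idx <- seq_len(nres)
  pos <- t(vapply(t_idx, function(t)
    origin + rise * t * axis +
      radius * (cos(twist * t) * u + sin(twist * t) * v),
    numeric(3)))

  new_atoms <- data.frame(
    atom_name = "CA", element = "C", residue_name = aa3,
    residue_number = anchor$residue_number + t_idx,
    chain_id = anchor$chain_id,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    charge = 0, lj_epsilon = 0, lj_rmin_half = 0,
    tags = "modeled", stringsAsFactors = FALSE)
  model$atoms <- rbind(a, new_atoms)
  rownames(model$atoms) <- NULL
  model$selections$modeled <- which(has_tag(model$atoms$tags, "modeled"))
  model$net_charge <- sum(model$atoms$charge)
  model
}
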