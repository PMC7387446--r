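#' Atom collections
#'
#' An `atom_collection` is a data frame of atoms with columns `x`, `y`, `z`
#' (Angstrom), `element` (chemical symbol), `is_hydrogen`, `is_calpha`
#' (logical flags), `charge` (elementary charges, `NA` when unassigned) and
#' `radius` (Angstrom, 0 = point atom), plus optional `chain`, `resid`,
#' `resno`, `elety` bookkeeping columns retained from PDB input. The
#' `frame_note` attribute records coordinate-frame normalizations that have
#' been applied. The support plane is z = 0 and samples occupy z >= 0 after
#' grounding.
#'
#' @param x,y,z Numeric coordinate vectors in Angstrom.
#' @param element Character vector of chemical symbols (recycled).
#' @param is_hydrogen Logical flags; defaults to `element == "H"`.
#' @param is_calpha Logical flags; default all `FALSE`.
#' @param charge Per-atom partial charges in elementary charges (`NA` =
#'   unassigned).
#' @param radius Per-atom radii in Angstrom (default 0: point atoms).
#' @param frame_note Text tag recording applied normalizations.
#' @return An `atom_collection` object.
#' @export
#' @examples
#' ac <- atom_collection(x = c(0, 1), y = c(0, 0), z = c(0, 5))
#' nrow(ac)
atom_collection <- function(x, y, z, element = "C",
                            is_hydrogen = NULL, is_calpha = FALSE,
                            charge = NA_real_, radius = 0,
                            frame_note = "raw") {
  n <- length(x)
  if (n == 0L) stop("atom_collection must contain at least one atom",
                    call. = FALSE)
  if (length(y) != n || length(z) != n)
    stop("x, y, z must have equal length", call. = FALSE)
  .stopifnot_finite(c(x, y, z), "coordinates")
  element <- rep_len(as.character(element), n)
  if (is.null(is_hydrogen)) is_hydrogen <- toupper(element) == "H"
  df <- data.frame(
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    element = element,
    is_hydrogen = rep_len(as.logical(is_hydrogen), n),
    is_calpha = rep_len(as.logical(is_calpha), n),
    charge = rep_len(as.numeric(charge), n),
    radius = rep_len(as.numeric(radius), n),
    stringsAsFactors = FALSE
  )
  if (any(df$radius < 0)) stop("atom radius must be >= 0", call. = FALSE)
  structure(df, class = c("atom_collection", "data.frame"),
            frame_note = frame_note)
}

.assert_atoms <- function(atoms) {
  if (!inherits(atoms, "atom_collection"))
    stop("expected an 'atom_collection'", call. = FALSE)
  if (nrow(atoms) == 0L) stop("empty atom collection", call. = FALSE)
  invisible(atoms)
}

#' @export
print.atom_collection <- function(x, ...) {
  cat(sprintf("<atom_collection> %d atoms (%d heavy, %d C-alpha)\n",
              nrow(x), sum(!x$is_hydrogen), sum(x$is_calpha)))
  cat(sprintf("  frame: %s\n", attr(x, "frame_note")))
  zr <- range(x$z)
  cat(sprintf("  z range: [%.2f, %.2f] Angstrom; charges: %s\n",
              zr[1], zr[2],
              if (all(is.na(x$charge))) "unassigned" else
                sprintf("net %+.2f e", sum(x$charge, na.rm = TRUE))))
  invisible(x)
}

#' Keep only heavy (non-hydrogen) atoms
#'
#' @param atoms An `atom_collection`.
#' @return The collection restricted to atoms with `is_hydrogen == FALSE`.
#' @export
heavy_atoms <- function(atoms) {
  .assert_atoms(atoms)
  out <- atoms[!atoms$is_hydrogen, , drop = FALSE]
  if (nrow(out) == 0L) stop("no heavy atoms present", call. = FALSE)
  attr(out, "frame_note") <- attr(atoms, "frame_note")
  class(out) <- class(atoms)
  out
}

#' Read an atomic model from a PDB file
#'
#' Parses a (possibly multi-model) PDB file via \pkg{bio3d} and returns an
#' [atom_collection()] with hydrogen and C-alpha atoms flagged and
#' chain/residue identity retained.
#'
#' @param path Path to a PDB file.
#' @param model_index 1-based model number for multi-model files.
#' @return An `atom_collection`.
#' @export
read_structure <- function(path, model_index = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("could not parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  nmod <- nrow(pdb$xyz)
  if (is.null(nmod)) nmod <- 1L
  if (model_index < 1L || model_index > nmod)
    stop(sprintf("model_index %d out of range (file has %d model(s))",
                 model_index, nmod), call. = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0L) stop("PDB file contains no atoms", call. = FALSE)
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    # fall back on the first letter of the atom name
    elem <- sub("^[0-9]*", "", at$elety)
    elem <- substr(elem, 1, 1)
  }
  elem <- toupper(trimws(elem))
  ac <- atom_collection(
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = elem,
    is_hydrogen = elem == "H",
    is_calpha = trimws(at$elety) == "CA" & elem != "CA",  # exclude calcium
    frame_note = sprintf("as-read:%s", basename(path))
  )
  ac$chain <- at$chain
  ac$resid <- at$resid
  ac$resno <- at$resno
  ac$elety <- trimws(at$elety)
  ac
}

#' Write an atom collection to a PDB file
#'
#' @param atoms An `atom_collection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(atoms, path) {
  .assert_atoms(atoms)
  n <- nrow(atoms)
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  elety <- if ("elety" %in% names(atoms)) atoms$elety else atoms$element
  resid <- if ("resid" %in% names(atoms)) atoms$resid else rep("UNK", n)
  resno <- if ("resno" %in% names(atoms)) atoms$resno else seq_len(n)
  chain <- if ("chain" %in% names(atoms)) atoms$chain else rep("A", n)
  bio3d::write.pdb(file = path, xyz = xyz, type = "ATOM",
                   resno = resno, resid = resid, chain = chain,
                   elety = elety, elesy = atoms$element)
  invisible(path)
}

#' Ground a structure on the support plane
#'
#' Recenters the collection at (x = 0, y = 0) (all-atom centroid) and
#' translates along +z until the minimum z over C-alpha atoms is 0. For
#' models without C-alpha atoms (e.g. synthetic particles) the all-atom
#' minimum z is used and recorded in the `frame_note`.
#'
#' @param atoms An `atom_collection`.
#' @return The grounded `atom_collection` (idempotent).
#' @export
#' @examples
#' ac <- atom_collection(x = 1:3, y = 1:3, z = c(5, 7, 9), is_calpha = TRUE)
#' ground_structure(ac)$z
ground_structure <- function(atoms) {
  .assert_atoms(atoms)
  dx <- mean(atoms$x)
  dy <- mean(atoms$y)
  if (any(atoms$is_calpha)) {
    dz <- min(atoms$z[atoms$is_calpha])
    note <- "grounded:min-CA-z=0"
  } else {
    dz <- min(atoms$z)
    note <- "grounded:min-z=0 (no CA atoms; all-atom fallback)"
  }
  out <- atoms
  out$x <- atoms$x - dx
  out$y <- atoms$y - dy
  out$z <- atoms$z - dz
  attr(out, "frame_note") <- note
  out
}

#' Assign formal charges at pH 7 charge-center atoms
#'
#' Applies the integer formal-charge scheme for a standard pH-7 protein:
#' Asp -1 (at CG), Glu -1 (at CD), Lys +1 (at NZ), Arg +1 (at CZ), His 0,
#' +1 at each chain's N-terminal backbone N and -1 at its C-terminal
#' carboxylate (OXT if present, else C). All other atoms get charge 0.
#' Intended for order-of-magnitude macrodipole estimates; force-field
#' partial charges on equilibrated structures will differ.
#'
#' @param atoms An `atom_collection` read from a PDB file (needs `resid`,
#'   `resno`, `chain`, `elety` columns).
#' @param termini Include the +1/-1 terminal charges? Default `TRUE`.
#' @return The collection with the `charge` column filled in.
#' @export
assign_formal_charges <- function(atoms, termini = TRUE) {
  .assert_atoms(atoms)
  need <- c("resid", "resno", "chain", "elety")
  if (!all(need %in% names(atoms)))
    stop("formal charges need PDB residue metadata (",
         paste(need, collapse = ", "), ")", call. = FALSE)
  ch <- rep(0, nrow(atoms))
  ch[atoms$resid == "ASP" & atoms$elety == "CG"] <- -1
  ch[atoms$resid == "GLU" & atoms$elety == "CD"] <- -1
  ch[atoms$resid == "LYS" & atoms$elety == "NZ"] <- +1
  ch[atoms$resid == "ARG" & atoms$elety == "CZ"] <- +1
  if (termini) {
    for (cid in unique(atoms$chain)) {
      idx <- which(atoms$chain == cid & !atoms$is_hydrogen)
      first_res <- atoms$resno[idx[1]]
      last_res <- atoms$resno[idx[length(idx)]]
      i_n <- idx[atoms$resno[idx] == first_res & atoms$elety[idx] == "N"]
      if (length(i_n)) ch[i_n[1]] <- ch[i_n[1]] + 1
      i_oxt <- idx[atoms$resno[idx] == last_res & atoms$elety[idx] == "OXT"]
      if (!length(i_oxt))
        i_oxt <- idx[atoms$resno[idx] == last_res & atoms$elety[idx] == "C"]
      if (length(i_oxt)) ch[i_oxt[1]] <- ch[i_oxt[1]] - 1
    }
  }
  atoms$charge <- ch
  atoms
}

#' Macrodipole moment of a charged atom collection
#'
#' Computes the electric dipole moment mu = sum q_i (r_i - r_0) about the
#' charge centroid r_0 = sum |q_i| r_i / sum |q_i| over heavy atoms
#' (hydrogens are excluded), converted to debye (1 e Angstrom = 4.8032 D).
#' For a net-neutral charge set the result is origin independent.
#'
#' @param atoms An `atom_collection` whose heavy atoms all carry a
#'   `charge` value (see [assign_formal_charges()]).
#' @return Numeric length-3 dipole vector in debye, with attribute
#'   `"magnitude"` (debye).
#' @export
#' @examples
#' ac <- atom_collection(x = 0, y = 0, z = c(12.5, -12.5), charge = c(1, -1))
#' macrodipole(ac)  # (0, 0, 120.08) D
macrodipole <- function(atoms) {
  .assert_atoms(atoms)
  a <- atoms[!atoms$is_hydrogen, , drop = FALSE]
  if (nrow(a) == 0L) stop("no heavy atoms to sum over", call. = FALSE)
  if (any(is.na(a$charge)))
    stop("all heavy atoms must carry a partial charge; ",
         "see assign_formal_charges()", call. = FALSE)
  r <- as.matrix(a[, c("x", "y", "z")])
  q <- a$charge
  w <- abs(q)
  r0 <- if (sum(w) > 0) colSums(r * w) / sum(w) else colMeans(r)
  mu_eA <- colSums(q * sweep(r, 2, r0))   # e * Angstrom
  mu_D <- mu_eA * .const$eA_debye
  names(mu_D) <- c("x", "y", "z")
  attr(mu_D, "magnitude") <- sqrt(sum(mu_D^2))
  mu_D
}
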