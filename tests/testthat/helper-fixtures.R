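# Fixtures are built in code at test time; no binary data on disk.

# hand-written PDB text (fixed-column format), independent of any writer
pdb_line <- function(serial, name, res, chain, resno, x, y, z, elem) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, res, chain, resno, x, y, z, 1, 0, elem)
}

write_mini_pdb <- function(path = tempfile(fileext = ".pdb"),
                           with_hydrogens = FALSE) {
  lines <- c(
    pdb_line(1, "N",  "ALA", "A", 1, 11.104, 6.134, -6.504, "N"),
    pdb_line(2, "CA", "ALA", "A", 1, 12.000, 5.000,  7.250, "C"),
    pdb_line(3, "C",  "ALA", "A", 1, -3.500, 0.125,  2.000, "C")
  )
  if (with_hydrogens) {
    lines <- c(lines, pdb_line(4, "H", "ALA", "A", 1, 11.5, 6.5, -6.0, "H"))
  }
  writeLines(c(lines, "END"), path)
  path
}

# random point-atom scene inside a window, grounded convention (z >= 0)
random_scene <- function(n_atoms, seed, half_width = 15, z_max = 20) {
  set.seed(seed)
  atom_collection(
    x = runif(n_atoms, -half_width, half_width),
    y = runif(n_atoms, -half_width, half_width),
    z = runif(n_atoms, 0, z_max),
    frame_note = sprintf("random-scene seed=%d", seed)
  )
}

# expected single-atom spherical-cap profile: apparent height at lateral
# offset rho from a point atom at height h under an apex of radius R
cap_profile <- function(rho, h, R) pmax(0, h + sqrt(pmax(R^2 - rho^2, 0)) - R)
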