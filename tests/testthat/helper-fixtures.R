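# In-code fixtures: hand-written structure files and profile generators.

# One fixed-column PDB ATOM record (columns per the PDB v3 standard).
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          elem = substr(name, 1, 1), altloc = " ",
                          insert = " ", record = "ATOM  ") {
  sprintf("%-6s%5d %s%-3s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial,
          if (nchar(name) >= 4) "" else " ",
          name, altloc, resn, chain, resno, insert, x, y, z, 1, 0, elem)
}

# 2-residue fixture: ALA 1 (N, CA), GLY 2 (N, CA), chain A.
mini_pdb_lines <- function() c(
  pdb_atom_line(1, "N",  "ALA", "A", 1, 0, 0, 0),
  pdb_atom_line(2, "CA", "ALA", "A", 1, 2, 0, 0, elem = "C"),
  pdb_atom_line(3, "N",  "GLY", "A", 2, 0, 4, 0),
  pdb_atom_line(4, "CA", "GLY", "A", 2, 0, 6, 0, elem = "C"),
  "END")

write_mini_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(mini_pdb_lines(), path)
  path
}

# Same two residues as mmCIF.
write_mini_cif <- function(path = tempfile(fileext = ".cif")) {
  hdr <- c("data_MINI", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id",
                    "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                    "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                    "auth_seq_id", "auth_comp_id", "auth_asym_id",
                    "auth_atom_id", "pdbx_PDB_model_num")))
  row <- function(id, el, at, resn, seq, x, y, z)
    sprintf("ATOM %d %s %s . %s A 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s A %s 1",
            id, el, at, resn, seq, x, y, z, seq, resn, at)
  writeLines(c(hdr,
               row(1, "N", "N",  "ALA", 1, 0, 0, 0),
               row(2, "C", "CA", "ALA", 1, 2, 0, 0),
               row(3, "N", "N",  "GLY", 2, 0, 4, 0),
               row(4, "C", "CA", "GLY", 2, 0, 6, 0),
               "#"), path)
  path
}

# Two cysteines whose SG atoms sit a chosen distance apart.
write_cys_pdb <- function(sg_dist, resno = c(3, 9),
                          path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    pdb_atom_line(1, "CA", "CYS", "A", resno[1], 0, 0, 0, elem = "C"),
    pdb_atom_line(2, "SG", "CYS", "A", resno[1], 1, 0, 0, elem = "S"),
    pdb_atom_line(3, "CA", "CYS", "A", resno[2], 1 + sg_dist, 1, 0,
                  elem = "C"),
    pdb_atom_line(4, "SG", "CYS", "A", resno[2], 1 + sg_dist, 0, 0,
                  elem = "S"),
    "END"), path)
  path
}

# Random normalized profile (Gamma draws, strictly positive).
rand_profile <- function(n, role = "O") {
  v <- stats::rgamma(n, shape = 2) + 1e-6
  hydro_profile(v, role = role)
}

# Independent O(N^2) double-loop oracle for the observed profile
# (unnormalized Levitt sums; no epsilon handling).
observed_oracle <- function(xyz, h, cutoff = 9) {
  n <- nrow(xyz)
  o <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r <= cutoff) {
        q <- r / cutoff
        o[i] <- o[i] + (h[i] + h[j]) *
          (1 - 0.5 * (7 * q^2 - 9 * q^4 + 5 * q^6 - q^9))
      }
    }
  }
  o
}

# Independent direct-summation KL oracle.
kl_oracle <- function(p, q, base = 2) {
  s <- 0
  for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log(p[i] / q[i], base)
  s
}
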