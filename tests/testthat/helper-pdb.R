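# Build multi-atom PDB text in code so structure parsing can be tested
# without stored files. `atoms` is a data.frame with chain, resno, aa,
# elety, x, y, z and optionally alt, occ, element.

write_test_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  alt <- if ("alt" %in% names(atoms)) atoms$alt else rep(" ", nrow(atoms))
  occ <- if ("occ" %in% names(atoms)) atoms$occ else rep(1, nrow(atoms))
  el <- if ("element" %in% names(atoms))
    atoms$element else substr(gsub("[0-9]", "", atoms$elety), 1, 1)
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    nm <- atoms$elety[i]
    nm4 <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
    sprintf("ATOM  %5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, nm4, alt[i], atoms$aa[i], atoms$chain[i], atoms$resno[i],
            atoms$x[i], atoms$y[i], atoms$z[i], occ[i], 0, el[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# a two-residue, multi-atom toy structure
toy_atoms <- function() {
  data.frame(
    chain = "A",
    resno = c(1, 1, 1, 2, 2, 2, 2),
    aa    = c("GLY", "GLY", "GLY", "ALA", "ALA", "ALA", "ALA"),
    elety = c("N", "CA", "C", "N", "CA", "C", "CB"),
    x = c(0, 2, 1, 10, 12, 11, 11),
    y = c(0, 0, 3, 0, 0, 3, 1),
    z = c(0, 0, 0, 0, 0, 0, 4),
    stringsAsFactors = FALSE)
}
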