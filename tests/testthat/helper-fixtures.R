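# In-code PDB fixtures: format a C-alpha ATOM line and write toy files.

pdb_ca_line <- function(serial, resnum, x, y, z, chain = "A", b = 0,
                        resname = "ALA", altloc = " ", icode = " ",
                        name = " CA ") {
  sprintf("ATOM  %5d %4s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, altloc, resname, chain, resnum, icode,
          x, y, z, 1.00, b, "C")
}

write_toy_pdb <- function(lines, path = withr::local_tempfile(
                            fileext = ".pdb",
                            .local_envir = parent.frame())) {
  writeLines(c(lines, "END"), path)
  path
}

# A random compact cloud of residues for similarity property tests.
random_structure <- function(n, spread = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ca_structure("A", seq_len(n),
               matrix(stats::runif(3 * n, 0, spread), ncol = 3),
               source_id = "random")
}

random_interface <- function(name, s, size) {
  interface(name, sample(s$residues, size))
}
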