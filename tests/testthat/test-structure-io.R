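test_that("write/read round-trip preserves residue keys and Ca coordinates", {
  g <- make_ig_domain(sandwich_spec("V_set"))
  f <- tempfile(fileext = ".pdb")
  write_structure(g$structure, f)
  st2 <- read_structure(f, format = "pdb")
  tr1 <- extract_ca(g$structure, "A")
  tr2 <- extract_ca(st2, "A")
  expect_equal(tr2$resno, tr1$resno)
  expect_equal(tr2$ins, tr1$ins)
  expect_lt(max(abs(tr2$xyz - tr1$xyz)), 1e-3)  # PDB fixed-width precision
  # independent text scan: Ca atom lines in the file match the trace length
  n_ca <- sum(grepl("^ATOM", readLines(f)) &
              substr(readLines(f), 13, 16) == " CA ")
  expect_equal(n_ca, nrow(tr1$xyz))
})

test_that("format auto-detection and mmCIF parsing give the same model", {
  g <- make_ig_domain(sandwich_spec("C1_set"))
  f <- tempfile(fileext = ".pdb")
  write_structure(g$structure, f)
  st_auto <- read_structure(f)
  expect_s3_class(st_auto, "StructureModel")
  expect_equal(structure_chains(st_auto), "A")
  cif <- tempfile(fileext = ".cif")
  at <- g$structure$atoms
  lines <- c(
    "data_synthetic", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s %s . %s A 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s A %s 1",
            seq_len(nrow(at)), at$elesy, at$elety, at$resid, at$resno,
            at$x, at$y, at$z, at$resno, at$resid, at$elety),
    "#")
  writeLines(lines, cif)
  st_cif <- read_structure(cif, format = "mmcif")
  trc <- extract_ca(st_cif, "A")
  trp <- extract_ca(g$structure, "A")
  expect_equal(nrow(trc$xyz), nrow(trp$xyz))
  expect_lt(max(abs(trc$xyz - trp$xyz)), 1e-3)
})

test_that("altloc resolution keeps the highest occupancy and MSE maps to MET", {
  f <- tempfile(fileext = ".pdb")
  fmt <- function(serial, name, alt, res, resno, x, occ, elem, rec = "ATOM  ")
    sprintf("%s%5d %-4s%s%3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, name, alt, res, resno, x, 0, 0, occ, 0, elem)
  writeLines(c(
    fmt(1, " N  ", " ", "ALA", 1, 0.0, 1, "N"),
    fmt(2, " CA ", "A", "ALA", 1, 1.0, 0.4, "C"),
    fmt(3, " CA ", "B", "ALA", 1, 2.0, 0.6, "C"),
    fmt(4, " N  ", " ", "MSE", 2, 3.0, 1, "N", "HETATM"),
    fmt(5, " CA ", " ", "MSE", 2, 4.0, 1, "C", "HETATM"),
    fmt(6, " O  ", " ", "HOH", 3, 9.0, 1, "O", "HETATM"),
    "END"), f)
  st <- read_structure(f, format = "pdb")
  ca1 <- st$atoms[st$atoms$resno == 1 & st$atoms$elety == "CA", ]
  expect_equal(nrow(ca1), 1)
  expect_equal(ca1$x, 2.0)                    # occupancy 0.6 wins
  expect_true("MET" %in% st$atoms$resid)      # MSE retained as parent MET
  expect_false("HOH" %in% st$atoms$resid)     # water dropped
})

test_that("residues lacking a Ca are excluded from the trace", {
  g <- make_ig_domain(sandwich_spec("C2_set", atom_mode = "full"))
  at <- g$structure$atoms
  drop <- at$resno == 25 & at$elety == "CA"
  st <- new_structure(at[!drop, , drop = FALSE])
  tr <- extract_ca(st, "A")
  expect_false(25 %in% tr$resno)
  expect_equal(nrow(tr$xyz), length(unique(at$resno)) - 1)
})

test_that("extract_ca restricts to a closed interval and validates input", {
  g <- make_ig_domain(sandwich_spec("V_set"))
  tr <- extract_ca(g$structure, "A", range = c(12, 17))
  expect_equal(tr$resno, 12:17)
  expect_error(extract_ca(g$structure, "Z"), "unknown chain")
  expect_error(extract_ca(g$structure, "A", range = c(900, 950)), "empty selection")
})

test_that("FASTA export writes one record per sequence", {
  f <- tempfile(fileext = ".fasta")
  write_fasta(c(p1 = "ACDEF", p2 = "GHIKL"), f)
  txt <- readLines(f)
  expect_equal(sum(grepl("^>", txt)), 2)
  g <- make_ig_domain(sandwich_spec("V_set"))
  seq <- chain_sequence(g$structure, "A")
  expect_equal(nchar(seq), nrow(extract_ca(g$structure, "A")$xyz))
  expect_match(seq, "^[A-Z]+$")
})
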