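#' @importFrom stats setNames
NULL

# amino-acid code tables; non-standard residues with Ca are mapped to a parent
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q", GLU = "E",
  GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
  PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "C", PYL = "K", HYP = "P", MLY = "K", SEP = "S",
  TPO = "T", PTR = "Y", CSO = "C"
)
.parent3 <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO", MLY = "LYS",
              SEP = "SER", TPO = "THR", PTR = "TYR", CSO = "CYS")

#' Read a protein structure into a uniform coordinate model
#'
#' Parses a PDB or mmCIF file (via bio3d) into a `StructureModel`: an atom
#' table in file order carrying the original residue numbering. Waters and
#' ligands are dropped; non-standard amino acids with a Ca atom (e.g. MSE) are
#' retained and mapped to their parent residue. Alternate locations are
#' resolved to the highest occupancy, ties to the first listed. Only the first
#' model of multi-model files is used.
#'
#' @param path file path.
#' @param format one of `"auto"` (by extension), `"pdb"`, `"mmcif"`.
#' @return an object of class `StructureModel`: a list with elements `id`
#'   (basename of the file) and `atoms`, a data.frame with columns `chain`,
#'   `resno`, `ins`, `resid` (3-letter), `elety` (atom name), `elesy`
#'   (element), `x`, `y`, `z`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "mmcif") suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    else bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse '", path, "' as ", format, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: ", path)
  # first model only (bio3d already collapses to model 1 with multi = FALSE;
  # read.cif keeps a model column in some dialects)
  if (!is.null(at$model)) at <- at[at$model == at$model[1] | is.na(at$model), , drop = FALSE]
  keep <- at$type == "ATOM" | at$resid %in% names(.parent3)
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure (no polymer atoms): ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc: highest occupancy, ties to first listed
  if (any(at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    ord <- order(key, -at$o, seq_len(nrow(at)))
    file_pos <- seq_len(nrow(at))[ord]
    at <- at[ord, , drop = FALSE]
    keep <- !duplicated(paste(at$chain, at$resno, at$insert, at$elety))
    at <- at[keep, , drop = FALSE]
    at <- at[order(file_pos[keep]), , drop = FALSE]
  }
  resid <- at$resid
  resid[resid %in% names(.parent3)] <- .parent3[resid[resid %in% names(.parent3)]]
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)))
    elesy <- sub("^[0-9]*([A-Za-z]).*$", "\\1", at$elety)
  atoms <- data.frame(
    chain = as.character(at$chain), resno = as.integer(at$resno),
    ins = as.character(at$insert), resid = resid,
    elety = as.character(at$elety), elesy = toupper(as.character(elesy)),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$elesy != "H", , drop = FALSE]
  new_structure(atoms, id = sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path),
                                ignore.case = TRUE))
}

#' Construct a StructureModel from an atom table
#'
#' @param atoms data.frame with columns chain, resno, ins, resid, elety,
#'   elesy, x, y, z.
#' @param id identifier string.
#' @return a `StructureModel`.
#' @export
new_structure <- function(atoms, id = "structure") {
  needed <- c("chain", "resno", "ins", "resid", "elety", "elesy", "x", "y", "z")
  stopifnot(all(needed %in% names(atoms)))
  structure(list(id = id, atoms = atoms), class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  rk <- unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$ins))
  cat("StructureModel '", x$id, "': ", length(unique(x$atoms$chain)),
      " chain(s), ", length(rk), " residues, ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Chains of a structure
#' @param structure a `StructureModel`.
#' @return character vector of chain identifiers in file order.
#' @export
structure_chains <- function(structure) unique(structure$atoms$chain)

# residue table of one chain, in file order; flags residues lacking a Ca
residue_table <- function(structure, chain_id) {
  at <- structure$atoms[structure$atoms$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0) stop("unknown chain: ", chain_id)
  key <- paste(at$resno, at$ins, sep = "|")
  first <- !duplicated(key)
  res <- data.frame(resno = at$resno[first], ins = at$ins[first],
                    resid = at$resid[first], stringsAsFactors = FALSE)
  ca <- at[at$elety == "CA", , drop = FALSE]
  cakey <- paste(ca$resno, ca$ins, sep = "|")
  m <- match(paste(res$resno, res$ins, sep = "|"), cakey)
  res$has_ca <- !is.na(m)
  res$x <- ca$x[m]; res$y <- ca$y[m]; res$z <- ca$z[m]
  res
}

#' Extract the Ca trace of a chain
#'
#' A pure projection: positions are taken as-is (never modified or
#' interpolated), residues lacking a Ca atom are excluded, gaps in the
#' numbering are preserved as absent keys.
#'
#' @param structure a `StructureModel`.
#' @param chain_id chain identifier.
#' @param range optional length-2 integer vector: closed residue interval in
#'   source numbering.
#' @return an object of class `CaTrace`: list with `chain_id`, `resno`, `ins`,
#'   `resid`, and `xyz` (n x 3 matrix, Angstrom), index-aligned.
#' @export
extract_ca <- function(structure, chain_id, range = NULL) {
  res <- residue_table(structure, chain_id)
  res <- res[res$has_ca, , drop = FALSE]
  if (!is.null(range)) {
    stopifnot(length(range) == 2)
    res <- res[res$resno >= range[1] & res$resno <= range[2], , drop = FALSE]
  }
  if (nrow(res) == 0) stop("empty selection for chain ", chain_id)
  structure(list(chain_id = chain_id, resno = res$resno, ins = res$ins,
                 resid = res$resid,
                 xyz = unname(cbind(res$x, res$y, res$z))),
            class = "CaTrace")
}

#' One-letter sequence of a chain
#' @inheritParams extract_ca
#' @return character scalar (unknown residues become `X`).
#' @export
chain_sequence <- function(structure, chain_id) {
  res <- residue_table(structure, chain_id)
  aa <- .aa3to1[res$resid]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Write a StructureModel to a PDB file
#'
#' @param structure a `StructureModel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  at <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$resno, resid = at$resid, chain = at$chain,
    insert = ifelse(at$ins == "", NA, at$ins),
    elety = at$elety, elesy = at$elesy
  )
  invisible(path)
}

#' Write per-chain (or arbitrary) sequences to FASTA
#'
#' @param seqs named character vector of one-letter sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (requireNamespace("seqinr", quietly = TRUE)) {
    seqinr::write.fasta(lapply(seqs, function(s) strsplit(s, "")[[1]]),
                        names = names(seqs), file.out = path)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  }
  invisible(path)
}

# residue key formatting used in reports
rkey <- function(resno, ins) paste0(resno, ifelse(is.na(ins) | ins == "", "", ins))
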