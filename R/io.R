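#' Read a multi-model PDB file into an ensemble
#'
#' Parses ATOM records of a (possibly multi-model) PDB file. Only the first
#' chain is read; alternate locations take conformer 'A'; hydrogens are
#' dropped on input. One `conformer` is produced per MODEL (or a single one
#' when no MODEL records are present). All models must contain the same atom
#' records, the usual layout of conformer ensembles and trajectory snapshots.
#'
#' @param path PDB file path.
#' @return An [ensemble()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  at <- pdb$atom
  at_idx <- seq_len(nrow(at))
  keep <- at$type == "ATOM"
  # first chain only, alt-loc A (or blank)
  ch <- at$chain[keep][1]
  keep <- keep & (at$chain == ch | is.na(at$chain))
  keep <- keep & (is.na(at$alt) | at$alt %in% c("", "A"))
  keep <- keep & !(at$elesy %in% "H") & !grepl("^[0-9]*H", at$elety)
  if (!any(keep)) stop("no ATOM records found in ", path)
  at <- at[keep, ]
  at_idx <- at_idx[keep]

  resid_raw <- at$resno
  resid <- as.integer(factor(resid_raw, levels = unique(resid_raw)))
  n <- max(resid)
  aa1 <- aa_three_to_one(at$resid[match(seq_len(n), resid)])

  nmod <- nrow(pdb$xyz)
  confs <- lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)[at_idx, , drop = FALSE]
    atoms <- tibble::tibble(resid = resid, elety = at$elety,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    ca_res <- unique(atoms$resid[atoms$elety == "CA"])
    missing <- setdiff(seq_len(n), ca_res)
    if (length(missing) > 0L)
      stop("residue ", missing[1L], " has no CA atom in ", path)
    conformer(atoms, sequence = aa1,
              id = paste0(basename(path), "#", m))
  })
  ensemble(confs)
}

aa_three_to_one <- function(three) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  out <- tab[toupper(three)]
  out[is.na(out)] <- "X"
  unname(out)
}

aa_one_to_three <- function(one) {
  tab <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  out <- tab[toupper(one)]
  out[is.na(out)] <- "UNK"
  unname(out)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Fixed-width ATOM records (Angstrom, 3 decimals); one MODEL/ENDMDL block per
#' conformer. Residue numbering is 1-based. Reading the file back reproduces
#' coordinates to the format precision (1e-3 Angstrom).
#'
#' @param x An [ensemble()] or single [conformer()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "conformer")) x <- ensemble(list(x))
  stopifnot(inherits(x, "ensemble"))
  if (length(x) == 0L) stop("cannot write an empty ensemble")
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(x)) {
    cf <- x[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    at <- cf$atoms
    res3 <- aa_one_to_three(cf$sequence)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)),
      ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety),
      res3[at$resid], at$resid, at$x, at$y, at$z,
      substr(at$elety, 1, 1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a CA-only XYZ trace file
#'
#' Plain XYZ format: first line the atom count, second a comment, then one
#' `element x y z` line per CA; repeated per frame for trajectories.
#'
#' @param path XYZ file path.
#' @return An [ensemble()] of CA-only conformers.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  confs <- list()
  i <- 1L
  while (i <= length(ln)) {
    n <- suppressWarnings(as.integer(trimws(ln[i])))
    if (is.na(n)) stop("malformed XYZ header at line ", i)
    block <- ln[(i + 2L):(i + 1L + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    xyz <- matrix(as.numeric(parts[, 2:4]), ncol = 3)
    confs[[length(confs) + 1L]] <-
      conformer_from_ca(xyz, id = paste0(basename(path), "#", length(confs) + 1L))
    i <- i + 2L + n
  }
  if (length(confs) == 0L) stop("no frames in ", path)
  ensemble(confs)
}

#' Write CA traces of an ensemble in XYZ format
#'
#' @param x An [ensemble()] or [conformer()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(x, path) {
  if (inherits(x, "conformer")) x <- ensemble(list(x))
  stopifnot(inherits(x, "ensemble"), length(x) > 0L)
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in unclass(x)) {
    m <- ca_coords(cf)
    writeLines(as.character(nrow(m)), con)
    writeLines(cf$id, con)
    writeLines(sprintf("CA %12.6f %12.6f %12.6f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}
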