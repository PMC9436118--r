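# Structure I/O: the residue/atom data model every other module consumes.
# PDB parsing and writing are delegated to bio3d; this layer enforces the
# package's conventions: heavy atoms only, one altloc, one chain, pLDDT
# carried per residue, and a 1-based sequence index that is distinct from
# the author residue number.

#' Construct a StructureModel
#'
#' A `StructureModel` is an ordered set of protein residues with heavy-atom
#' coordinates (Angstrom), author residue numbers, and optional per-residue
#' pLDDT confidence. All positional APIs in this package address residues by
#' the 1-based *sequence index* (`res_index`), not by author numbering
#' (`resno`): the MSA is indexed by query position while PDB files carry
#' arbitrary author numbers, and conflating the two is the classic silent
#' error in MSA-driven mutagenesis. Author numbers are retained only for
#' matching predicted models against experimental references.
#'
#' @param atoms data.frame with columns `res_index` (integer, 1-based,
#'   consecutive per residue), `resno` (author number), `resid` (3-letter
#'   residue name), `elety` (atom name, unique within a residue),
#'   `x`, `y`, `z` (Angstrom).
#' @param plddt optional numeric vector, one value in \[0, 100\] per residue.
#' @param model_id opaque identifier.
#' @param source_path file of origin, if any.
#' @return object of class `StructureModel`.
#' @export
structure_model <- function(atoms, plddt = NULL, model_id = "model",
                            source_path = NA_character_) {
  stopifnot(is.data.frame(atoms),
            all(c("res_index", "resno", "resid", "elety", "x", "y", "z")
                %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("StructureModel with zero atoms")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  idx <- unique(atoms$res_index)
  if (!identical(as.integer(idx), seq_along(idx))) {
    stop("res_index must be consecutive 1-based integers in file order")
  }
  res <- atoms[!duplicated(atoms$res_index), c("res_index", "resno", "resid")]
  names(res) <- c("index", "resno", "name")
  rownames(res) <- NULL
  if (is.unsorted(res$resno, strictly = TRUE)) {
    stop("author residue numbers must be strictly increasing within the chain")
  }
  dup <- stats::aggregate(elety ~ res_index, atoms,
                          function(e) anyDuplicated(e) > 0L)
  if (any(dup$elety)) {
    stop("duplicated atom names within residue(s): ",
         paste(dup$res_index[dup$elety], collapse = ", "))
  }
  if (!is.null(plddt)) {
    if (length(plddt) != nrow(res)) {
      stop("plddt length (", length(plddt), ") != residue count (",
           nrow(res), ")")
    }
    ok <- is.na(plddt) | (plddt >= 0 & plddt <= 100)
    if (!all(ok)) stop("pLDDT outside [0, 100]")
    res$plddt <- as.numeric(plddt)
  } else {
    res$plddt <- NA_real_
  }
  structure(list(model_id = model_id, atoms = atoms, residues = res,
                 source_path = source_path),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel", sQuote(x$model_id), "-", nrow(x$residues),
      "residues,", nrow(x$atoms), "heavy atoms\n")
  if (!all(is.na(x$residues$plddt))) {
    cat("  mean pLDDT:", round(mean(x$residues$plddt, na.rm = TRUE), 1), "\n")
  }
  invisible(x)
}

#' Number of residues in a model
#' @param model StructureModel.
#' @export
n_residues <- function(model) nrow(model$residues)

# 3-letter -> 1-letter; common modified residues mapped to their parent.
aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  MSE = "M", SEP = "S", TPO = "T", PTR = "Y", CSO = "C", HYP = "P",
  MLY = "K", M3L = "K", KCX = "K", PCA = "E", CME = "C", CSX = "C"
)

aa_one_to_three <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

#' Extract the query sequence of a model
#'
#' One letter per residue, in sequence-index order; residues without a known
#' 1-letter mapping become `"X"`.
#'
#' @param model StructureModel.
#' @return character scalar of length `n_residues(model)`.
#' @export
query_sequence <- function(model) {
  one <- aa_three_to_one[toupper(model$residues$name)]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Read a predicted or experimental model from PDB
#'
#' Reads a single protein chain from a PDB file into a [structure_model()].
#' Hydrogens are dropped everywhere; for alternate locations only the
#' highest-occupancy conformer is kept, so distances are deterministic.
#' AlphaFold2-class predictors store per-residue pLDDT in the B-factor
#' column; with `plddt_from_bfactor = TRUE` the Calpha B-factor becomes the
#' residue's pLDDT.
#'
#' @param path PDB file.
#' @param chain chain identifier; default is the first chain containing
#'   protein residues. Files with several protein chains require an explicit
#'   selector.
#' @param plddt_from_bfactor read pLDDT from the Calpha B-factor.
#' @param model_id identifier; defaults to the file name.
#' @param require_single_chain error (rather than silently picking the
#'   first) when several protein chains are present and `chain` is `NULL`.
#' @return StructureModel.
#' @export
read_model <- function(path, chain = NULL, plddt_from_bfactor = TRUE,
                       model_id = NULL, require_single_chain = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(model_id)) {
    model_id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  }
  # altlocs are resolved here (highest occupancy), so bio3d's ALT notice
  # is redundant
  pdb <- withCallingHandlers(
    bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    warning = function(w) {
      if (grepl("ALT", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  at <- pdb$atom
  known <- at$resid %in% names(aa_three_to_one)
  at <- at[known & (at$type == "ATOM" | at$resid == "MSE"), , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("no parseable protein residues in ", path,
         " (non-protein-only file?)")
  }
  prot_chains <- unique(at$chain)
  if (is.null(chain)) {
    if (length(prot_chains) > 1L && require_single_chain) {
      stop("multiple protein chains (", paste(prot_chains, collapse = ", "),
           ") in ", path, "; supply `chain`")
    }
    chain <- prot_chains[1L]
  } else if (!chain %in% prot_chains) {
    stop("chain ", sQuote(chain), " has no protein residues in ", path)
  }
  at <- at[at$chain %in% chain, , drop = FALSE]
  # drop hydrogens (element symbol if present, else atom-name heuristic)
  elesy <- trimws(at$elesy)
  hyd <- if (any(nzchar(elesy))) {
    toupper(elesy) %in% c("H", "D")
  } else {
    grepl("^[0-9]*H", trimws(at$elety))
  }
  at <- at[!hyd, , drop = FALSE]
  # altlocs: keep highest occupancy per (resno, insert, atom name)
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(match(key, unique(key)), -occ)
  at <- at[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  rkey <- paste(at$resno, at$insert, sep = "\r")
  res_index <- match(rkey, unique(rkey))
  atoms <- data.frame(res_index = res_index,
                      resno = at$resno,
                      resid = toupper(at$resid),
                      elety = trimws(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  plddt <- NULL
  if (isTRUE(plddt_from_bfactor)) {
    ca <- at$elety == "CA"
    plddt <- rep(NA_real_, max(res_index))
    plddt[res_index[ca]] <- at$b[ca]
    if (all(is.na(plddt))) plddt <- NULL
  }
  structure_model(atoms, plddt = plddt, model_id = model_id,
                  source_path = path)
}

#' Write a model to PDB
#'
#' Residue pLDDT (when present) is written to the B-factor column of every
#' atom of the residue, so written models round-trip through [read_model()].
#'
#' @param model StructureModel.
#' @param path output file.
#' @param chain chain identifier to emit.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, chain = "A") {
  at <- model$atoms
  b <- model$residues$plddt[at$res_index]
  b[is.na(b)] <- 0
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno,
                   resid = at$resid,
                   elety = at$elety,
                   chain = rep(chain, nrow(at)),
                   o = rep(1, nrow(at)),
                   b = b)
  invisible(path)
}

#' Calpha coordinates of a model
#'
#' @param model StructureModel.
#' @param required error when a residue lacks a Calpha (superposition, PCA
#'   and TM-scoring all require one per residue).
#' @return `n_residues x 3` matrix; rows of residues without Calpha are `NA`
#'   when `required = FALSE`.
#' @export
ca_coords <- function(model, required = TRUE) {
  at <- model$atoms[model$atoms$elety == "CA", , drop = FALSE]
  n <- n_residues(model)
  m <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  m[at$res_index, ] <- as.matrix(at[, c("x", "y", "z")])
  if (required && anyNA(m)) {
    miss <- which(is.na(m[, 1]))
    stop("residue(s) without a Calpha atom: index ",
         paste(miss, collapse = ", "), " (resno ",
         paste(model$residues$resno[miss], collapse = ", "), ")")
  }
  m
}

#' Write a query sequence as FASTA
#' @param sequence 1-letter amino-acid string.
#' @param id header (without `>`).
#' @param path output file.
#' @export
write_query_fasta <- function(sequence, id, path) {
  writeLines(c(paste0(">", id), sequence), path)
  invisible(path)
}
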