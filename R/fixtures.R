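## Generators for synthetic proteomes and toy structures, plus the shipped
## filament fold-region sequences.

#' Generate a synthetic decoy proteome
#'
#' Sequences are drawn i.i.d. from a background model; given the same seed
#' the result (and any file written) is byte-identical across runs. An
#' optional true protein can be embedded at a seeded position in record
#' order, with `embedded|` prefixed to its identifier so downstream scans
#' can tell it from the decoys.
#'
#' @param n number of decoy sequences (0 allowed).
#' @param len fixed sequence length, or a function(n) returning n
#'   integer lengths (e.g. a log-normal sampler).
#' @param bg a [BackgroundModel-class].
#' @param seed integer seed.
#' @param embed optional single named sequence to embed.
#' @param path optional FASTA output path (wrapped at 60 columns).
#' @return an `AAStringSet` (invisibly also written to `path` if given).
#' @export
generateSyntheticProteome <- function(n, len = 300L,
                                      bg = uniformBackground(), seed = 1L,
                                      embed = NULL, path = NULL) {
  if (n < 0L) stop("n must be non-negative")
  set.seed(as.integer(seed))
  lens <- if (is.function(len)) as.integer(len(n))
          else rep.int(as.integer(len), n)
  if (n > 0L && (anyNA(lens) || any(lens < 1L)))
    stop("sequence lengths must be positive integers")
  seqs <- character(n)
  if (n > 0L) {
    pool <- sample(AA20, sum(lens), replace = TRUE, prob = bgFrequencies(bg))
    ends <- cumsum(lens)
    big <- paste(pool, collapse = "")
    seqs <- substring(big, c(1L, utils::head(ends, -1L) + 1L), ends)
  }
  names(seqs) <- sprintf("synthetic%05d", seq_len(n))
  if (!is.null(embed)) {
    emb <- asResidueStrings(embed)
    if (length(emb) != 1L) stop("embed must be a single named sequence")
    at <- sample.int(n + 1L, 1L)
    seqs <- append(seqs, stats::setNames(unname(emb),
                                         paste0("embedded|", names(emb))),
                   after = at - 1L)
  }
  out <- Biostrings::AAStringSet(seqs)
  if (!is.null(path)) {
    con <- file(path, "wb")   # binary mode: identical bytes on any platform
    on.exit(close(con))
    for (k in seq_along(seqs)) {
      wrapped <- gsub("(.{60})", "\\1\n", seqs[[k]])
      wrapped <- sub("\n$", "", wrapped)
      writeLines(c(paste0(">", names(seqs)[[k]]), wrapped), con, sep = "\n")
    }
  }
  out
}

## Idealized extended-chain coordinates for one residue.
residueTemplate <- function(resLetter, d) {
  atoms <- rbind(
    c("N",  0.00,  0.00, 0.00),
    c("CA", 1.46,  0.50, 0.00),
    c("C",  2.50, -0.40, 0.00),
    c("O",  2.45, -1.63, 0.00))
  if (resLetter != "G")
    atoms <- rbind(atoms, c("CB", 1.46, 1.40, 1.10))
  data.frame(elety = atoms[, 1L],
             x = as.numeric(atoms[, 2L]) + d,
             y = as.numeric(atoms[, 3L]),
             z = as.numeric(atoms[, 4L]),
             stringsAsFactors = FALSE)
}

#' Generate a toy multi-chain structure as matched PDB and mmCIF files
#'
#' Builds idealized extended chains (3.8 Angstrom per residue along x; N,
#' CA, C, O and, except for glycine, CB per residue) with successive chains
#' displaced by a fixed vector, so inter-chain atom distances are known by
#' construction. Optional water oxygens can be placed at explicit
#' coordinates. The two output files describe the identical model and are
#' the interface/solvent test fixtures of this package.
#'
#' @param chains named list of one-letter residue strings, e.g.
#'   `list(A = "GAS", B = "AAA")`; names become chain identifiers.
#' @param displacement numeric length-3 vector between successive chains
#'   (Angstrom).
#' @param waters optional numeric matrix (k x 3) of water oxygen positions.
#' @param pdbPath,cifPath optional output paths.
#' @return invisibly, a list with the atom `data.frame` and the paths.
#' @export
generateToyStructure <- function(chains, displacement = c(0, 0, 4),
                                 waters = NULL, pdbPath = NULL,
                                 cifPath = NULL) {
  stopifnot(is.list(chains), length(chains) >= 1L,
            !is.null(names(chains)), length(displacement) == 3L)
  one2three <- stats::setNames(names(AA3TO1), AA3TO1)
  rows <- list()
  for (ci in seq_along(chains)) {
    chainId <- names(chains)[[ci]]
    res <- strsplit(toupper(chains[[ci]]), "", fixed = TRUE)[[1L]]
    if (!all(res %in% AA20)) stop("chain residues must be standard letters")
    off <- (ci - 1L) * displacement
    for (ri in seq_along(res)) {
      tmpl <- residueTemplate(res[[ri]], d = 3.8 * (ri - 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        type = "ATOM", chain = chainId, resno = ri,
        resid = unname(one2three[[res[[ri]]]]), elety = tmpl$elety,
        x = tmpl$x + off[[1L]], y = tmpl$y + off[[2L]], z = tmpl$z + off[[3L]],
        occupancy = 1, elesy = substr(tmpl$elety, 1L, 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(waters)) {
    waters <- as.matrix(waters)
    stopifnot(ncol(waters) == 3L)
    rows[[length(rows) + 1L]] <- data.frame(
      type = "HETATM", chain = "S", resno = seq_len(nrow(waters)),
      resid = "HOH", elety = "O",
      x = waters[, 1L], y = waters[, 2L], z = waters[, 3L],
      occupancy = 1, elesy = "O", stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))

  if (!is.null(pdbPath)) {
    rec <- sprintf("%-6s%5d  %-3s%4s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   atoms$type, atoms$serial, atoms$elety, atoms$resid,
                   atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z,
                   atoms$occupancy, 0, atoms$elesy)
    writeLines(c(rec, "END"), pdbPath)
  }
  if (!is.null(cifPath)) {
    hdr <- c("data_toy", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                      "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
    rec <- sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
                   atoms$type, atoms$serial, atoms$elesy, atoms$elety,
                   atoms$resid, atoms$chain, atoms$resno,
                   atoms$x, atoms$y, atoms$z, atoms$occupancy, 0,
                   atoms$resno, atoms$resid, atoms$chain, atoms$elety)
    writeLines(c(hdr, rec, "#"), cifPath)
  }
  invisible(list(atoms = atoms, pdbPath = pdbPath, cifPath = cifPath))
}

#' Filament fold-region sequences shipped with the package
#'
#' Returns the two low-complexity-domain fragments whose co-assembly this
#' package's analyses revolve around: the annexin A11 N-terminal LCD
#' fragment (residues 37-74 of UniProt P50995 numbering) and the TDP-43
#' C-terminal LCD fragment (residues 273-363 of UniProt Q13148 numbering).
#' Each element carries its parent numbering offset so segment operations
#' can use full-length residue indices.
#'
#' @return list with elements `ANXA11` and `TDP43`, each a list with
#'   `sequence` (named character) and `offset` (residue number of the first
#'   letter).
#' @examples
#' fr <- foldRegionSequences()
#' seg <- segmentSpec("ANXA11", 39, 74)
#' segmentMass(seg, fr$ANXA11$sequence, offset = fr$ANXA11$offset) / 1000
#' @export
foldRegionSequences <- function() {
  path <- system.file("extdata", "filament_fold_regions.fasta",
                      package = "densid", mustWork = TRUE)
  seqs <- readProteome(path)
  desc <- attr(seqs, "descriptions")
  out <- list()
  for (id in names(seqs)) {
    m <- regmatches(desc[[id]], regexec("region=(\\d+)-(\\d+)", desc[[id]]))[[1L]]
    out[[id]] <- list(
      sequence = stats::setNames(as.character(seqs[[id]]), id),
      offset = as.integer(m[[2L]]))
  }
  out
}
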