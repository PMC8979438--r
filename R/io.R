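# Readers, writers and validation for all external data the pipeline touches.
# Positions are 1-based at every user-facing boundary.

#' Read a table of single-residue variants
#'
#' Parses a CSV/TSV/XLSX table with columns \code{wt_aa}, \code{position},
#' \code{mut_aa}, \code{phenotype} and optionally \code{chain} plus any
#' number of precomputed numeric feature columns (e.g. \code{ddG},
#' \code{conservation}). Phenotype labels are normalized case-insensitively
#' into the closed vocabulary \code{control / mild / severe}; anything else
#' is a row-level error, not a fourth class. Rows with \code{wt_aa ==
#' mut_aa} are rejected.
#'
#' @param path file path.
#' @param dialect "auto" (from the extension), "csv", "tsv" or "xlsx".
#' @param chainDefault chain id assigned when the table has no chain column.
#' @return data.frame with columns wt_aa, position, mut_aa, chain,
#'   phenotype, followed by any extra columns from the file.
#' @export
readMutationTable <- function(path, dialect = c("auto", "csv", "tsv", "xlsx"),
                              chainDefault = "A") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("mutation table not found: %s", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                      xlsx = "xlsx",
                      stopf("cannot infer dialect from extension '%s'", ext))
  }
  df <- switch(dialect,
    csv  = utils::read.csv(path, stringsAsFactors = FALSE),
    tsv  = utils::read.delim(path, stringsAsFactors = FALSE),
    xlsx = as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE))
  names(df) <- trimws(names(df))
  required <- c("wt_aa", "position", "mut_aa", "phenotype")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("mutation table schema error: missing required column(s): %s",
          paste(missing, collapse = ", "))
  if (!"chain" %in% names(df)) df$chain <- chainDefault
  df$wt_aa <- toupper(trimws(df$wt_aa))
  df$mut_aa <- toupper(trimws(df$mut_aa))
  df$phenotype <- tolower(trimws(df$phenotype))
  df$position <- as.integer(df$position)

  problems <- character(0)
  badPheno <- which(!df$phenotype %in% PHENOTYPE_LEVELS)
  if (length(badPheno))
    problems <- c(problems, sprintf("row %d: unknown phenotype '%s'",
                                    badPheno, df$phenotype[badPheno]))
  same <- which(df$wt_aa == df$mut_aa)
  if (length(same))
    problems <- c(problems, sprintf("row %d: wt_aa equals mut_aa ('%s')",
                                    same, df$wt_aa[same]))
  badAA <- which(!(df$wt_aa %in% AA_ALPHABET20) |
                 !(df$mut_aa %in% AA_ALPHABET20))
  if (length(badAA))
    problems <- c(problems, sprintf("row %d: non-standard amino acid", badAA))
  badPos <- which(is.na(df$position) | df$position < 1L)
  if (length(badPos))
    problems <- c(problems, sprintf("row %d: invalid position", badPos))
  if (length(problems))
    stopf("invalid mutation rows:\n%s", paste(problems, collapse = "\n"))

  front <- c("wt_aa", "position", "mut_aa", "chain", "phenotype")
  df[, c(front, setdiff(names(df), front)), drop = FALSE]
}

#' Read an aligned FASTA file
#'
#' Enforces equal row lengths (a ragged alignment is a format error naming
#' the first offending identifier), uppercases residues and normalizes gap
#' characters (\code{.}, \code{~}) to \code{-}.
#'
#' @param path aligned FASTA file.
#' @param referenceIndex which row is the query protein (default 1).
#' @return \linkS4class{SequenceAlignment}
#' @export
readAlignment <- function(path, referenceIndex = 1L) {
  if (!file.exists(path)) stopf("alignment not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 2L) stopf("alignment must contain at least 2 sequences")
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L) {
    bad <- which(w != w[1])[1]
    stopf("ragged alignment: sequence '%s' has length %d, expected %d",
          names(ss)[bad], w[bad], w[1])
  }
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[.~]", "-", seqs)
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  dimnames(chars) <- NULL
  methods::new("SequenceAlignment", ids = names(ss), chars = chars,
               referenceIndex = as.integer(referenceIndex))
}

#' Write an alignment as aligned FASTA
#'
#' @param aln a \linkS4class{SequenceAlignment}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeAlignment <- function(aln, path) {
  seqs <- apply(aln@chars, 1, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- aln@ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Construct a StructureModel from a residue table
#'
#' @param residues data.frame with chain, position, resid, aa, ca.*, cb.*.
#' @param atoms optional heavy-atom data.frame.
#' @param annotations optional named character of functional-domain labels.
#' @return \linkS4class{StructureModel}
#' @export
structureModel <- function(residues, atoms = NULL, annotations = character(0)) {
  if (is.null(atoms))
    atoms <- data.frame(chain = character(0), position = integer(0),
                        elety = character(0), element = character(0),
                        x = numeric(0), y = numeric(0), z = numeric(0))
  methods::new("StructureModel", residues = residues, atoms = atoms,
               annotations = annotations)
}

#' Read a protein structure from a PDB file
#'
#' Keeps heavy atoms of ATOM records. Alternate locations are resolved by
#' highest occupancy, ties broken by label "A"; insertion codes are
#' rejected with a clear message; a residue without a C-alpha is a
#' structure error naming the residue. Glycines carry no C-beta.
#'
#' @param path PDB file.
#' @return \linkS4class{StructureModel}
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stopf("structure not found: %s", path)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stopf("no ATOM records in %s", path)
  ins <- !(is.na(at$insert) | at$insert == "" | at$insert == " ")
  if (any(ins))
    stopf("insertion codes are not supported (first at %s%d%s)",
          at$chain[ins][1], at$resno[ins][1], at$insert[ins][1])
  # drop hydrogens
  at <- at[!(at$elesy %in% "H") & !grepl("^[0-9]*H", at$elety), , drop = FALSE]
  # altloc resolution: highest occupancy, then label 'A', per atom identity
  alt <- ifelse(is.na(at$alt) | at$alt == "", " ", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$elety)
  ord <- order(key, -occ, alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$chain, at$resno), , drop = FALSE]

  rkey <- paste(at$chain, at$resno)
  ridx <- !duplicated(rkey)
  res <- data.frame(chain = at$chain[ridx], position = at$resno[ridx],
                    resid = at$resid[ridx], stringsAsFactors = FALSE)
  res$aa <- aa321(res$resid)
  res$aa[is.na(res$aa)] <- "X"
  atomKey <- paste(at$chain, at$resno, at$elety)
  pick <- function(elety) {
    m <- match(paste(res$chain, res$position, elety), atomKey)
    cbind(at$x[m], at$y[m], at$z[m])
  }
  ca <- pick("CA")
  if (any(!is.finite(ca[, 1]))) {
    bad <- which(!is.finite(ca[, 1]))[1]
    stopf("residue %s%d (%s) has no C-alpha atom",
          res$chain[bad], res$position[bad], res$resid[bad])
  }
  cb <- pick("CB")
  res$ca.x <- ca[, 1]; res$ca.y <- ca[, 2]; res$ca.z <- ca[, 3]
  res$cb.x <- cb[, 1]; res$cb.y <- cb[, 2]; res$cb.z <- cb[, 3]
  atoms <- data.frame(chain = at$chain, position = at$resno,
                      elety = at$elety,
                      element = ifelse(is.na(at$elesy) | at$elesy == "",
                                       substr(gsub("[0-9]", "", at$elety), 1, 1),
                                       at$elesy),
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  structureModel(res, atoms)
}

# fixed-width PDB ATOM line
.pdbAtomLine <- function(serial, name, resid, chain, resno, x, y, z,
                         element) {
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, resid, chain, resno, x, y, z, 1.0, 0.0, element)
}

#' Write a StructureModel to a PDB file
#'
#' Writes heavy atoms when present, otherwise the C-alpha / C-beta
#' representation, with TER records between chains.
#'
#' @param struct a \linkS4class{StructureModel}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeStructure <- function(struct, path) {
  lines <- .structureLines(struct)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

.structureLines <- function(struct) {
  r <- struct@residues
  a <- struct@atoms
  lines <- character(0)
  serial <- 0L
  for (ch in unique(r$chain)) {
    if (nrow(a)) {
      sub <- a[a$chain == ch, , drop = FALSE]
      rsub <- r[r$chain == ch, , drop = FALSE]
      resid <- rsub$resid[match(sub$position, rsub$position)]
      for (i in seq_len(nrow(sub))) {
        serial <- serial + 1L
        lines <- c(lines, .pdbAtomLine(serial, sub$elety[i], resid[i], ch,
                                       sub$position[i], sub$x[i], sub$y[i],
                                       sub$z[i], sub$element[i]))
      }
    } else {
      sub <- r[r$chain == ch, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        serial <- serial + 1L
        lines <- c(lines, .pdbAtomLine(serial, "CA", sub$resid[i], ch,
                                       sub$position[i], sub$ca.x[i],
                                       sub$ca.y[i], sub$ca.z[i], "C"))
        if (is.finite(sub$cb.x[i])) {
          serial <- serial + 1L
          lines <- c(lines, .pdbAtomLine(serial, "CB", sub$resid[i], ch,
                                         sub$position[i], sub$cb.x[i],
                                         sub$cb.y[i], sub$cb.z[i], "C"))
        }
      }
    }
    lines <- c(lines, "TER")
  }
  lines
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a \linkS4class{TrajectoryEnsemble}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeTrajectoryPdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  r <- traj@residues
  for (f in seq_len(dim(traj@ca)[1])) {
    writeLines(sprintf("MODEL     %4d", f), con)
    rf <- r
    rf$ca.x <- traj@ca[f, , 1]; rf$ca.y <- traj@ca[f, , 2]
    rf$ca.z <- traj@ca[f, , 3]
    rf$cb.x <- traj@cb[f, , 1]; rf$cb.y <- traj@cb[f, , 2]
    rf$cb.z <- traj@cb[f, , 3]
    writeLines(.structureLines(structureModel(rf)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a trajectory from a multi-model PDB
#'
#' @param path multi-model PDB file.
#' @return \linkS4class{TrajectoryEnsemble}
#' @export
readTrajectoryPdb <- function(path) {
  txt <- readLines(path)
  starts <- grep("^MODEL", txt)
  ends <- grep("^ENDMDL", txt)
  if (length(starts) < 2L) stopf("need at least 2 MODEL blocks in %s", path)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  frames <- lapply(seq_along(starts), function(i) {
    writeLines(c(txt[(starts[i] + 1L):(ends[i] - 1L)], "END"), tmp)
    readStructure(tmp)
  })
  r0 <- frames[[1]]@residues
  n <- nrow(r0)
  ca <- array(NA_real_, c(length(frames), n, 3))
  cb <- array(NA_real_, c(length(frames), n, 3))
  for (f in seq_along(frames)) {
    rf <- frames[[f]]@residues
    if (nrow(rf) != n) stopf("frame %d has %d residues, expected %d", f,
                             nrow(rf), n)
    ca[f, , ] <- as.matrix(rf[, c("ca.x", "ca.y", "ca.z")])
    cb[f, , ] <- as.matrix(rf[, c("cb.x", "cb.y", "cb.z")])
  }
  methods::new("TrajectoryEnsemble", ca = ca, cb = cb, residues = r0,
               source = "imported")
}

# map a 1-based reference-sequence position to its alignment column
alnColumnForPosition <- function(aln, position) {
  ref <- referenceRow(aln)
  idx <- cumsum(ref != "-")
  col <- match(position, idx)
  if (is.na(col)) stopf("position %d beyond ungapped reference length %d",
                        position, max(idx))
  col
}

#' Cross-validate mutations against alignment and structure
#'
#' Report-only: for each mutation, checks that the wild-type residue
#' matches both the alignment reference column and the structure residue
#' type. Inputs are never modified.
#'
#' @param muts mutation data.frame from \code{\link{readMutationTable}}.
#' @param aln \linkS4class{SequenceAlignment} (may be NULL to skip).
#' @param struct \linkS4class{StructureModel} (may be NULL to skip).
#' @return data.frame with one row per mutation and columns
#'   \code{structure_aa}, \code{alignment_aa}, \code{ok}.
#' @export
validateMutations <- function(muts, aln = NULL, struct = NULL) {
  n <- nrow(muts)
  rep <- data.frame(row = seq_len(n),
                    key = residueKey(muts$chain, muts$position),
                    wt_aa = muts$wt_aa,
                    structure_aa = NA_character_,
                    alignment_aa = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(struct)) {
    r <- struct@residues
    m <- match(rep$key, residueKey(r$chain, r$position))
    rep$structure_aa <- r$aa[m]
  }
  if (!is.null(aln)) {
    refLen <- sum(referenceRow(aln) != "-")
    ok <- muts$position >= 1 & muts$position <= refLen
    cols <- rep(NA_integer_, n)
    cols[ok] <- vapply(muts$position[ok],
                       function(p) alnColumnForPosition(aln, p), integer(1))
    rep$alignment_aa[ok] <- referenceRow(aln)[cols[ok]]
  }
  rep$ok <- (is.na(rep$structure_aa) | rep$structure_aa == rep$wt_aa) &
            (is.na(rep$alignment_aa) | rep$alignment_aa == rep$wt_aa)
  rep
}

#' Construct a FeatureTable
#'
#' @param mutations data.frame (wt_aa, position, mut_aa, chain, phenotype).
#' @param values data.frame of numeric feature columns (registered names).
#' @param provenance named character, "computed" or "imported" per column.
#' @return \linkS4class{FeatureTable}
#' @export
featureTable <- function(mutations, values,
                         provenance = stats::setNames(
                           rep("computed", ncol(values)), names(values))) {
  methods::new("FeatureTable", mutations = mutations,
               values = as.data.frame(values), provenance = provenance)
}

#' Write a FeatureTable as TSV
#'
#' Floats are written with 17 significant digits so that a read-back is
#' identical to 1e-12 relative precision; provenance is stored in
#' \code{#%} header comments.
#'
#' @param ft a \linkS4class{FeatureTable}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeFeatureTable <- function(ft, path) {
  df <- cbind(ft@mutations, ft@values)
  num <- vapply(df, is.numeric, logical(1)) &
         !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  hdr <- sprintf("#%% provenance %s=%s", names(ft@provenance),
                 unname(ft@provenance))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FeatureTable written by \code{\link{writeFeatureTable}}
#'
#' @param path TSV file.
#' @return \linkS4class{FeatureTable}
#' @export
readFeatureTable <- function(path) {
  txt <- readLines(path)
  hdr <- grep("^#% provenance ", txt, value = TRUE)
  prov <- character(0)
  if (length(hdr)) {
    kv <- sub("^#% provenance ", "", hdr)
    parts <- strsplit(kv, "=", fixed = TRUE)
    prov <- stats::setNames(vapply(parts, `[`, "", 2),
                            vapply(parts, `[`, "", 1))
  }
  df <- utils::read.delim(text = txt[!startsWith(txt, "#%")],
                          stringsAsFactors = FALSE)
  front <- c("wt_aa", "position", "mut_aa", "chain", "phenotype")
  vals <- df[, setdiff(names(df), front), drop = FALSE]
  featureTable(df[, front], vals,
               if (length(prov)) prov[names(vals)] else
                 stats::setNames(rep("computed", ncol(vals)), names(vals)))
}
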