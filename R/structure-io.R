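# Structure preparation stage, part 1: PDB parsing, bond perception,
# serialization and rigid transforms.

.residue_key <- function(resid, chain, resno, icode) {
  paste0(resid, ":", chain, ":", resno, ifelse(icode == "", "", icode))
}

.read_input_lines <- function(source) {
  if (is.character(source) && length(source) == 1 && !grepl("\n", source) &&
      file.exists(source)) {
    return(readLines(source, warn = FALSE))
  }
  if (is.character(source) && length(source) == 1) {
    return(strsplit(source, "\n", fixed = TRUE)[[1]])
  }
  if (is.character(source)) {
    return(source)
  }
  stop("source must be a file path or PDB text")
}

.parse_conect <- function(lines) {
  cl <- lines[startsWith(lines, "CONECT")]
  if (length(cl) == 0) return(matrix(integer(0), ncol = 2))
  pairs <- list()
  for (ln in cl) {
    flds <- c(
      substr(ln, 7, 11), substr(ln, 12, 16), substr(ln, 17, 21),
      substr(ln, 22, 26), substr(ln, 27, 31)
    )
    vals <- suppressWarnings(as.integer(trimws(flds)))
    vals <- vals[!is.na(vals)]
    if (length(vals) >= 2) {
      a <- vals[1]
      for (b in vals[-1]) {
        pairs[[length(pairs) + 1]] <- c(min(a, b), max(a, b))
      }
    }
  }
  unique(do.call(rbind, pairs))
}

# Covalent bond inference by the distance rule d <= r1 + r2 + 0.45 A using a
# cell list so large structures stay tractable. Hydrogen-hydrogen pairs are
# never bonded; a lower bound of 0.4 A guards against duplicate atoms.
.infer_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  cell <- 3.5
  ix <- floor(atoms$x / cell)
  iy <- floor(atoms$y / cell)
  iz <- floor(atoms$z / cell)
  keys <- paste(ix, iy, iz)
  buckets <- split(seq_len(n), keys)
  radii <- .covalent_radius(atoms$element)
  is_h <- atoms$is_h
  out <- list()
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      k <- paste(ix[i] + dx, iy[i] + dy, iz[i] + dz)
      b <- buckets[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- cand[cand > i]
    if (length(cand) == 0) next
    dx <- atoms$x[cand] - atoms$x[i]
    dy <- atoms$y[cand] - atoms$y[i]
    dz <- atoms$z[cand] - atoms$z[i]
    d <- sqrt(dx^2 + dy^2 + dz^2)
    cut <- pmin(radii[i] + radii[cand] + 0.45, 3.4)
    keep <- d > 0.4 & d <= cut & !(is_h[i] & is_h[cand])
    if (any(keep)) {
      out[[length(out) + 1]] <- cbind(i, cand[keep])
    }
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

.bonds_from_pairs <- function(serial_pairs) {
  bonds <- list()
  if (nrow(serial_pairs) == 0) return(bonds)
  for (r in seq_len(nrow(serial_pairs))) {
    a <- as.character(serial_pairs[r, 1])
    b <- as.character(serial_pairs[r, 2])
    bonds[[a]] <- union(bonds[[a]], serial_pairs[r, 2])
    bonds[[b]] <- union(bonds[[b]], serial_pairs[r, 1])
  }
  lapply(bonds, sort)
}

#' Parse a protein-ligand complex from PDB format
#'
#' Reads ATOM/HETATM/MODEL/CONECT records (wwPDB v3.3 fixed columns, via
#' \pkg{bio3d}), resolves alternate locations by keeping the highest-occupancy
#' conformer (ties broken by altloc letter order), classifies residues as
#' protein, water or ligand-candidate, and perceives covalent bonds from
#' CONECT records plus a covalent-radius distance rule.
#'
#' @param source Path to a PDB file, or PDB text (single string or character
#'   vector of lines).
#' @param model Model number to extract from multi-model files (default 1).
#' @param identifier Structure identifier; defaults to the file stem or
#'   `"structure"` for raw text input.
#' @return An object of class `ligprof_structure`: a list with `identifier`,
#'   `model_index`, `n_models`, `atoms` (data frame with serial, name, altloc,
#'   resid, chain, resno, icode, coordinates, occupancy, element, record,
#'   is_h, reskey), `residues` (one row per residue with a `kind` column) and
#'   `bonds` (adjacency list keyed by atom serial).
#' @export
parse_pdb <- function(source, model = 1, identifier = NULL) {
  lines <- .read_input_lines(source)
  if (is.null(identifier)) {
    identifier <- if (is.character(source) && length(source) == 1 &&
                      !grepl("\n", source) && file.exists(source)) {
      sub("\\.[^.]*$", "", basename(source))
    } else {
      "structure"
    }
  }
  rec_lines <- grep("^(ATOM  |HETATM)", lines)
  if (length(rec_lines) == 0) {
    stop(
      "parse error: no ATOM or HETATM records found (first line: ",
      if (length(lines)) substr(lines[1], 1, 40) else "<empty>", ")"
    )
  }

  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) {
    n_models <- 1L
    if (model != 1) {
      stop("requested model ", model, " absent; available models: 1")
    }
    block <- lines
  } else {
    model_ends <- grep("^ENDMDL", lines)
    n_models <- length(model_starts)
    if (model < 1 || model > n_models) {
      stop(
        "requested model ", model, " absent; available models: ",
        paste(seq_len(n_models), collapse = ", ")
      )
    }
    end <- if (length(model_ends) >= model) model_ends[model] else length(lines)
    block <- lines[(model_starts[model] + 1):(end - 1)]
    block <- block[!startsWith(block, "MODEL")]
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(c(block, "END"), tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, verbose = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("parse error: no atoms in selected model ", model)
  }

  element <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  blank <- element == ""
  if (any(blank)) {
    element[blank] <- vapply(at$elety[blank], .guess_element, character(1))
  }
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resid = trimws(at$resid),
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    element = element,
    record = at$type,
    stringsAsFactors = FALSE
  )
  atoms$is_h <- atoms$element %in% c("H", "D")

  # Altloc policy: keep the highest-occupancy conformer of each atom,
  # ties broken by altloc letter order.
  key <- paste(atoms$resid, atoms$chain, atoms$resno, atoms$icode, atoms$name)
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$serial), , drop = FALSE]
  rownames(atoms) <- NULL
  if (anyDuplicated(atoms$serial)) {
    stop("parse error: duplicate atom serials within model ", model)
  }
  atoms$reskey <- .residue_key(atoms$resid, atoms$chain, atoms$resno, atoms$icode)

  first <- !duplicated(atoms$reskey)
  residues <- data.frame(
    reskey = atoms$reskey[first],
    resid = atoms$resid[first],
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    icode = atoms$icode[first],
    record = atoms$record[first],
    stringsAsFactors = FALSE
  )
  residues$kind <- ifelse(
    residues$resid %in% .water_codes, "water",
    ifelse(residues$record == "ATOM", "protein", "ligand-candidate")
  )

  conect <- .parse_conect(lines)
  if (nrow(conect) > 0) {
    conect <- conect[conect[, 1] %in% atoms$serial &
                       conect[, 2] %in% atoms$serial, , drop = FALSE]
  }
  idx_pairs <- .infer_bonds(atoms)
  inferred <- if (nrow(idx_pairs) > 0) {
    cbind(atoms$serial[idx_pairs[, 1]], atoms$serial[idx_pairs[, 2]])
  } else {
    matrix(integer(0), ncol = 2)
  }
  all_pairs <- rbind(conect, inferred)
  if (nrow(all_pairs) > 0) {
    all_pairs <- unique(t(apply(all_pairs, 1, sort)))
  }

  structure(
    list(
      identifier = identifier,
      model_index = as.integer(model),
      n_models = n_models,
      atoms = atoms,
      residues = residues,
      bonds = .bonds_from_pairs(all_pairs),
      conect = conect
    ),
    class = "ligprof_structure"
  )
}

#' @export
print.ligprof_structure <- function(x, ...) {
  cat(
    "<ligprof_structure>", x$identifier,
    "| model", x$model_index, "of", x$n_models,
    "|", nrow(x$atoms), "atoms,", nrow(x$residues), "residues\n"
  )
  cat("  residue kinds:", paste(
    names(table(x$residues$kind)), table(x$residues$kind),
    collapse = ", "
  ), "\n")
  invisible(x)
}

.atom_xyz <- function(s, serials) {
  i <- match(serials, s$atoms$serial)
  m <- cbind(s$atoms$x[i], s$atoms$y[i], s$atoms$z[i])
  if (length(serials) == 1) as.numeric(m) else m
}

.heavy_neighbors <- function(s, serial) {
  nb <- s$bonds[[as.character(serial)]]
  if (is.null(nb)) return(integer(0))
  nb[!s$atoms$is_h[match(nb, s$atoms$serial)]]
}

.h_neighbors <- function(s, serial) {
  nb <- s$bonds[[as.character(serial)]]
  if (is.null(nb)) return(integer(0))
  nb[s$atoms$is_h[match(nb, s$atoms$serial)]]
}

.format_pdb_line <- function(record, serial, name, resid, chain, resno, icode,
                             x, y, z, occ, element) {
  fname <- if (nchar(name) >= 4) {
    substr(name, 1, 4)
  } else {
    sprintf("%-3s", name)
  }
  if (nchar(fname) == 3) fname <- paste0(" ", fname)
  sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    record, serial, fname, " ", resid, chain, resno,
    ifelse(icode == "", " ", icode), x, y, z, occ, 0, element
  )
}

#' Serialize a structure back to PDB text
#'
#' Writes ATOM/HETATM records at standard 3-decimal coordinate precision,
#' plus CONECT records for every bond involving a HETATM atom (bonds within
#' the polymer are re-derived from geometry on parsing).
#'
#' @param s A `ligprof_structure`.
#' @param path Optional output file; when `NULL` the text is returned.
#' @return Character vector of PDB lines (invisibly when `path` is given).
#' @export
write_structure_pdb <- function(s, path = NULL) {
  a <- s$atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    .format_pdb_line(
      a$record[i], a$serial[i], a$name[i], a$resid[i], a$chain[i],
      a$resno[i], a$icode[i], a$x[i], a$y[i], a$z[i], a$occupancy[i],
      a$element[i]
    )
  }, character(1))
  het <- a$serial[a$record == "HETATM"]
  conect <- character(0)
  for (serial in het) {
    nb <- s$bonds[[as.character(serial)]]
    if (length(nb) > 0) {
      conect <- c(conect, paste0(
        "CONECT", sprintf("%5d", serial),
        paste(sprintf("%5d", nb), collapse = "")
      ))
    }
  }
  out <- c(lines, conect, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Apply a rigid rotation and translation to all coordinates
#'
#' @param s A `ligprof_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Numeric xyz vector.
#' @return The transformed structure.
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- cbind(s$atoms$x, s$atoms$y, s$atoms$z)
  new <- xyz %*% t(rotation)
  s$atoms$x <- new[, 1] + translation[1]
  s$atoms$y <- new[, 2] + translation[2]
  s$atoms$z <- new[, 3] + translation[3]
  s
}
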