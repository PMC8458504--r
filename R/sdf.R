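# SDF V2000 read/write for the molecule graph model. Aromatic bonds use
# bond type 4; formal charges go through M  CHG property lines.

#' Read molecules from an SDF (V2000) file
#'
#' @param path path to an SDF file (or a character vector of lines).
#' @return list of `molecule` objects; atom-block coordinates, when not
#'   all zero, are attached as a single conformer.
#' @export
read_sdf <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  # split into records on $$$$
  recs <- list()
  cur <- character()
  for (ln in lines) {
    if (trimws(ln) == "$$$$") {
      recs[[length(recs) + 1L]] <- cur
      cur <- character()
    } else cur <- c(cur, ln)
  }
  if (length(cur) && any(nzchar(trimws(cur)))) recs[[length(recs) + 1L]] <- cur
  out <- vector("list", length(recs))
  for (ri in seq_along(recs)) {
    out[[ri]] <- tryCatch(.parse_sdf_record(recs[[ri]]),
      error = function(e) stop("SDF format error in record ", ri, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  out
}

.parse_sdf_record <- function(rec) {
  if (length(rec) < 4L) stop("truncated record (fewer than 4 lines)")
  name <- trimws(rec[1L])
  counts <- rec[4L]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 0L || nb < 0L)
    stop("bad counts line: '", counts, "'")
  if (length(rec) < 4L + na + nb) stop("truncated atom/bond block")
  atoms <- data.frame(element = character(na), charge = integer(na),
                      nH = rep(NA_integer_, na), aromatic = logical(na))
  xyz <- matrix(0, na, 3)
  for (k in seq_len(na)) {
    ln <- rec[4L + k]
    x <- suppressWarnings(as.numeric(substr(ln, 1, 10)))
    y <- suppressWarnings(as.numeric(substr(ln, 11, 20)))
    z <- suppressWarnings(as.numeric(substr(ln, 21, 30)))
    el <- trimws(substr(ln, 31, 34))
    if (is.na(x) || is.na(y) || is.na(z) || !nzchar(el))
      stop("bad atom line ", k, ": '", ln, "'")
    xyz[k, ] <- c(x, y, z)
    atoms$element[k] <- el
  }
  bonds <- data.frame(i = integer(nb), j = integer(nb), order = integer(nb))
  for (k in seq_len(nb)) {
    ln <- rec[4L + na + k]
    i <- suppressWarnings(as.integer(substr(ln, 1, 3)))
    j <- suppressWarnings(as.integer(substr(ln, 4, 6)))
    o <- suppressWarnings(as.integer(substr(ln, 7, 9)))
    if (is.na(i) || is.na(j) || is.na(o)) stop("bad bond line ", k)
    bonds[k, ] <- list(i, j, o)
  }
  # property lines
  for (ln in rec[-seq_len(4L + na + nb)]) {
    if (startsWith(ln, "M  CHG")) {
      n <- as.integer(substr(ln, 7, 9))
      for (q in seq_len(n)) {
        off <- 10L + (q - 1L) * 8L
        ai <- as.integer(substr(ln, off, off + 3L))
        cg <- as.integer(substr(ln, off + 4L, off + 7L))
        atoms$charge[ai] <- cg
      }
    }
    if (startsWith(ln, "M  END")) break
  }
  atoms$aromatic <- FALSE
  for (k in seq_len(nb)) {
    if (bonds$order[k] == 4L) {
      atoms$aromatic[bonds$i[k]] <- TRUE
      atoms$aromatic[bonds$j[k]] <- TRUE
    }
  }
  m <- structure(list(atoms = atoms, bonds = bonds, name = name,
                      conformers = list()), class = "molecule")
  m <- fill_implicit_h(m)
  if (any(xyz != 0)) {
    m$conformers <- list(list(xyz = xyz, energy = NA_real_))
  }
  validate_molecule(m)
  m
}

#' Write molecules to an SDF (V2000) file
#'
#' Coordinates come from each molecule's first conformer (zeros when no
#' conformer is present). Round-tripping through [read_sdf()] preserves
#' atom count, bond count and coordinates to 4 decimals.
#'
#' @param molecules list of `molecule` objects (or a single molecule).
#' @param path output path.
#' @param conformer index of the conformer whose coordinates to write.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(molecules, path, conformer = 1L) {
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  out <- character()
  for (m in molecules) {
    na <- nrow(m$atoms); nb <- nrow(m$bonds)
    xyz <- if (length(m$conformers) >= conformer)
      m$conformers[[conformer]]$xyz else matrix(0, na, 3)
    out <- c(out, m$name, "  wasscreen", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
    for (k in seq_len(na)) {
      out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                            xyz[k, 1], xyz[k, 2], xyz[k, 3], m$atoms$element[k]))
    }
    for (k in seq_len(nb)) {
      out <- c(out, sprintf("%3d%3d%3d  0", m$bonds$i[k], m$bonds$j[k],
                            m$bonds$order[k]))
    }
    chg <- which(m$atoms$charge != 0L)
    if (length(chg)) {
      out <- c(out, paste0("M  CHG", sprintf("%3d", length(chg)),
                           paste0(sprintf("%4d%4d", chg, m$atoms$charge[chg]),
                                  collapse = "")))
    }
    out <- c(out, "M  END", "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}
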