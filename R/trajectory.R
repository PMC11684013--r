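# In-memory frame model: a Trajectory holds a Topology (per-atom metadata),
# a coords array (atoms x 3 x frames), per-frame orthorhombic cell lengths
# and per-frame times in ns.

# Standard atomic masses (amu) and atomic numbers for the elements that occur
# in protein/lipid/water systems, plus "Bd": a lipid headgroup pseudo-bead
# carrying the pooled electron count of a phosphocholine-like headgroup.
.elements <- data.frame(
  elem   = c("H", "C", "N", "O", "P", "S", "NA", "CL", "K", "MG", "CA", "FE", "ZN", "BD"),
  mass   = c(1.008, 12.011, 14.007, 15.999, 30.974, 32.06, 22.990, 35.45,
             39.098, 24.305, 40.078, 55.845, 65.38, 94.0),
  atomno = c(1L, 6L, 7L, 8L, 15L, 16L, 11L, 17L, 19L, 12L, 20L, 26L, 30L, 50L),
  stringsAsFactors = FALSE
)

#' Infer the element symbol from a PDB atom name
#'
#' Two-letter ions (NA, CL, MG, ...) are matched first; otherwise the first
#' alphabetic character of the stripped atom name is taken (so `"OG"` is O,
#' `"1HB"` is H, `"CA"` inside a residue is carbon).
#'
#' @param name character vector of atom names
#' @return character vector of element symbols
#' @keywords internal
infer_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z0-9]", "", name))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("NA", "CL", "MG", "FE", "ZN", "BD") & nchar(nm) == 2,
                two, NA_character_)
  first <- sub("^[0-9]*", "", nm)
  out[is.na(out)] <- substr(first[is.na(out)], 1, 1)
  out
}

#' Build a Topology table
#'
#' @param name atom names; @param resname residue names; @param chain chain labels
#' @param resno residue numbers (author-style, per chain)
#' @param elem element symbols; inferred from `name` when `NULL`
#' @return data.frame with columns name, resname, chain, resno, elem, mass, atomno
#' @export
topology <- function(name, resname, chain, resno, elem = NULL) {
  n <- length(name)
  if (is.null(elem)) elem <- infer_element(name)
  elem <- toupper(elem)
  i <- match(elem, .elements$elem)
  if (anyNA(i)) {
    bad <- unique(elem[is.na(i)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            "; treating as carbon")
    i[is.na(i)] <- match("C", .elements$elem)
    elem[is.na(match(elem, .elements$elem))] <- "C"
  }
  top <- data.frame(name = as.character(name), resname = as.character(resname),
                    chain = as.character(chain), resno = as.integer(resno),
                    elem = elem, mass = .elements$mass[i],
                    atomno = .elements$atomno[i], stringsAsFactors = FALSE)
  stopifnot(nrow(top) == n, all(top$mass > 0), all(top$atomno >= 1))
  # residue numbering must be non-decreasing within each chain
  for (ch in unique(top$chain)) {
    r <- top$resno[top$chain == ch]
    if (is.unsorted(r)) stop("residue numbers decrease within chain ", ch)
  }
  top
}

#' Construct a Trajectory
#'
#' @param top Topology data.frame (see [topology()])
#' @param coords numeric array `n_atoms x 3 x n_frames` (or a single `n x 3`
#'   matrix), Angstrom
#' @param box per-frame orthorhombic cell lengths: `n_frames x 3` matrix, a
#'   single length-3 vector (recycled), or `NULL` (no cell)
#' @param time per-frame times in ns (defaults to 0, 1, 2, ...)
#' @return object of class `Trajectory`
#' @export
trajectory <- function(top, coords, box = NULL, time = NULL) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != nrow(top))
    stop("coordinate array holds ", dim(coords)[1], " atoms but topology has ",
         nrow(top))
  nf <- dim(coords)[3]
  if (is.null(box)) box <- rep(NA_real_, 3)
  if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
  if (any(stats::na.omit(as.vector(box)) <= 0)) stop("box lengths must be > 0")
  if (is.null(time)) time <- seq_len(nf) - 1
  structure(list(top = top, coords = coords, box = box, time = as.numeric(time)),
            class = "Trajectory")
}

#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract a single frame
#' @param traj a Trajectory; @param i frame index
#' @return list with `coords` (n x 3), `box`, `time`, class `Frame`
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  structure(list(coords = matrix(traj$coords[, , i], ncol = 3),
                 box = traj$box[i, ], time = traj$time[i]), class = "Frame")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d atoms, %d frames, %d chain(s) [%s]\n",
              n_atoms(x), n_frames(x), length(unique(x$top$chain)),
              paste(unique(x$top$chain), collapse = ",")))
  if (all(is.finite(x$box[1, ])))
    cat(sprintf("  cell: %.1f x %.1f x %.1f A\n", x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  cat(sprintf("  time: %.3f .. %.3f ns\n", x$time[1], x$time[n_frames(x)]))
  invisible(x)
}

#' Select atoms by metadata
#'
#' Each non-`NULL` argument restricts the selection (logical AND).
#'
#' @param traj Trajectory (or bare Topology data.frame)
#' @param chain,resno,name,resname,elem vectors of accepted values
#' @param exclude_h drop hydrogens
#' @return integer atom indices
#' @export
select_atoms <- function(traj, chain = NULL, resno = NULL, name = NULL,
                         resname = NULL, elem = NULL, exclude_h = FALSE) {
  top <- if (inherits(traj, "Trajectory")) traj$top else traj
  keep <- rep(TRUE, nrow(top))
  if (!is.null(chain))   keep <- keep & top$chain %in% chain
  if (!is.null(resno))   keep <- keep & top$resno %in% resno
  if (!is.null(name))    keep <- keep & top$name %in% name
  if (!is.null(resname)) keep <- keep & top$resname %in% resname
  if (!is.null(elem))    keep <- keep & top$elem %in% elem
  if (exclude_h)         keep <- keep & top$elem != "H"
  which(keep)
}

#' Alpha-carbon selection helper
#' @export
select_calpha <- function(traj, chain = NULL)
  select_atoms(traj, chain = chain, name = "CA", elem = "C")

# ---------------------------------------------------------------- file I/O --

.check_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  at <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(at)) stop("no ATOM/HETATM records in ", path)
  for (i in which(at)) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop("PDB parse error at line ", i, ": truncated record")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz)) stop("PDB parse error at line ", i, ": malformed coordinates")
  }
  invisible(lines)
}

#' Read a PDB structure or multi-model PDB trajectory
#'
#' Coordinates of every MODEL become trajectory frames; the CRYST1 record, if
#' present, supplies the orthorhombic cell. Elements missing from the element
#' column are inferred from atom names (with a warning).
#'
#' @param path path to a PDB file
#' @param time_step ns between successive models (default 1)
#' @return a [trajectory()] object
#' @export
read_structure <- function(path, time_step = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- .check_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || anyNA(elem) || any(!nzchar(trimws(elem)))) {
    warning("element column absent or incomplete in ", basename(path),
            "; inferring elements from atom names")
    elem <- infer_element(at$elety)
  } else elem <- toupper(trimws(elem))
  ch <- at$chain
  ch[is.na(ch) | !nzchar(ch)] <- "A"
  top <- topology(name = at$elety, resname = at$resid, chain = ch,
                  resno = at$resno, elem = elem)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); na <- nrow(top)
  coords <- array(0, c(na, 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  box <- rep(NA_real_, 3)
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (length(cry)) {
    b <- suppressWarnings(as.numeric(c(substr(cry[1], 7, 15),
                                       substr(cry[1], 16, 24),
                                       substr(cry[1], 25, 33))))
    if (!anyNA(b) && all(b > 0)) box <- b
  }
  trajectory(top, coords, box = box, time = (seq_len(nf) - 1) * time_step)
}

#' Write a Trajectory as a (multi-model) PDB file
#'
#' Emits CRYST1 (when the cell is defined), MODEL/ENDMDL per frame, and
#' fixed-width ATOM records with the element column filled; coordinates keep
#' the format's 3-decimal precision.
#'
#' @param traj Trajectory; @param path output path
#' @export
write_pdb <- function(traj, path) {
  top <- traj$top
  con <- file(path, "wt")
  on.exit(close(con))
  b <- traj$box[1, ]
  if (all(is.finite(b)))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       b[1], b[2], b[3], 90, 90, 90), con)
  nf <- n_frames(traj)
  elem2 <- ifelse(nchar(top$elem) == 2 & top$elem %in% .elements$elem,
                  top$elem, substr(top$elem, 1, 1))
  name4 <- ifelse(nchar(top$name) >= 4, substr(top$name, 1, 4),
                  sprintf(" %-3s", top$name))
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[, , f, drop = TRUE]
    writeLines(sprintf(
      "ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      (seq_len(nrow(top)) - 1L) %% 99999L + 1L, name4, substr(top$resname, 1, 4),
      substr(top$chain, 1, 1), top$resno, xyz[, 1], xyz[, 2], xyz[, 3],
      1, 0, elem2), con)
    writeLines(if (nf > 1) c("TER", "ENDMDL") else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write trajectory coordinates as a CHARMM-style DCD file
#'
#' Little-endian CHARMM dialect: Fortran-style length-prefixed records, a
#' "CORD" header with the frame count, a unit-cell block per frame (when the
#' cell is defined) and X/Y/Z float records per frame. Readable by common MD
#' tools; [read_dcd()] pairs it with a topology.
#'
#' @param traj Trajectory; @param path output path
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj); na <- n_atoms(traj)
  has_cell <- all(is.finite(traj$box[1, ]))
  rec <- function(writer) {
    raw <- writer
    writeBin(length(raw), con, size = 4, endian = "little")
    writeBin(raw, con, endian = "little")
    writeBin(length(raw), con, size = 4, endian = "little")
  }
  # header record: "CORD" + 20 int32 control words (icntrl)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- if (has_cell) 1L else 0L
  icntrl[20] <- 24L  # CHARMM version stamp
  hdr <- c(writeBin(charToRaw("CORD"), raw()), writeBin(icntrl, raw(), size = 4,
                                                        endian = "little"))
  writeBin(length(hdr), con, size = 4, endian = "little")
  writeBin(hdr, con, endian = "little")
  writeBin(length(hdr), con, size = 4, endian = "little")
  rec(c(writeBin(1L, raw(), size = 4, endian = "little"),
        writeBin(charToRaw(formatC("memsig trajectory", width = 80, flag = "-")), raw())))
  rec(writeBin(as.integer(na), raw(), size = 4, endian = "little"))
  for (f in seq_len(nf)) {
    if (has_cell) {
      b <- traj$box[f, ]
      # CHARMM unit cell: a, gamma, b, beta, alpha, c (cosines for angles)
      rec(writeBin(as.double(c(b[1], 0, b[2], 0, 0, b[3])), raw(), size = 8,
                   endian = "little"))
    }
    for (k in 1:3)
      rec(writeBin(as.double(traj$coords[, k, f]), raw(), size = 4,
                   endian = "little"))
  }
  invisible(path)
}

#' Read a DCD coordinate file against a known topology
#'
#' @param path DCD file; @param top Topology data.frame supplying atom metadata
#' @param time_step ns between frames
#' @return a [trajectory()] object
#' @export
read_dcd <- function(path, top, time_step = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  xyz <- bio3d::read.dcd(path, cell = FALSE, verbose = FALSE)
  cell <- tryCatch(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE),
                   error = function(e) NULL)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); na <- ncol(xyz) / 3
  if (na != nrow(top))
    stop("DCD holds ", na, " atoms but topology has ", nrow(top))
  coords <- array(0, c(na, 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  box <- if (!is.null(cell)) as.matrix(cell[, 1:3, drop = FALSE]) else NULL
  trajectory(top, coords, box = box, time = (seq_len(nf) - 1) * time_step)
}
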