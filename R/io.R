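# On-disk formats are plain columnar text throughout: times in ps,
# distances in Angstrom, energies in kcal/mol, charges in e. No unit
# autodetection. Floats are written with 15 significant digits so
# write -> read round-trips are identity up to the last ulp or two.

.fmt_num <- function(x) formatC(x, digits = 15, format = "g")

#' Write a replica or temperature trajectory to columnar text
#'
#' First line: `#replica <id>` (or `#temperature <k>`) when the trajectory
#' carries one; second line: whitespace-separated column names; then one row
#' per frame, 15 significant digits.
#'
#' @param trajectory A data frame with a `time` column plus per-frame series.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(is.data.frame(trajectory), "time" %in% names(trajectory))
  con <- file(path, "w")
  on.exit(close(con))
  rid <- attr(trajectory, "replica_id")
  tid <- attr(trajectory, "temp_index")
  if (!is.null(rid)) writeLines(paste("#replica", rid), con)
  if (!is.null(tid)) writeLines(paste("#temperature", tid), con)
  writeLines(paste(names(trajectory), collapse = " "), con)
  if (nrow(trajectory)) {
    cols <- lapply(trajectory, function(cl)
      if (is.numeric(cl) && !is.integer(cl)) .fmt_num(cl)
      else as.character(cl))
    writeLines(do.call(paste, cols), con)
  }
  invisible(path)
}

#' Read a columnar trajectory file
#'
#' @param path File path.
#' @param schema Optional character vector of allowed column names; columns
#'   outside it raise an error. Default accepts any named columns.
#' @return A data frame of class `replica_traj` (or `temp_traj` when the
#'   header marks a temperature trajectory) with the file's columns; a
#'   header-only file yields an empty trajectory with a warning.
#' @export
read_trajectory <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines)
  rid <- tid <- NULL
  for (i in meta) {
    f <- strsplit(trimws(sub("^#", "", lines[i])), "\\s+")[[1]]
    if (length(f) == 2 && f[1] == "replica") rid <- as.integer(f[2])
    if (length(f) == 2 && f[1] == "temperature") tid <- as.integer(f[2])
  }
  body <- if (length(meta)) lines[-meta] else lines
  body_offset <- if (length(meta)) max(meta) else 0L
  if (length(body) == 0) stop("trajectory file has no header line: ", path)
  header <- strsplit(trimws(body[1]), "[,[:space:]]+")[[1]]
  if (!"time" %in% header)
    stop("trajectory file lacks the required 'time' column: ", path)
  if (!is.null(schema)) {
    bad <- setdiff(header, schema)
    if (length(bad))
      stop("unknown column(s) ", paste(bad, collapse = ", "),
           " at line ", body_offset + 1L)
  }
  rows <- body[-1]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) == 0) {
    warning("trajectory file has a header but no frames: ", path)
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(header)),
                                 header))
  } else {
    fields <- strsplit(trimws(rows), "[,[:space:]]+")
    nf <- lengths(fields)
    if (any(nf != length(header))) {
      bad <- which(nf != length(header))[1]
      stop("ragged row (", nf[bad], " fields, expected ", length(header),
           ") at line ", body_offset + 1L + bad, " of ", path)
    }
    m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = length(header), byrow = TRUE)
    if (anyNA(m)) {
      bad <- which(apply(m, 1, anyNA))[1]
      stop("non-numeric field at line ", body_offset + 1L + bad, " of ", path)
    }
    df <- as.data.frame(m)
    names(df) <- header
    if (is.unsorted(df$time, strictly = TRUE)) {
      bad <- which(diff(df$time) <= 0)[1] + 1L
      stop("time not strictly increasing at line ", body_offset + 1L + bad,
           " of ", path)
    }
  }
  for (cn in intersect(c("temp", "state", "source_replica"), names(df)))
    df[[cn]] <- as.integer(df[[cn]])
  if (!is.null(tid)) {
    attr(df, "temp_index") <- tid
    class(df) <- c("temp_traj", "data.frame")
  } else {
    if (!is.null(rid)) attr(df, "replica_id") <- rid
    class(df) <- c("replica_traj", "data.frame")
  }
  df
}

#' Write an exchange log
#'
#' One record per attempt: time (ps), the neighbouring temperature indices,
#' the replica ids occupying them, and the accepted flag (0/1).
#'
#' @param log An `exchange_log` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exchange_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  M <- attr(log, "n_temps")
  if (!is.null(M)) writeLines(paste("#n_temps", M), con)
  writeLines("time temp_lo temp_hi replica_lo replica_hi accepted", con)
  if (nrow(log))
    writeLines(paste(.fmt_num(log$time), log$temp_lo, log$temp_hi,
                     log$replica_lo, log$replica_hi,
                     as.integer(log$accepted)), con)
  invisible(path)
}

#' Read an exchange log
#'
#' Validates that recorded pairs are ladder neighbours and that replaying
#' the accepted swaps from the identity permutation reproduces the recorded
#' occupants (i.e. the log describes a valid permutation history).
#'
#' @param path File path.
#' @param n_temps Ladder size; read from the file header when present.
#' @return An `exchange_log` data frame.
#' @export
read_exchange_log <- function(path, n_temps = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  for (l in grep("^#", lines, value = TRUE)) {
    f <- strsplit(trimws(sub("^#", "", l)), "\\s+")[[1]]
    if (length(f) == 2 && f[1] == "n_temps") n_temps <- as.integer(f[2])
  }
  lines <- grep("^#", lines, value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 ||
      (length(lines) == 1 && grepl("time", lines[1]))) {
    log <- data.frame(time = numeric(0), temp_lo = integer(0),
                      temp_hi = integer(0), replica_lo = integer(0),
                      replica_hi = integer(0), accepted = logical(0))
  } else {
    start <- if (grepl("time", lines[1])) 2L else 1L
    fields <- strsplit(trimws(lines[seq(start, length(lines))]), "[,[:space:]]+")
    if (any(lengths(fields) != 6))
      stop("exchange log rows must have 6 fields (line ",
           which(lengths(fields) != 6)[1] + start - 1L, ")")
    m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = 6, byrow = TRUE)
    # replica ids (columns 4-5) are optional and may be NA
    if (anyNA(m[, c(1:3, 6)]))
      stop("non-numeric field in exchange log (line ",
           which(apply(is.na(m[, c(1:3, 6)]), 1, any))[1] + start - 1L, ")")
    log <- data.frame(time = m[, 1], temp_lo = as.integer(m[, 2]),
                      temp_hi = as.integer(m[, 3]),
                      replica_lo = as.integer(m[, 4]),
                      replica_hi = as.integer(m[, 5]),
                      accepted = m[, 6] != 0)
  }
  class(log) <- c("exchange_log", "data.frame")
  if (is.null(n_temps))
    n_temps <- if (nrow(log)) max(log$temp_hi) else 2L
  attr(log, "n_temps") <- n_temps
  .replay_snapshots(log, n_temps)   # validates neighbours + permutation
  log
}

#' Construct a molecular frame
#'
#' @param atom Atom names.
#' @param resname,resid Residue names and ids (recycled).
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param charge Optional per-atom partial charges (e).
#' @return An object of class `"molecular_frame"`.
#' @export
molecular_frame <- function(atom, xyz, resname = "UNK", resid = 1L,
                            charge = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- length(atom)
  if (nrow(xyz) != n) stop("xyz must have one row per atom")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (!is.null(charge) && length(charge) != n)
    stop("charges: need one per atom (", n, "), got ", length(charge))
  structure(list(atom = as.character(atom),
                 resname = rep_len(as.character(resname), n),
                 resid = rep_len(as.integer(resid), n),
                 xyz = xyz, charge = charge),
            class = "molecular_frame")
}

#' Read a (possibly multi-model) PDB file
#'
#' Parses fixed-width ATOM/HETATM records (coordinates from columns 31-54,
#' tolerating merged whitespace-free fields) via \pkg{bio3d}, one frame per
#' MODEL block. A light pre-validation pass reports malformed records with
#' their line numbers; a file without atom records yields an empty list
#' with a warning.
#'
#' @param path PDB file path.
#' @return A list of `molecular_frame`s.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  at <- grep("^(ATOM  |HETATM)", lines)
  if (length(at) == 0) {
    warning("no ATOM/HETATM records in ", path)
    return(list())
  }
  for (i in at) {
    l <- lines[i]
    if (nchar(l) < 54)
      stop("malformed ATOM record (too short) at line ", i, " of ", path)
    if (anyNA(suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                            substr(l, 39, 46),
                                            substr(l, 47, 54))))))
      stop("malformed coordinates in ATOM record at line ", i, " of ", path)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(m)
    molecular_frame(atom = pdb$atom$elety,
                    xyz = matrix(xyz[m, ], ncol = 3, byrow = TRUE),
                    resname = pdb$atom$resid,
                    resid = as.integer(pdb$atom$resno)))
}

#' Read a multi-frame XYZ file
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' `name x y z` line per atom; frames are concatenated and the frame count
#' is inferred from the atom-count headers.
#'
#' @param path XYZ file path.
#' @return A list of `molecular_frame`s.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 0]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop("expected an atom count at line ", i, " of ", path)
    if (i + 1L + n > length(lines))
      stop("truncated frame starting at line ", i, " of ", path)
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    if (any(lengths(rows) < 4))
      stop("malformed atom line at line ",
           i + 1L + which(lengths(rows) < 4)[1], " of ", path)
    atom <- vapply(rows, `[`, "", 1L)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- molecular_frame(atom, xyz)
    i <- i + 2L + n
  }
  frames
}

#' Read a two-column partial-charge table
#'
#' @param path Text file with `atom_name charge` per line.
#' @return A named numeric vector (charges in e); names must be unique.
#' @export
read_charges <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0) return(setNames(numeric(0), character(0)))
  fields <- strsplit(trimws(lines), "[,[:space:]]+")
  if (any(lengths(fields) != 2))
    stop("charge table rows must have 2 fields (atom name, charge)")
  nm <- vapply(fields, `[`, "", 1L)
  q <- as.numeric(vapply(fields, `[`, "", 2L))
  if (anyNA(q)) stop("non-numeric charge in table")
  if (anyDuplicated(nm))
    stop("duplicate atom name in charge table: ", nm[duplicated(nm)][1])
  setNames(q, nm)
}
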