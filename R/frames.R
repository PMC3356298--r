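#' Map active-site roles to atoms
#'
#' The geometry stage works on four named roles of the SN2 methyl-transfer
#' centre: the donor sulfur `S_delta` of AdoMet, the transferable methyl
#' carbon `C_methyl`, the acceptor nitrogen `N_zeta` of the target lysine,
#' and the exactly three substituents bonded to `N_zeta` (the epsilon carbon
#' plus, depending on the methylation state, hydrogens and/or methyl
#' carbons) from which the lone-pair direction is constructed. A role map
#' binds these roles to atom selectors in the input files; bonds are always
#' declared this way, never inferred.
#'
#' Selectors match atom labels case-insensitively. For PDB input a selector
#' may be `"RESNAME:ATOMNAME"` to additionally require the residue name;
#' a bare name matches any residue. Each of `s_delta`, `c_methyl` and
#' `n_zeta` must resolve to exactly one atom per frame; the union of matches
#' of `n_substituents` must resolve to exactly three.
#'
#' @param s_delta selector for the AdoMet sulfur.
#' @param c_methyl selector for the transferable methyl carbon.
#' @param n_zeta selector for the lysine epsilon-amino nitrogen.
#' @param n_substituents character vector of selectors whose union matches
#'   the three atoms bonded to `n_zeta`.
#' @return An object of class `role_map`.
#' @examples
#' role_map("SD", "CM", "NZ", c("CE", "HZ1", "HZ2"))
#' @export
role_map <- function(s_delta, c_methyl, n_zeta, n_substituents) {
  for (sel in list(s_delta, c_methyl, n_zeta)) {
    if (!is.character(sel) || length(sel) != 1L || !nzchar(sel)) {
      stop("each single-atom role selector must be one non-empty string",
           call. = FALSE)
    }
  }
  if (!is.character(n_substituents) || length(n_substituents) < 1L ||
      !all(nzchar(n_substituents))) {
    stop("`n_substituents` must be a non-empty character vector of selectors",
         call. = FALSE)
  }
  structure(
    list(s_delta = s_delta, c_methyl = c_methyl, n_zeta = n_zeta,
         n_substituents = n_substituents),
    class = "role_map"
  )
}

# indices of atoms matching a selector within one frame's label vectors
.match_selector <- function(names, resnames, selector) {
  selector <- trimws(selector)
  if (grepl(":", selector, fixed = TRUE)) {
    parts <- strsplit(selector, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      stop(sprintf("malformed selector '%s' (expected RESNAME:ATOMNAME)",
                   selector), call. = FALSE)
    }
    hit <- toupper(names) == toupper(parts[2L])
    if (!is.null(resnames)) {
      hit <- hit & !is.na(resnames) & toupper(resnames) == toupper(parts[1L])
    } else {
      hit <- rep(FALSE, length(names))
    }
    which(hit)
  } else {
    which(toupper(names) == toupper(selector))
  }
}

.resolve_role <- function(names, resnames, selectors, role, n_expected,
                          frame) {
  idx <- unique(unlist(lapply(selectors, .match_selector,
                              names = names, resnames = resnames)))
  if (length(idx) != n_expected) {
    stop(sprintf(
      "cannot resolve role '%s' in frame %d: matched %d atom(s), expected %d",
      role, frame, length(idx), n_expected), call. = FALSE)
  }
  sort(idx)
}

#' Assemble a series of labelled coordinate frames
#'
#' The in-memory container for trajectory snapshots of the active-site
#' subsystem. Coordinates are stored as an `n_atoms x 3 x n_frames` array in
#' angstrom; all four active-site roles are resolved eagerly, per frame, so
#' downstream geometry never touches raw labels.
#'
#' @param coords numeric array, `n_atoms x 3 x n_frames`, angstrom.
#' @param atom_names character matrix `n_atoms x n_frames` (or a vector
#'   recycled across frames) of atom labels.
#' @param role_map a [role_map()].
#' @param temperature ensemble temperature in kelvin (default 283.15).
#' @param elements optional element symbols (matrix or vector); guessed from
#'   labels when omitted.
#' @param resnames optional residue names (matrix or vector), used by
#'   `RESNAME:ATOMNAME` selectors.
#' @param index frame ordinals, strictly increasing; defaults to `1:n`.
#' @param time optional per-frame times in ps.
#' @return An object of class `frame_series` with resolved role indices.
#' @export
frame_series <- function(coords, atom_names, role_map,
                         temperature = .default_temperature,
                         elements = NULL, resnames = NULL,
                         index = NULL, time = NULL) {
  if (!inherits(role_map, "role_map")) {
    stop("`role_map` must be a role_map object", call. = FALSE)
  }
  if (length(dim(coords)) != 3L || dim(coords)[2L] != 3L) {
    stop("`coords` must be an n_atoms x 3 x n_frames array", call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("all coordinates must be finite", call. = FALSE)
  }
  n_atoms <- dim(coords)[1L]
  n_frames <- dim(coords)[3L]
  if (n_frames < 1L) stop("a frame series must be non-empty", call. = FALSE)
  .kT(temperature)  # validates

  as_mat <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) {
      if (nrow(x) != n_atoms || ncol(x) != n_frames) {
        stop(sprintf("`%s` matrix must be n_atoms x n_frames", what),
             call. = FALSE)
      }
      x
    } else {
      if (length(x) != n_atoms) {
        stop(sprintf("`%s` must have one entry per atom", what),
             call. = FALSE)
      }
      matrix(x, nrow = n_atoms, ncol = n_frames)
    }
  }
  atom_names <- as_mat(atom_names, "atom_names")
  resnames <- as_mat(resnames, "resnames")
  if (is.null(elements)) {
    elements <- apply(atom_names, 2L, function(nm) {
      vapply(nm, .guess_element, character(1L))
    })
    if (!is.matrix(elements)) elements <- matrix(elements, nrow = n_atoms)
  } else {
    elements <- as_mat(elements, "elements")
  }
  if (any(!nzchar(elements))) {
    stop("element symbols must be non-empty", call. = FALSE)
  }

  if (is.null(index)) index <- seq_len(n_frames)
  if (length(index) != n_frames || any(diff(index) <= 0)) {
    stop("`index` must be strictly increasing with one entry per frame",
         call. = FALSE)
  }
  if (!is.null(time) && length(time) != n_frames) {
    stop("`time` must have one entry per frame", call. = FALSE)
  }

  # resolve every role in every frame; errors name the role and frame
  role_index <- matrix(NA_integer_, nrow = 6L, ncol = n_frames,
                       dimnames = list(c("s_delta", "c_methyl", "n_zeta",
                                         "sub1", "sub2", "sub3"), NULL))
  for (f in seq_len(n_frames)) {
    nm <- atom_names[, f]
    rn <- if (is.null(resnames)) NULL else resnames[, f]
    role_index["s_delta", f] <-
      .resolve_role(nm, rn, role_map$s_delta, "S_delta", 1L, index[f])
    role_index["c_methyl", f] <-
      .resolve_role(nm, rn, role_map$c_methyl, "C_methyl", 1L, index[f])
    role_index["n_zeta", f] <-
      .resolve_role(nm, rn, role_map$n_zeta, "N_zeta", 1L, index[f])
    role_index[4:6, f] <-
      .resolve_role(nm, rn, role_map$n_substituents, "N_substituents", 3L,
                    index[f])
  }

  structure(
    list(coords = coords, atom_names = atom_names, elements = elements,
         resnames = resnames, index = as.integer(index), time = time,
         role_map = role_map, role_index = role_index,
         temperature = temperature),
    class = "frame_series"
  )
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> %d frame(s), %d atoms, T = %.2f K\n",
              n_frames(x), dim(x$coords)[1L], x$temperature))
  invisible(x)
}

#' Number of frames in a frame series
#' @param x a `frame_series`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "frame_series"))
  dim(x$coords)[3L]
}

# element symbol from an atom label: leading alphabetic run, two-letter
# symbols recognised explicitly, otherwise the first letter
.guess_element <- function(label) {
  alpha <- regmatches(label, regexpr("^[A-Za-z]+", label))
  if (length(alpha) == 0L || !nzchar(alpha)) return("X")
  two <- toupper(substr(alpha, 1L, 2L))
  known2 <- c("CL", "BR", "MG", "ZN", "FE", "SE", "SI", "MN", "CU")
  if (nchar(alpha) >= 2L && two %in% known2) {
    paste0(substr(two, 1L, 1L), tolower(substr(two, 2L, 2L)))
  } else {
    toupper(substr(alpha, 1L, 1L))
  }
}

# n_frames x 3 matrix of coordinates for one resolved role row
.role_coords <- function(fs, role) {
  idx <- fs$role_index[role, ]
  n <- length(idx)
  frames <- seq_len(n)
  cbind(fs$coords[cbind(idx, 1L, frames)],
        fs$coords[cbind(idx, 2L, frames)],
        fs$coords[cbind(idx, 3L, frames)])
}

#' Read trajectory frames from an XYZ or PDB file
#'
#' Reads a multi-frame coordinate file and resolves the active-site roles in
#' every frame. XYZ input is the standard concatenated dialect (atom count,
#' comment, then `label x y z` lines per frame); PDB input is
#' `MODEL`/`ENDMDL`-delimited (a file without MODEL records is one frame).
#' Coordinates are taken to be in angstrom.
#'
#' @param path path to the trajectory file.
#' @param format `"xyz"` or `"pdb"`.
#' @param role_map a [role_map()]; every role must resolve in every frame.
#' @param temperature ensemble temperature, K.
#' @return A [frame_series()].
#' @export
read_frames <- function(path, format = c("xyz", "pdb"), role_map,
                        temperature = .default_temperature) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  parsed <- switch(format,
                   xyz = .parse_xyz(path),
                   pdb = .parse_pdb(path))
  frame_series(parsed$coords, parsed$names, role_map,
               temperature = temperature,
               resnames = parsed$resnames)
}

.parse_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  n_atoms <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) {
      stop(sprintf("XYZ format error at line %d: expected an atom count", i),
           call. = FALSE)
    }
    if (is.na(n_atoms)) n_atoms <- n
    if (n != n_atoms) {
      stop(sprintf(
        "XYZ format error: frame %d has %d atoms, expected %d",
        length(frames) + 1L, n, n_atoms), call. = FALSE)
    }
    if (i + 1L + n > length(lines)) {
      stop("XYZ format error: truncated final frame", call. = FALSE)
    }
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(toks, length, integer(1L)) < 4L)
    if (length(bad) > 0L) {
      stop(sprintf("XYZ format error at line %d: expected 'label x y z'",
                   i + 1L + bad[1L]), call. = FALSE)
    }
    nm <- vapply(toks, `[[`, character(1L), 1L)
    xyz <- vapply(toks, function(t) as.numeric(t[2:4]), numeric(3L))
    if (any(is.na(xyz))) {
      stop(sprintf("XYZ format error: non-numeric coordinate in frame %d",
                   length(frames) + 1L), call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- list(names = nm, coords = t(xyz))
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("XYZ file contains no frames", call. = FALSE)
  coords <- array(NA_real_, c(n_atoms, 3L, length(frames)))
  names_m <- matrix(NA_character_, n_atoms, length(frames))
  for (f in seq_along(frames)) {
    coords[, , f] <- frames[[f]]$coords
    names_m[, f] <- frames[[f]]$names
  }
  list(coords = coords, names = names_m, resnames = NULL)
}

.parse_pdb <- function(path) {
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  is_model <- grepl("^MODEL", lines)
  is_end <- grepl("^ENDMDL", lines)
  if (!any(is_atom)) stop("PDB file contains no atom records", call. = FALSE)

  if (any(is_model)) {
    starts <- which(is_model)
    bounds <- c(which(is_model | is_end), length(lines) + 1L)
    blocks <- lapply(seq_along(starts), function(k) {
      from <- starts[k]
      to <- min(bounds[bounds > from]) - 1L
      if (!any(is_end & seq_along(lines) > from)) to <- length(lines)
      idx <- which(is_atom & seq_along(lines) > from &
                     seq_along(lines) <= to)
      lines[idx]
    })
  } else {
    blocks <- list(lines[is_atom])
  }
  blocks <- Filter(function(b) length(b) > 0L, blocks)
  if (length(blocks) == 0L) {
    stop("PDB file contains no atom records inside MODEL blocks",
         call. = FALSE)
  }
  n_atoms <- length(blocks[[1L]])
  counts <- vapply(blocks, length, integer(1L))
  if (any(counts != n_atoms)) {
    bad <- which(counts != n_atoms)[1L]
    stop(sprintf("PDB format error: model %d has %d atoms, expected %d",
                 bad, counts[bad], n_atoms), call. = FALSE)
  }
  coords <- array(NA_real_, c(n_atoms, 3L, length(blocks)))
  names_m <- matrix(NA_character_, n_atoms, length(blocks))
  res_m <- matrix(NA_character_, n_atoms, length(blocks))
  for (f in seq_along(blocks)) {
    b <- blocks[[f]]
    names_m[, f] <- trimws(substr(b, 13L, 16L))
    res_m[, f] <- trimws(substr(b, 18L, 20L))
    x <- suppressWarnings(as.numeric(substr(b, 31L, 38L)))
    y <- suppressWarnings(as.numeric(substr(b, 39L, 46L)))
    z <- suppressWarnings(as.numeric(substr(b, 47L, 54L)))
    if (any(is.na(c(x, y, z)))) {
      stop(sprintf("PDB format error: non-numeric coordinate in model %d", f),
           call. = FALSE)
    }
    coords[, , f] <- cbind(x, y, z)
  }
  list(coords = coords, names = names_m, resnames = res_m)
}

#' Write a frame series as a multi-frame XYZ file
#'
#' Coordinates are written with full double precision (`%.17g`) so a
#' write/read round trip reproduces them exactly.
#'
#' @param fs a [frame_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frames_xyz <- function(fs, path) {
  stopifnot(inherits(fs, "frame_series"))
  n_atoms <- dim(fs$coords)[1L]
  out <- character(0L)
  for (f in seq_len(n_frames(fs))) {
    header <- c(as.character(n_atoms),
                sprintf("frame %d", fs$index[f]))
    body <- sprintf("%s %.17g %.17g %.17g",
                    fs$atom_names[, f],
                    fs$coords[, 1L, f], fs$coords[, 2L, f],
                    fs$coords[, 3L, f])
    out <- c(out, header, body)
  }
  writeLines(out, path)
  invisible(path)
}
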