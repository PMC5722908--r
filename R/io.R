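#' Write bead coordinates to PDB or XYZ
#'
#' The PDB dialect is minimal fixed-column ATOM/HETATM records (one bead
#' per residue, chain A, occupancy/B-factor written as 1.00/0.00 and
#' ignored on read); coordinates are stored at the format's 3-decimal
#' precision in Angstrom. XYZ stores 9 decimals. Site labels from the
#' system (when given) become atom names; an `ion` site is written as a
#' HETATM with element MG.
#'
#' @param coords `n x 3` coordinate matrix (finite).
#' @param path output file.
#' @param format `"pdb"` or `"xyz"` (default guessed from the extension).
#' @param system optional [particle_system()] supplying site labels.
#' @param comment title/comment line.
#' @return `path`, invisibly.
#' @export
write_structure <- function(coords, path, format = NULL, system = NULL,
                            comment = "stepmd bead model") {
  coords <- .as_coords(coords)
  if (any(!is.finite(coords))) stop("coordinates must be finite",
                                    call. = FALSE)
  format <- .guess_format(path, format, c("pdb", "xyz"))
  n <- nrow(coords)
  names <- rep("B", n)
  ion_i <- integer(0)
  if (!is.null(system)) {
    stopifnot(inherits(system, "particle_system"))
    for (lb in names(system$labels)) {
      names[system$labels[[lb]]] <- toupper(substr(lb, 1, 4))
    }
    if ("ion" %in% names(system$labels)) ion_i <- system$labels[["ion"]]
  }
  if (format == "xyz") {
    lines <- c(as.character(n), comment,
               sprintf("%-4s %.9f %.9f %.9f", names,
                       coords[, 1], coords[, 2], coords[, 3]))
  } else {
    rec <- ifelse(seq_len(n) %in% ion_i, "HETATM", "ATOM  ")
    elem <- ifelse(seq_len(n) %in% ion_i, "MG", " C")
    lines <- c(sprintf("TITLE     %s", comment),
               sprintf("%s%5d %-4s%s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       rec, seq_len(n), substr(names, 1, 4), " BEA",
                       seq_len(n) %% 10000,
                       coords[, 1], coords[, 2], coords[, 3], 1, 0, elem),
               "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read bead coordinates from PDB or XYZ
#'
#' @param path input file.
#' @param format `"pdb"` or `"xyz"` (default guessed from the extension).
#' @return `n x 3` coordinate matrix with an `atom_names` attribute.
#'   Malformed records raise an error naming the offending line.
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- .guess_format(path, format, c("pdb", "xyz"))
  lines <- readLines(path)
  if (format == "xyz") {
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n)) stop("parse error at line 1: expected atom count",
                       call. = FALSE)
    if (length(lines) < n + 2) {
      stop("truncated XYZ file: expected ", n, " atom lines", call. = FALSE)
    }
    coords <- matrix(NA_real_, n, 3)
    names <- character(n)
    for (k in seq_len(n)) {
      ln <- n_line <- k + 2
      parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts[2:4]))
      if (length(parts) < 4 || any(is.na(vals))) {
        stop("parse error at line ", ln, ": expected `name x y z`",
             call. = FALSE)
      }
      names[k] <- parts[1]
      coords[k, ] <- vals
    }
  } else {
    is_atom <- grepl("^(ATOM  |HETATM)", lines)
    if (!any(is_atom)) stop("no ATOM/HETATM records in ", path,
                            call. = FALSE)
    rows <- which(is_atom)
    coords <- matrix(NA_real_, length(rows), 3)
    names <- character(length(rows))
    for (k in seq_along(rows)) {
      ln <- rows[k]
      line <- lines[ln]
      if (nchar(line) < 54) {
        stop("parse error at line ", ln, ": missing coordinate columns",
             call. = FALSE)
      }
      vals <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                            substr(line, 39, 46),
                                            substr(line, 47, 54))))
      if (any(is.na(vals))) {
        stop("parse error at line ", ln, ": non-numeric coordinates",
             call. = FALSE)
      }
      names[k] <- trimws(substr(line, 13, 16))
      coords[k, ] <- vals
    }
  }
  attr(coords, "atom_names") <- names
  coords
}

.guess_format <- function(path, format, allowed) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  if (!format %in% allowed) {
    stop("unknown format: ", format, " (expected ",
         paste(allowed, collapse = "/"), ")", call. = FALSE)
  }
  format
}

#' Write a trajectory to the package's text container
#'
#' A self-describing text format: a header with the particle count and
#' bias-channel names, then per frame a `frame` line carrying the time,
#' potential energy and channel values at full double precision (`%.17g`,
#' so round-trips are bit-exact), followed by one coordinate line per
#' particle.
#'
#' @param trajectory an `md_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  nf <- n_frames(trajectory)
  np <- dim(trajectory$coords)[1]
  channels <- colnames(trajectory$bias)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#stepmd-trajectory v1",
               paste("n_particles", np),
               paste("channels", if (length(channels)) {
                 paste(channels, collapse = ",")
               } else "-")), con)
  for (i in seq_len(nf)) {
    dv <- if (length(channels)) {
      paste0(" dv=", paste(sprintf("%.17g", trajectory$bias[i, ]),
                           collapse = ","))
    } else ""
    writeLines(sprintf("frame t=%.17g energy=%.17g%s",
                       trajectory$times[i], trajectory$energy[i], dv), con)
    writeLines(sprintf("%.17g %.17g %.17g",
                       trajectory$coords[, 1, i],
                       trajectory$coords[, 2, i],
                       trajectory$coords[, 3, i]), con)
  }
  invisible(path)
}

#' Read a trajectory from the package's text container
#'
#' @param path input file.
#' @param system optional [particle_system()] to attach (needed by
#'   label-based analyses).
#' @return an `md_trajectory`. A truncated file raises an error stating
#'   how many complete frames were recovered.
#' @export
read_trajectory <- function(path, system = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "#stepmd-trajectory v1") {
    stop("not a stepmd trajectory file: ", path, call. = FALSE)
  }
  np <- as.integer(strsplit(lines[2], " ")[[1]][2])
  ch_spec <- strsplit(lines[3], " ")[[1]][2]
  channels <- if (ch_spec == "-") character(0) else
    strsplit(ch_spec, ",")[[1]]
  pos <- 4L
  times <- numeric(0); energy <- numeric(0)
  coords <- list(); bias <- list()
  nf <- 0L
  while (pos <= length(lines)) {
    header <- lines[pos]
    if (!grepl("^frame ", header)) {
      stop("parse error at line ", pos, ": expected frame header",
           call. = FALSE)
    }
    if (pos + np > length(lines)) {
      stop("truncated trajectory: ", nf,
           " complete frame(s) recovered before line ", pos, call. = FALSE)
    }
    t <- as.numeric(sub(".*t=([^ ]+).*", "\\1", header))
    e <- as.numeric(sub(".*energy=([^ ]+).*", "\\1", header))
    dv <- if (length(channels)) {
      as.numeric(strsplit(sub(".*dv=([^ ]+).*", "\\1", header), ",")[[1]])
    } else numeric(0)
    block <- lines[(pos + 1):(pos + np)]
    xyz <- matrix(as.numeric(unlist(strsplit(block, " "))), np, 3,
                  byrow = TRUE)
    if (any(is.na(xyz)) || is.na(t)) {
      stop("truncated trajectory: ", nf,
           " complete frame(s) recovered before line ", pos, call. = FALSE)
    }
    nf <- nf + 1L
    times[nf] <- t; energy[nf] <- e
    coords[[nf]] <- xyz; bias[[nf]] <- dv
    pos <- pos + np + 1L
  }
  coords_arr <- array(NA_real_, c(np, 3, max(nf, 0L)))
  for (i in seq_len(nf)) coords_arr[, , i] <- coords[[i]]
  bias_mat <- if (length(channels)) {
    do.call(rbind, bias)
  } else {
    matrix(0, nf, 0)
  }
  if (length(channels)) colnames(bias_mat) <- channels
  if (nf == 0L) {
    coords_arr <- array(NA_real_, c(np, 3, 0))
    bias_mat <- matrix(0, 0, length(channels),
                       dimnames = list(NULL, channels))
  }
  new_md_trajectory(times = times, coords = coords_arr, energy = energy,
                    bias = bias_mat, system = system,
                    metadata = list(source = path))
}
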