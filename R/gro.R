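# GRO (Gromacs coordinate) text I/O for bilayer frames.
#
# Fixed-column dialect: per frame a title line, an atom-count line, one
# fixed-width atom line per atom ("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", nm), and a
# box line whose first two fields are taken as Lx and Ly. Velocities, if
# present, are ignored. Atom naming convention used by the writer (and the
# default selection map): "P" for the phosphate marker, "C<k>" for chain
# carbon k, "H<k>A"/"H<k>B" for its two hydrogens.

#' Default atom-name selection map for GRO input
#'
#' Maps atom names to structural roles: exact names in `phosphate`, regular
#' expressions with one capture group (the chain position) for `carbon` and
#' `hydrogen`. Hydrogens are bonded to the same-position carbon within the
#' same residue.
#'
#' @return a list usable as `selection_map` in [read_gro()].
#' @export
default_selection_map <- function() {
  list(phosphate = "P",
       carbon = "^C([0-9]+)$",
       hydrogen = "^H([0-9]+)[A-Z]?$")
}

#' Write bilayer frames to a GRO file
#'
#' @param frames a `bilayer_trajectory` or single `bilayer_frame`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_gro <- function(frames, path) {
  if (inherits(frames, "bilayer_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    a <- fr$atoms
    name <- character(nrow(a))
    name[a$role == "phosphate"] <- "P"
    cc <- a$role == "chain_carbon"
    name[cc] <- sprintf("C%d", a$chain_pos[cc])
    hh <- a$role == "chain_hydrogen"
    # alternate A/B suffix per carbon: order within (lipid, chain_pos)
    if (any(hh)) {
      key <- paste(a$lipid_id[hh], a$chain_pos[hh])
      suffix <- stats::ave(seq_along(key), key, FUN = seq_along)
      name[hh] <- sprintf("H%d%s", a$chain_pos[hh], c("A", "B")[suffix])
    }
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     a$lipid_id %% 100000L, "LIP", name,
                     a$atom_id %% 100000L, a$x, a$y, a$z)
    writeLines(c(sprintf("synthetic bilayer frame %d", f),
                 sprintf("%5d", nrow(a)),
                 lines,
                 sprintf("%10.5f%10.5f%10.5f",
                         fr$box[["lx"]], fr$box[["ly"]], fr$box[["lz"]])),
               con)
  }
  invisible(path)
}

# parse one frame's atom lines (vectorized fixed columns)
parse_gro_atoms <- function(lines, line_numbers, selection_map, strict) {
  resid <- trimws(substr(lines, 1, 5))
  name <- trimws(substr(lines, 11, 15))
  xs <- substr(lines, 21, 28)
  ys <- substr(lines, 29, 36)
  zs <- substr(lines, 37, 44)
  x <- suppressWarnings(as.numeric(xs))
  y <- suppressWarnings(as.numeric(ys))
  z <- suppressWarnings(as.numeric(zs))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0L)
    abort2(sprintf("malformed GRO coordinate field at line %d",
                   line_numbers[bad[1L]]), "parse_error")

  role <- rep(NA_character_, length(lines))
  chain_pos <- rep(NA_integer_, length(lines))
  role[name %in% selection_map$phosphate] <- "phosphate"
  mc <- regmatches(name, regexec(selection_map$carbon, name))
  is_c <- lengths(mc) == 2L
  role[is_c] <- "chain_carbon"
  chain_pos[is_c] <- as.integer(vapply(mc[is_c], `[[`, character(1), 2L))
  mh <- regmatches(name, regexec(selection_map$hydrogen, name))
  is_h <- is.na(role) & lengths(mh) == 2L
  role[is_h] <- "chain_hydrogen"
  chain_pos[is_h] <- as.integer(vapply(mh[is_h], `[[`, character(1), 2L))

  if (anyNA(role)) {
    unmapped <- unique(name[is.na(role)])
    msg <- paste0("atom name(s) not in selection map: ",
                  paste(unmapped, collapse = ", "))
    if (strict) abort2(msg, "unmapped_atom") else warning(msg, call. = FALSE)
  }

  # residue id can wrap at 100000; a change in the printed id marks a new lipid
  lipid_id <- cumsum(c(TRUE, resid[-1L] != resid[-length(resid)]))
  data.frame(lipid_id = lipid_id, role = role, chain_pos = chain_pos,
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

#' Read bilayer frames from a GRO file
#'
#' Roles come from `selection_map`; C-H bonds are reconstructed by matching
#' hydrogen chain positions to the same-position carbon within each residue.
#' Leaflets are assigned from geometry: lipids whose phosphate sits above the
#' median phosphate z are "upper". Unmapped atom names are dropped with a
#' warning unless `strict = TRUE`.
#'
#' @param path GRO file path.
#' @param selection_map see [default_selection_map()].
#' @param strict error (rather than warn) on unmapped atom names.
#' @return a `bilayer_trajectory`.
#' @export
read_gro <- function(path, selection_map = default_selection_map(),
                     strict = FALSE) {
  raw <- readLines(path)
  frames <- list()
  pos <- 1L
  while (pos <= length(raw)) {
    if (!nzchar(trimws(raw[pos])) && pos == length(raw)) break
    natoms <- suppressWarnings(as.integer(trimws(raw[pos + 1L])))
    if (is.na(natoms))
      abort2(sprintf("malformed atom-count line at line %d", pos + 1L),
             "parse_error")
    atom_lines <- raw[(pos + 2L):(pos + 1L + natoms)]
    parsed <- parse_gro_atoms(atom_lines, (pos + 2L):(pos + 1L + natoms),
                              selection_map, strict)
    box_fields <- strsplit(trimws(raw[pos + 2L + natoms]), "\\s+")[[1L]]
    box <- suppressWarnings(as.numeric(box_fields))
    if (length(box) < 2L || anyNA(box[1:2]))
      abort2(sprintf("malformed box line at line %d", pos + 2L + natoms),
             "parse_error")
    lz <- if (length(box) >= 3L && !is.na(box[3L])) box[3L] else NA_real_

    a <- parsed[!is.na(parsed$role), , drop = FALSE]
    a$atom_id <- seq_len(nrow(a))
    # leaflet from geometry: phosphate z relative to the median phosphate z
    pz <- a$z[a$role == "phosphate"]
    plip <- a$lipid_id[a$role == "phosphate"]
    if (length(pz) == 0L)
      abort2("no phosphate atoms matched the selection map", "selection_error")
    mid <- stats::median(pz)
    upper_lipids <- plip[pz > mid]
    lower_lipids <- plip[pz <= mid]
    if (length(upper_lipids) == 0L || length(lower_lipids) == 0L)
      abort2("cannot partition lipids into two leaflets (all phosphates on one side)",
             "leaflet_partition_error")
    a$leaflet <- ifelse(a$lipid_id %in% upper_lipids, "upper", "lower")

    # reconstruct C-H bonds within (lipid, chain position)
    ckey <- paste(a$lipid_id, a$chain_pos)
    cid <- a$atom_id[a$role == "chain_carbon"]
    cmap <- stats::setNames(cid, ckey[a$role == "chain_carbon"])
    hsel <- a$role == "chain_hydrogen"
    carbon_of <- cmap[ckey[hsel]]
    if (anyNA(carbon_of)) {
      msg <- "hydrogen without a same-position carbon in its residue"
      if (strict) abort2(msg, "topology_error") else warning(msg, call. = FALSE)
    }
    keep <- !is.na(carbon_of)
    bonds <- data.frame(carbon = unname(carbon_of[keep]),
                        hydrogen = a$atom_id[hsel][keep])

    frames[[length(frames) + 1L]] <- structure(
      list(box = c(lx = box[1L], ly = box[2L], lz = lz),
           atoms = a[, c("atom_id", "lipid_id", "leaflet", "role",
                         "chain_pos", "x", "y", "z")],
           bonds = bonds),
      class = "bilayer_frame")
    pos <- pos + 3L + natoms
  }
  if (length(frames) == 0L) abort2("no frames found", "parse_error")
  structure(frames, class = "bilayer_trajectory")
}
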