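# Synthetic bilayer generator.
#
# Produces idealized two-leaflet coordinate frames with analytically known
# area per lipid (box area / lipids per leaflet), phosphate-plane thickness
# (z_upper - z_lower in expectation) and C-H order parameter (closed form for
# fixed-tilt and cone modes, zero for isotropic). These frames are the test
# oracle for the trajectory-analysis routines; they carry no physics.

CH_BOND_NM <- 0.109   # carbon-hydrogen bond length
CC_STEP_NM <- 0.127   # z spacing between successive chain carbons

#' Specify a synthetic bilayer
#'
#' @param n_lipids_per_leaflet lipids per leaflet (> 0).
#' @param box_lx,box_ly lateral box dimensions in nm.
#' @param phosphate_z_upper,phosphate_z_lower mean phosphate plane z (nm);
#'   upper must exceed lower.
#' @param phosphate_z_jitter_sd Gaussian jitter of phosphate z (nm, >= 0).
#' @param chain_carbons carbons per acyl chain (>= 2); each carries two
#'   hydrogens.
#' @param ch_tilt_mode C-H orientation model: `"fixed_angle"` (all bonds at
#'   `tilt_angle_deg` from the membrane normal, mirrored in the lower
#'   leaflet), `"isotropic"` (uniform on the sphere) or `"wobble_cone"`
#'   (fixed polar angle, uniform azimuth).
#' @param tilt_angle_deg polar angle in degrees for the fixed/cone modes.
#' @param n_frames number of frames to generate.
#' @param seed integer RNG seed; identical specs give byte-identical frames.
#' @return an object of class `bilayer_spec`.
#' @export
bilayer_spec <- function(n_lipids_per_leaflet,
                         box_lx, box_ly,
                         phosphate_z_upper = 2.16,
                         phosphate_z_lower = -2.16,
                         phosphate_z_jitter_sd = 0,
                         chain_carbons = 16L,
                         ch_tilt_mode = c("fixed_angle", "isotropic", "wobble_cone"),
                         tilt_angle_deg = 0,
                         n_frames = 1L,
                         seed = 1L) {
  ch_tilt_mode <- match.arg(ch_tilt_mode)
  ok <- is.numeric(n_lipids_per_leaflet) && n_lipids_per_leaflet >= 1 &&
    box_lx > 0 && box_ly > 0 &&
    phosphate_z_upper > phosphate_z_lower &&
    phosphate_z_jitter_sd >= 0 &&
    chain_carbons >= 2 && n_frames >= 1
  if (!ok) abort2("invalid bilayer specification", "validation_error")
  structure(list(
    n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
    box_lx = box_lx, box_ly = box_ly,
    phosphate_z_upper = phosphate_z_upper,
    phosphate_z_lower = phosphate_z_lower,
    phosphate_z_jitter_sd = phosphate_z_jitter_sd,
    chain_carbons = as.integer(chain_carbons),
    ch_tilt_mode = ch_tilt_mode,
    tilt_angle_deg = tilt_angle_deg,
    n_frames = as.integer(n_frames),
    seed = as.integer(seed)
  ), class = "bilayer_spec")
}

# unit direction vectors for n C-H bonds in one leaflet
ch_directions <- function(n, mode, tilt_deg, mirror) {
  if (mode == "isotropic") {
    cz <- stats::runif(n, -1, 1)
    phi <- stats::runif(n, 0, 2 * pi)
    s <- sqrt(pmax(0, 1 - cz^2))
    dir <- cbind(s * cos(phi), s * sin(phi), cz)
  } else {
    theta <- tilt_deg * pi / 180
    phi <- stats::runif(n, 0, 2 * pi)
    dir <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi),
                 rep(cos(theta), n))
    if (mirror) dir[, 3] <- -dir[, 3]
  }
  dir
}

#' Generate synthetic bilayer frames
#'
#' True values by construction: area per lipid `box_lx * box_ly /
#' n_lipids_per_leaflet`; thickness `phosphate_z_upper - phosphate_z_lower`
#' in expectation; order parameter `(3 cos^2(tilt) - 1) / 2` for the
#' fixed-angle and cone modes and 0 for isotropic orientations.
#'
#' @param spec a [bilayer_spec()].
#' @return a `bilayer_trajectory`: list of frames, each a list with `box`
#'   (lx, ly, lz in nm), `atoms` (atom_id, lipid_id, leaflet, role,
#'   chain_pos, x, y, z) and `bonds` (carbon, hydrogen atom-id pairs).
#' @export
generate_bilayer <- function(spec) {
  stopifnot(inherits(spec, "bilayer_spec"))
  set.seed(spec$seed)
  n <- spec$n_lipids_per_leaflet
  nx <- ceiling(sqrt(n)); ny <- ceiling(n / nx)
  i <- seq_len(n) - 1L
  gx <- ((i %% nx) + 0.5) * spec$box_lx / nx
  gy <- ((i %/% nx) + 0.5) * spec$box_ly / ny
  nc <- spec$chain_carbons
  half_span <- abs(c(spec$phosphate_z_upper, spec$phosphate_z_lower))
  lz <- diff(range(spec$phosphate_z_lower, spec$phosphate_z_upper)) +
    6 * spec$phosphate_z_jitter_sd + 1

  frames <- vector("list", spec$n_frames)
  atoms_per_lipid <- 1L + 3L * nc  # P + carbons + 2 H each

  for (f in seq_len(spec$n_frames)) {
    rows <- vector("list", 2L)
    bonds <- vector("list", 2L)
    offset <- 0L
    for (li in 1:2) {
      leaflet <- c("upper", "lower")[li]
      z0 <- if (li == 1L) spec$phosphate_z_upper else spec$phosphate_z_lower
      dirsign <- if (li == 1L) -1 else 1   # chains point toward the midplane
      pz <- rep(z0, n) + if (spec$phosphate_z_jitter_sd > 0)
        stats::rnorm(n, 0, spec$phosphate_z_jitter_sd) else 0

      lipid_id <- (li - 1L) * n + seq_len(n)
      # phosphates
      p_id <- offset + seq_len(n)
      # carbons: chain_pos 1..nc per lipid
      cpos <- rep(seq_len(nc), times = n)
      clip <- rep(seq_len(n), each = nc)
      c_id <- offset + n + seq_len(n * nc)
      cz <- pz[clip] + dirsign * (0.1 + (cpos - 1L) * CC_STEP_NM)
      # two hydrogens per carbon
      h_id <- offset + n + n * nc + seq_len(2L * n * nc)
      hc <- rep(c_id, each = 2L)                    # bonded carbon id
      dir <- ch_directions(2L * n * nc, spec$ch_tilt_mode,
                           spec$tilt_angle_deg, mirror = li == 2L)
      cidx <- rep(seq_len(n * nc), each = 2L)
      hx <- gx[clip][cidx] + CH_BOND_NM * dir[, 1]
      hy <- gy[clip][cidx] + CH_BOND_NM * dir[, 2]
      hz <- cz[cidx] + CH_BOND_NM * dir[, 3]

      rows[[li]] <- data.frame(
        atom_id = c(p_id, c_id, h_id),
        lipid_id = c(lipid_id, lipid_id[clip], lipid_id[clip][cidx]),
        leaflet = leaflet,
        role = c(rep("phosphate", n), rep("chain_carbon", n * nc),
                 rep("chain_hydrogen", 2L * n * nc)),
        chain_pos = c(rep(NA_integer_, n), cpos, cpos[cidx]),
        x = c(gx, gx[clip], hx),
        y = c(gy, gy[clip], hy),
        z = c(pz, cz, hz),
        stringsAsFactors = FALSE
      )
      bonds[[li]] <- data.frame(carbon = hc, hydrogen = h_id)
      offset <- offset + n * atoms_per_lipid
    }
    atoms <- do.call(rbind, rows)
    all_bonds <- do.call(rbind, bonds)
    # contiguous residues: group atoms per lipid (GRO convention), renumber
    ord <- order(atoms$lipid_id, atoms$atom_id)
    atoms <- atoms[ord, , drop = FALSE]
    idmap <- integer(max(atoms$atom_id))
    idmap[atoms$atom_id] <- seq_len(nrow(atoms))
    atoms$atom_id <- seq_len(nrow(atoms))
    all_bonds$carbon <- idmap[all_bonds$carbon]
    all_bonds$hydrogen <- idmap[all_bonds$hydrogen]
    rownames(atoms) <- NULL
    frames[[f]] <- structure(
      list(box = c(lx = spec$box_lx, ly = spec$box_ly, lz = lz),
           atoms = atoms, bonds = all_bonds),
      class = "bilayer_frame")
  }
  structure(frames, class = "bilayer_trajectory", spec = spec)
}

#' True structural values implied by a bilayer spec
#'
#' @param spec a [bilayer_spec()].
#' @return list with `apl` (nm^2), `mt` (nm) and `scd` (NA for isotropic
#'   azimuth-free expectation 0 is returned as 0).
#' @export
bilayer_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "bilayer_spec"))
  scd <- switch(spec$ch_tilt_mode,
    isotropic = 0,
    0.5 * (3 * cos(spec$tilt_angle_deg * pi / 180)^2 - 1))
  list(apl = spec$box_lx * spec$box_ly / spec$n_lipids_per_leaflet,
       mt = spec$phosphate_z_upper - spec$phosphate_z_lower,
       scd = scd)
}
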