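# Structural property estimation from bilayer coordinate frames.
#
# Three standard bilayer descriptors, each time-averaged over frames with a
# population standard deviation:
#   APL  = <Lx * Ly / N>, N lipids in one leaflet (nm^2)
#   MT   = <mean phosphate z, upper leaflet  -  mean phosphate z, lower> (nm)
#   S_CD = 1/2 <3 cos^2(theta) - 1>, theta the C-H bond angle to +z
# The membrane normal is fixed to the z axis (planar bilayer convention);
# frames are assumed whole (no periodic-boundary unwrapping).

as_trajectory <- function(frames) {
  if (inherits(frames, "bilayer_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1L,
            all(vapply(frames, inherits, logical(1), "bilayer_frame")))
  frames
}

#' Property estimate container
#'
#' @param name one of `"APL"`, `"MT"`, `"SCD"`.
#' @param values per-frame (or per-replicate) values.
#' @param per_carbon_profile optional `data.frame` (chain_pos, mean, sd).
#' @return object of class `property_estimate` with `mean`, `sd`
#'   (population), `n_frames` and the raw `values`.
#' @export
property_estimate <- function(name, values, per_carbon_profile = NULL) {
  stopifnot(name %in% c("APL", "MT", "SCD"), length(values) >= 1L)
  structure(list(name = name, mean = mean(values), sd = pop_sd(values),
                 n_frames = length(values), values = values,
                 per_carbon_profile = per_carbon_profile),
            class = "property_estimate")
}

#' @export
print.property_estimate <- function(x, ...) {
  unit <- switch(x$name, APL = "nm^2", MT = "nm", SCD = "")
  cat(sprintf("%s: %.4f +/- %.4f %s (n = %d)\n",
              x$name, x$mean, x$sd, unit, x$n_frames))
  invisible(x)
}

#' Area per lipid
#'
#' Per frame, lateral box area divided by the number of lipids in one
#' leaflet, then averaged over frames.
#'
#' @param frames a `bilayer_trajectory` (or single frame).
#' @param n_per_leaflet lipids per leaflet; defaults to the count of lipids
#'   labelled `upper` in the first frame.
#' @return a [property_estimate()] in nm^2.
#' @export
area_per_lipid <- function(frames, n_per_leaflet = NULL) {
  frames <- as_trajectory(frames)
  if (is.null(n_per_leaflet)) {
    a1 <- frames[[1L]]$atoms
    n_per_leaflet <- length(unique(a1$lipid_id[a1$leaflet == "upper"]))
  }
  if (!is.numeric(n_per_leaflet) || n_per_leaflet <= 0)
    abort2("no lipids in leaflet", "undefined_metric")
  vals <- vapply(frames, function(fr)
    fr$box[["lx"]] * fr$box[["ly"]] / n_per_leaflet, numeric(1))
  property_estimate("APL", vals)
}

#' Membrane thickness from phosphate planes
#'
#' Per frame, leaflets are identified from geometry (phosphate z against the
#' median phosphate z) so the estimate is positive by construction and
#' invariant under rigid translation; the thickness is the difference of the
#' per-leaflet mean phosphate z.
#'
#' @param frames a `bilayer_trajectory`.
#' @return a [property_estimate()] in nm.
#' @export
membrane_thickness <- function(frames) {
  frames <- as_trajectory(frames)
  vals <- vapply(frames, function(fr) {
    pz <- fr$atoms$z[fr$atoms$role == "phosphate"]
    if (length(pz) < 2L)
      abort2("need phosphates in both leaflets", "undefined_metric")
    mid <- stats::median(pz)
    up <- pz[pz > mid]; lo <- pz[pz <= mid]
    if (length(up) == 0L || length(lo) == 0L)
      abort2("a leaflet has no phosphates", "undefined_metric")
    mean(up) - mean(lo)
  }, numeric(1))
  property_estimate("MT", vals)
}

#' Deuterium (C-H) order parameter
#'
#' For every carbon-hydrogen bond, `s = (3 cos^2(theta) - 1) / 2` with theta
#' the angle to the +z membrane normal; bonds are averaged within a frame and
#' the mean/sd taken over frames. A per-carbon profile (mean and sd over
#' frames of the per-position frame averages) is attached.
#'
#' @param frames a `bilayer_trajectory`.
#' @param chain_positions optional integer vector restricting the carbons
#'   included in the chain average.
#' @return a [property_estimate()] (dimensionless, in `[-0.5, 1]`).
#' @export
order_parameter <- function(frames, chain_positions = NULL) {
  frames <- as_trajectory(frames)
  per_frame <- lapply(frames, function(fr) {
    a <- fr$atoms; b <- fr$bonds
    if (is.null(b) || nrow(b) == 0L)
      abort2("frame has no C-H bonds", "undefined_metric")
    ci <- match(b$carbon, a$atom_id)
    hi <- match(b$hydrogen, a$atom_id)
    pos <- a$chain_pos[ci]
    if (!is.null(chain_positions)) {
      keep <- pos %in% chain_positions
      if (!any(keep)) abort2("empty chain-position selection", "undefined_metric")
      ci <- ci[keep]; hi <- hi[keep]; pos <- pos[keep]
    }
    dx <- a$x[hi] - a$x[ci]; dy <- a$y[hi] - a$y[ci]; dz <- a$z[hi] - a$z[ci]
    cz <- dz / sqrt(dx^2 + dy^2 + dz^2)
    s <- 0.5 * (3 * cz^2 - 1)
    list(mean = mean(s), by_pos = tapply(s, pos, mean))
  })
  vals <- vapply(per_frame, `[[`, numeric(1), "mean")
  pos_names <- sort(unique(unlist(lapply(per_frame, function(p) names(p$by_pos)))))
  prof <- do.call(rbind, lapply(pos_names, function(p) {
    v <- vapply(per_frame, function(x)
      if (p %in% names(x$by_pos)) x$by_pos[[p]] else NA_real_, numeric(1))
    v <- v[!is.na(v)]
    data.frame(chain_pos = as.integer(p), mean = mean(v), sd = pop_sd(v))
  }))
  property_estimate("SCD", vals, per_carbon_profile = prof)
}

#' Aggregate property estimates across replicates
#'
#' MD-ensemble convention: the first `k` replicate means are averaged,
#' giving ensembles of comparable size across systems; across replicates
#' the sample (n-1) sd is reported (within a replicate, sds over frames are
#' population sds).
#'
#' @param estimates list of [property_estimate()] objects of the same
#'   property.
#' @param k number of replicates to use (default 3).
#' @return a [property_estimate()] whose `values` are the replicate means.
#' @export
replicate_summary <- function(estimates, k = 3L) {
  stopifnot(is.list(estimates),
            all(vapply(estimates, inherits, logical(1), "property_estimate")))
  if (length(estimates) < k)
    abort2(sprintf("need at least %d replicates, got %d", k, length(estimates)),
           "insufficient_replicates")
  nm <- unique(vapply(estimates, `[[`, character(1), "name"))
  if (length(nm) != 1L)
    abort2("replicates mix different properties", "invalid_argument")
  means <- vapply(estimates[seq_len(k)], `[[`, numeric(1), "mean")
  out <- property_estimate(nm, means)
  out$sd <- if (k > 1L) stats::sd(means) else 0
  out
}
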