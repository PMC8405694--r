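# Construction and audit of the model membrane compositions.
#
# The reference ("null") systems hold 64 or 256 lipids with fixed sterol and
# sphingolipid counts; very-long-chain glycerophospholipids are introduced by
# replacing DOPC and POPI in equal numbers, each family split C20:C22:C24 in a
# fixed 4:2:1 ratio, so substitutions come in blocks of 14 molecules
# (2 families x (4 + 2 + 1)).

#' Create a membrane composition
#'
#' @param system_name identifier for the system.
#' @param counts named non-negative integer vector; names must be species in
#'   [lipid_registry()].
#' @return an object of class `membrane_composition`.
#' @export
membrane_composition <- function(system_name, counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    abort2("counts must be a named vector", "invalid_argument")
  unknown <- setdiff(names(counts), lipid_registry()$name)
  if (length(unknown) > 0L)
    abort2(paste0("unknown lipid species: ", paste(unknown, collapse = ", ")),
           "invalid_argument")
  if (any(counts < 0) || any(counts != round(counts)))
    abort2("counts must be non-negative integers", "invalid_argument")
  structure(
    list(system_name = system_name,
         counts = stats::setNames(as.integer(counts), names(counts))),
    class = "membrane_composition"
  )
}

#' @export
print.membrane_composition <- function(x, ...) {
  cat("Membrane composition:", x$system_name,
      sprintf("(%d lipids)\n", sum(x$counts)))
  print(x$counts[x$counts > 0L])
  invisible(x)
}

#' Build a reference (null) yeast bilayer composition
#'
#' The 256-lipid reference holds 40 ERG, 40 IPC, 88 DOPC and 88 POPI; the
#' 64-lipid variant holds 10/10/22/22.
#'
#' @param n_lipids total lipid count, 64 or 256.
#' @return a [membrane_composition()].
#' @export
#' @examples
#' build_null_system(256)
build_null_system <- function(n_lipids) {
  if (!(is.numeric(n_lipids) && length(n_lipids) == 1L && n_lipids %in% c(64, 256)))
    abort2("n_lipids must be 64 or 256", "invalid_argument")
  base <- c(ERG = 10L, IPC = 10L, DOPC = 22L, POPI = 22L)
  if (n_lipids == 256) base <- base * 4L
  membrane_composition(if (n_lipids == 64) "Null-64" else "Null-256", base)
}

#' Substitute very-long-chain glycerophospholipids into a null system
#'
#' Replaces DOPC and POPI with sn1-elongated species (C20, C22, C24) so that
#' roughly `target_pct_gpl` percent of the glycerophospholipids are
#' very-long-chain. Substitutions are quantized to blocks of 14 molecules:
#' per family (PC and PI) the C20:C22:C24 species are added 4:2:1. Ergosterol
#' and IPC counts are untouched and the total lipid count is conserved.
#'
#' @param base a null composition from [build_null_system()].
#' @param target_pct_gpl target very-long-chain percentage of GPLs, in (0,100].
#' @return a [membrane_composition()].
#' @export
#' @examples
#' substitute_long_chain(build_null_system(256), 24)
substitute_long_chain <- function(base, target_pct_gpl) {
  stopifnot(inherits(base, "membrane_composition"))
  cnt <- base$counts
  for (sp in c("ERG", "IPC", "DOPC", "POPI"))
    if (!sp %in% names(cnt)) cnt[sp] <- 0L
  if (any(cnt[very_long_species()] > 0L, na.rm = TRUE))
    abort2("base composition already contains very-long-chain species",
           "invalid_argument")
  if (cnt[["DOPC"]] != cnt[["POPI"]])
    abort2("base must have equal DOPC and POPI counts", "invalid_argument")
  if (!is.numeric(target_pct_gpl) || length(target_pct_gpl) != 1L ||
      target_pct_gpl <= 0 || target_pct_gpl > 100)
    abort2("target_pct_gpl must be in (0, 100]", "invalid_argument")

  n_gpl <- cnt[["DOPC"]] + cnt[["POPI"]]
  n_long <- 14L * as.integer(round_half_up(target_pct_gpl / 100 * n_gpl / 14))
  if (n_long == 0L || n_long > n_gpl)
    abort2(sprintf(
      "target %.6g%% not achievable with the 4:2:1 rule (n_long = %d of %d GPLs)",
      target_pct_gpl, n_long, n_gpl), "unachievable_target")
  k <- n_long %/% 14L  # per-family block multiplier

  out <- c(
    ERG  = cnt[["ERG"]], IPC = cnt[["IPC"]],
    DOPC = cnt[["DOPC"]] - 7L * k, POPI = cnt[["POPI"]] - 7L * k,
    AOPC = 4L * k, AOPI = 4L * k,
    BOPC = 2L * k, BOPI = 2L * k,
    LOPC = 1L * k, LOPI = 1L * k
  )
  comp <- membrane_composition(
    sprintf("%s+VLC%g", base$system_name, target_pct_gpl), out)
  comp$target_pct_gpl <- target_pct_gpl
  comp
}

#' Table of the ten study membrane systems
#'
#' Convenience constructor for the two null references plus the eight
#' substituted systems M1--M8 (8, 16, 24, 32, 40, 48, 64 and 96 % target
#' very-long-chain GPL).
#'
#' @return named list of [membrane_composition()] objects.
#' @export
study_systems <- function() {
  pct <- c(8, 16, 24, 32, 40, 48, 64, 96)
  null256 <- build_null_system(256)
  ms <- lapply(pct, function(p) {
    comp <- substitute_long_chain(null256, p)
    comp$system_name <- paste0("M", which(pct == p))
    comp
  })
  names(ms) <- paste0("M", seq_along(pct))
  c(list(`Null-64` = build_null_system(64), `Null-256` = null256), ms)
}

# count helpers ---------------------------------------------------------

counts_of <- function(comp, species) {
  x <- comp$counts[intersect(species, names(comp$counts))]
  sum(x, na.rm = TRUE)
}

#' Very-long-chain GPL percentage of all glycerophospholipids
#'
#' @param comp a [membrane_composition()].
#' @return unrounded percentage; round at report time only.
#' @export
pct_very_long_of_gpl <- function(comp) {
  stopifnot(inherits(comp, "membrane_composition"))
  n_gpl <- counts_of(comp, gpl_species())
  if (n_gpl == 0L) abort2("composition contains no GPLs", "undefined_metric")
  100 * counts_of(comp, very_long_species()) / n_gpl
}

#' Very-long-chain GPL percentage of all lipid molecules
#'
#' @param comp a [membrane_composition()].
#' @return unrounded percentage of total lipid molecules.
#' @export
pct_very_long_of_total <- function(comp) {
  stopifnot(inherits(comp, "membrane_composition"))
  n_tot <- sum(comp$counts)
  if (n_tot == 0L) abort2("empty composition", "undefined_metric")
  100 * counts_of(comp, very_long_species()) / n_tot
}

#' Mean glycerophospholipid chain carbons of a composition
#'
#' Averages acyl carbons over GPL molecules (sn1 + sn2 combined) or over
#' individual GPL acyl chains. Sterols and sphingolipids are excluded; the
#' paper-style average is per molecule.
#'
#' @param comp a [membrane_composition()].
#' @param per `"molecule"` (sn1+sn2 sum) or `"chain"` (single-chain mean).
#' @return mean carbon count.
#' @export
mean_gpl_chain_carbons <- function(comp, per = c("molecule", "chain")) {
  stopifnot(inherits(comp, "membrane_composition"))
  per <- match.arg(per)
  reg <- lipid_registry()
  reg <- reg[reg$category == "GPL" & reg$name %in% names(comp$counts), ]
  n <- comp$counts[reg$name]
  if (sum(n) == 0L) abort2("composition contains no GPLs", "undefined_metric")
  carbons <- reg$sn1_carbons + reg$sn2_carbons
  total_c <- sum(n * carbons)
  if (per == "molecule") total_c / sum(n) else total_c / (2 * sum(n))
}

#' Table-style composition report
#'
#' One row per system: per-species counts, total lipids, the tabulated
#' very-long-chain percentage of GPLs (`pct_gpl`: the design target when the
#' composition was built by [substitute_long_chain()], since the integer
#' 4:2:1 rule quantizes the achieved value -- e.g. 95.45 at target 96 --,
#' otherwise the rounded achieved value), the unrounded achieved percentage
#' (`pct_gpl_achieved`), the rounded percentage of all lipid molecules and
#' the mean GPL chain carbons per molecule.
#'
#' @param comps a [membrane_composition()] or list thereof.
#' @return a `data.frame`.
#' @export
composition_report <- function(comps) {
  if (inherits(comps, "membrane_composition")) comps <- list(comps)
  species <- lipid_registry()$name
  rows <- lapply(comps, function(cp) {
    cnt <- stats::setNames(integer(length(species)), species)
    cnt[names(cp$counts)] <- cp$counts
    achieved <- pct_very_long_of_gpl(cp)
    data.frame(
      system = cp$system_name,
      as.list(cnt),
      lipids = sum(cnt),
      pct_gpl = if (!is.null(cp$target_pct_gpl)) cp$target_pct_gpl
                else round_half_up(achieved),
      pct_gpl_achieved = achieved,
      pct_total = round_half_up(pct_very_long_of_total(cp)),
      mean_gpl_carbons = mean_gpl_chain_carbons(cp, "molecule"),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# composition I/O -------------------------------------------------------

#' Write / read compositions as long-format CSV
#'
#' Columns: `system,species,count`. Zero-count species are omitted on write.
#'
#' @param comps composition or list of compositions.
#' @param path file path.
#' @return `read_composition_csv` returns a named list of compositions.
#' @export
write_composition_csv <- function(comps, path) {
  if (inherits(comps, "membrane_composition")) comps <- list(comps)
  rows <- do.call(rbind, lapply(comps, function(cp) {
    keep <- cp$counts > 0L
    data.frame(system = cp$system_name,
               species = names(cp$counts)[keep],
               count = unname(cp$counts[keep]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_composition_csv
#' @export
read_composition_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("system", "species", "count")
  if (!all(need %in% names(df)))
    abort2("composition CSV must have columns system, species, count",
           "schema_error")
  out <- lapply(split(df, df$system), function(d)
    membrane_composition(d$system[1L],
                         stats::setNames(d$count, d$species)))
  out[unique(df$system)]
}

#' Write a composition (or list) to JSON
#'
#' @param comps composition or list of compositions.
#' @param path file path.
#' @export
write_composition_json <- function(comps, path) {
  if (inherits(comps, "membrane_composition")) comps <- list(comps)
  payload <- lapply(comps, function(cp)
    list(system = cp$system_name, counts = as.list(cp$counts[cp$counts > 0L])))
  names(payload) <- vapply(comps, function(cp) cp$system_name, character(1))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
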