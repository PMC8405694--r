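# Shared lipid-class vocabulary, headgroup shape taxonomy and chain
# bookkeeping used by the lipidome generator and the profile metrics.

#' Lipid class vocabulary
#'
#' The classes recognised in species tables: glycerophospholipids, lyso
#' forms, sphingolipids, storage lipids, mitochondrial-only classes and
#' CDP-DAG.
#'
#' @return character vector of class names.
#' @export
lipid_class_vocabulary <- function() {
  c("PC", "PE", "PI", "PS", "PA",
    "LPC", "LPE", "LPI", "LPS", "LPA",
    "DAG", "TAG", "EE",
    "Cer", "IPC", "MIPC", "MIP2C",
    "CL", "PG", "CDP-DAG")
}

#' Headgroup shape taxonomy
#'
#' Partition of the class vocabulary into geometric shape classes plus the
#' storage and mitochondrial-only groups. Membrane lipids are everything but
#' storage; plasma-membrane (PM) lipids additionally exclude PG and CL,
#' which reside only in mitochondrial membranes.
#'
#' @return named list of character vectors.
#' @export
shape_taxonomy <- function() {
  list(
    cylindrical        = c("PC", "PS", "PI", "IPC", "MIPC", "MIP2C", "Cer"),
    conical_small_head = c("DAG", "PA", "PE"),
    conical_large_head = c("LPC", "LPE", "LPI", "LPS", "LPA"),
    storage            = c("TAG", "EE"),
    mitochondrial_only = c("PG", "CL"),
    other              = c("CDP-DAG")
  )
}

# class groupings ----------------------------------------------------------

# two-chain glycerophospholipids used for chain-length metrics
gpl_classes <- function() c("PC", "PE", "PI", "PS", "PA")

lyso_classes <- function() c("LPC", "LPE", "LPI", "LPS", "LPA")

storage_classes <- function() shape_taxonomy()$storage

membrane_classes <- function() setdiff(lipid_class_vocabulary(), storage_classes())

pm_classes <- function() setdiff(membrane_classes(), shape_taxonomy()$mitochondrial_only)

#' Acyl chains per lipid molecule, by class
#'
#' Bookkeeping for fatty-acid-weighted fractions: two-chain GPLs, DAG, PG,
#' PA, CDP-DAG and the ceramide/IPC series carry 2 chains (sphingoid base +
#' amide FA for the sphingolipids), lyso forms and ergosterol esters 1,
#' TAG 3, cardiolipin 4.
#'
#' @return named integer vector over the class vocabulary.
#' @export
chains_per_lipid <- function() {
  c(PC = 2L, PE = 2L, PI = 2L, PS = 2L, PA = 2L,
    LPC = 1L, LPE = 1L, LPI = 1L, LPS = 1L, LPA = 1L,
    DAG = 2L, TAG = 3L, EE = 1L,
    Cer = 2L, IPC = 2L, MIPC = 2L, MIP2C = 2L,
    CL = 4L, PG = 2L, `CDP-DAG` = 2L)
}

# plausible total-carbon ranges per class (even integers)
class_carbon_ranges <- function() {
  two_chain <- c(24L, 48L)
  list(PC = two_chain, PE = two_chain, PI = two_chain, PS = two_chain,
       PA = two_chain, DAG = two_chain, PG = two_chain, `CDP-DAG` = two_chain,
       LPC = c(12L, 26L), LPE = c(12L, 26L), LPI = c(12L, 26L),
       LPS = c(12L, 26L), LPA = c(12L, 26L),
       TAG = c(42L, 60L), EE = c(14L, 26L),
       Cer = c(30L, 48L), IPC = c(30L, 48L), MIPC = c(30L, 48L),
       MIP2C = c(30L, 48L), CL = c(56L, 72L))
}

# per-class default total-carbon means for the generator
default_chain_means <- function() {
  c(PC = 34, PE = 34, PI = 34, PS = 34, PA = 34, DAG = 34, PG = 34,
    `CDP-DAG` = 34,
    LPC = 16, LPE = 16, LPI = 16, LPS = 16, LPA = 16,
    TAG = 50, EE = 18,
    Cer = 42, IPC = 42, MIPC = 42, MIP2C = 42, CL = 68)
}
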