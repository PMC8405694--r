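# Built-in registry of the lipid species used in the yeast bilayer models.
#
# The model membranes are built from ergosterol (ERG), inositol
# phosphorylceramide (IPC), two reference glycerophospholipids (DOPC 18:1/18:1
# and POPI 16:0/18:1) and six very-long-chain substitutes that keep the sn2
# oleoyl chain and elongate + saturate sn1 to 20 (AOPC/AOPI), 22 (BOPC/BOPI)
# or 24 (LOPC/LOPI) carbons.

#' Registry of bilayer model lipid species
#'
#' Returns the fixed species table used by the membrane composer: name,
#' category (sterol / sphingolipid / GPL), headgroup and per-position acyl
#' chain lengths and double-bond counts. IPC carries nominal 18:0/26:0 chains
#' for mass bookkeeping but, being a sphingolipid, is excluded from all
#' GPL chain-length metrics.
#'
#' @return a `data.frame` with one row per species.
#' @export
#' @examples
#' lipid_registry()
lipid_registry <- function() {
  data.frame(
    name      = c("ERG", "IPC", "DOPC", "POPI",
                  "AOPC", "AOPI", "BOPC", "BOPI", "LOPC", "LOPI"),
    category  = c("sterol", "sphingolipid", rep("GPL", 8L)),
    headgroup = c("ERG", "IPC",
                  "PC", "PI", "PC", "PI", "PC", "PI", "PC", "PI"),
    sn1_carbons      = c(0L, 18L, 18L, 16L, 20L, 20L, 22L, 22L, 24L, 24L),
    sn1_double_bonds = c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    sn2_carbons      = c(0L, 26L, 18L, 18L, 18L, 18L, 18L, 18L, 18L, 18L),
    sn2_double_bonds = c(0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

# species names by role
gpl_species <- function() {
  reg <- lipid_registry()
  reg$name[reg$category == "GPL"]
}

very_long_species <- function() {
  reg <- lipid_registry()
  reg$name[reg$category == "GPL" & reg$sn1_carbons >= 20L]
}
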