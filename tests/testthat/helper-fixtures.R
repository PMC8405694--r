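# Shared in-code fixtures for the test suite.

# Printed reference composition table: per-species counts plus the tabulated
# very-long-chain percentage of GPLs (design target) and of all lipid
# molecules (rounded achieved).
reference_table1 <- function() {
  data.frame(
    system = c("Null-64", "Null-256", paste0("M", 1:8)),
    ERG  = c(10, rep(40, 9)),
    IPC  = c(10, rep(40, 9)),
    DOPC = c(22, 88, 81, 74, 67, 60, 53, 46, 32, 4),
    POPI = c(22, 88, 81, 74, 67, 60, 53, 46, 32, 4),
    AOPC = c(0, 0, 4, 8, 12, 16, 20, 24, 32, 48),
    BOPC = c(0, 0, 2, 4, 6, 8, 10, 12, 16, 24),
    LOPC = c(0, 0, 1, 2, 3, 4, 5, 6, 8, 12),
    lipids = c(64, rep(256, 9)),
    pct_gpl = c(0, 0, 8, 16, 24, 32, 40, 48, 64, 96),
    pct_total = c(0, 0, 5, 11, 16, 22, 27, 33, 44, 66)
  )
}

# tiny lipidome table built by hand (one strain, one replicate unless asked)
toy_lipidome <- function(classes, carbons, db, abundance,
                         strain = "s1", replicate = 1L) {
  tab <- data.frame(sample = strain, replicate = replicate,
                    lipid_class = classes, total_carbons = as.integer(carbons),
                    total_double_bonds = as.integer(db),
                    abundance = abundance, stringsAsFactors = FALSE)
  class(tab) <- c("lipidome_table", "data.frame")
  tab
}

# a small random atom mass table: heavy backbone, each heavy atom gets 1-3
# hydrogens, heavy masses large enough that repartitioning stays feasible
random_topology <- function(n_heavy, seed) {
  set.seed(seed)
  heavy_elements <- sample(c("C", "N", "O", "P", "S"), n_heavy, replace = TRUE)
  heavy_mass <- c(C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06)
  atoms <- data.frame(id = seq_len(n_heavy), element = heavy_elements,
                      mass = unname(heavy_mass[heavy_elements]))
  bonds <- data.frame(from = integer(), to = integer())
  next_id <- n_heavy
  for (i in seq_len(n_heavy)) {
    # keep removal below the heavy mass: at most floor((m - 0.1)/3.024) H
    max_h <- min(3L, floor((atoms$mass[i] - 0.1) / 3.024))
    nh <- sample(0:max_h, 1L)
    if (nh > 0L) {
      ids <- next_id + seq_len(nh)
      atoms <- rbind(atoms, data.frame(id = ids, element = "H", mass = 1.008))
      bonds <- rbind(bonds, data.frame(from = i, to = ids))
      next_id <- next_id + nh
    }
  }
  atom_mass_table(atoms, bonds)
}
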