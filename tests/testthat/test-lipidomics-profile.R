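test_that("parsing a toy CSV yields a validated table", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,replicate,lipid_class,total_carbons,total_double_bonds,abundance",
               "s1,1,PC,34,1,0.5",
               "s1,1,PE,36,2,0.3",
               "s1,1,DAG,32,1,0.2"), path)
  tab <- parse_lipidome(path)
  expect_s3_class(tab, "lipidome_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$lipid_class, c("PC", "PE", "DAG"))
})

test_that("non-positive abundances are dropped with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,replicate,lipid_class,total_carbons,total_double_bonds,abundance",
               "s1,1,PC,34,1,0.5",
               "s1,1,PE,36,2,-1"), path)
  expect_warning(tab <- parse_lipidome(path), "1 row")
  expect_equal(nrow(tab), 1L)
})

test_that("schema and vocabulary violations are classed errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,replicate,lipid_class,total_carbons,total_double_bonds,abundance",
               "s1,1,NOTALIPID,34,1,0.5"), path)
  err <- expect_error(parse_lipidome(path), class = "vocabulary_error")
  expect_match(conditionMessage(err), "NOTALIPID")
  cmap <- c(sample = "no_such_col", replicate = "replicate",
            lipid_class = "lipid_class", total_carbons = "total_carbons",
            total_double_bonds = "total_double_bonds", abundance = "abundance")
  expect_error(parse_lipidome(path, column_map = cmap), class = "schema_error")
})

test_that("a written synthetic lipidome round-trips through the parser", {
  g <- generate_lipidome(lipidome_spec(seed = 6, sample_name = "syn"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_lipidome_csv(g$table, path)
  back <- parse_lipidome(path)
  expect_equal(nrow(back), nrow(g$table))
  expect_equal(back$abundance, g$table$abundance, tolerance = 1e-12)
  expect_equal(back$lipid_class, g$table$lipid_class)
})

test_that("mean GPL carbons is the abundance-weighted mean over GPL classes", {
  tab <- toy_lipidome(c("PC", "PI"), c(36, 34), c(2, 1), c(1, 1))
  expect_equal(mean_gpl_carbons_lipidomics(tab, "s1")$mean, 35.0)
  # weighting follows abundance
  tab2 <- toy_lipidome(c("PC", "PI"), c(36, 34), c(2, 1), c(3, 1))
  expect_equal(mean_gpl_carbons_lipidomics(tab2, "s1")$mean, 35.5)
  # non-GPL classes are invisible to the metric
  tab3 <- toy_lipidome(c("PC", "PI", "TAG", "LPC"), c(36, 34, 52, 16),
                       c(2, 1, 1, 0), c(1, 1, 9, 9))
  expect_equal(mean_gpl_carbons_lipidomics(tab3, "s1")$mean, 35.0)
  erg <- toy_lipidome("TAG", 52, 1, 1)
  expect_error(mean_gpl_carbons_lipidomics(erg, "s1"),
               class = "undefined_metric")
})

test_that("mean double bonds covers membrane lipids, excluding storage", {
  tab <- toy_lipidome(c("PC", "PE", "PI"), c(34, 34, 34), c(1, 1, 2),
                      c(1, 1, 1))
  expect_equal(mean_double_bonds_membrane(tab, "s1")$mean, 4 / 3,
               tolerance = 1e-12)
  # storage lipids (TAG/EE) do not contribute
  tab2 <- toy_lipidome(c("PC", "TAG"), c(34, 52), c(1, 6), c(1, 10))
  expect_equal(mean_double_bonds_membrane(tab2, "s1")$mean, 1.0)
})

test_that("shape fractions partition PM lipids and sum to one", {
  tab <- toy_lipidome(c("DAG", "PC", "LPC", "PG", "TAG"),
                      c(32, 34, 16, 34, 52), c(1, 1, 0, 1, 2),
                      c(0.2, 0.5, 0.1, 0.7, 0.9))
  sf <- shape_class_fractions(tab, "s1")
  # PG (mitochondrial) and TAG (storage) are excluded from the denominator
  expect_equal(sum(sf$shape$mean), 1.0, tolerance = 1e-9)
  expect_equal(sf$shape$mean[sf$shape$group == "conical_small_head"],
               0.2 / 0.8, tolerance = 1e-12)
  dag_only <- toy_lipidome("DAG", 32, 1, 1)
  sfd <- shape_class_fractions(dag_only, "s1")
  expect_equal(sfd$shape$mean[sfd$shape$group == "conical_small_head"], 1.0)
  mito_only <- toy_lipidome("PG", 34, 1, 1)
  expect_error(shape_class_fractions(mito_only, "s1"),
               class = "undefined_metric")
})

test_that("chain-length bins split at the printed boundaries", {
  tab <- toy_lipidome(rep("PC", 4), c(31, 32, 36, 37), c(1, 1, 1, 1),
                      c(1, 1, 1, 1))
  cb <- chain_bin_fractions(tab, "s1")
  expect_equal(stats::setNames(cb$mean, cb$bin),
               c(medium = 0.25, long = 0.5, very_long = 0.25))
  all34 <- toy_lipidome(rep("PC", 3), c(34, 34, 34), c(1, 1, 1), c(1, 2, 3))
  cb34 <- chain_bin_fractions(all34, "s1")
  expect_equal(cb34$mean[cb34$bin == "long"], 1.0)
  # out-of-range carbons clamp to the nearest bin with a warning
  oob <- toy_lipidome(c("PC", "PC"), c(22, 50), c(0, 0), c(1, 1))
  expect_warning(cbo <- chain_bin_fractions(oob, "s1"), "outside")
  expect_equal(cbo$mean[cbo$bin == "medium"], 0.5)
  expect_equal(cbo$mean[cbo$bin == "very_long"], 0.5)
})

test_that("both GPL chain-length tails are reported around the threshold", {
  tab <- toy_lipidome(rep("PC", 3), c(34, 36, 38), c(1, 1, 1), c(1, 1, 2))
  tails <- gpl_chain_tail_fractions(tab, "s1", threshold = 36)
  expect_equal(tails$below$mean, 0.25)
  expect_equal(tails$above$mean, 0.50)
})

test_that("PM fatty-acid fraction uses per-class chain counts", {
  only_pc <- toy_lipidome("PC", 34, 1, 5)
  expect_equal(pm_fa_fraction(only_pc, "s1")$mean, 1.0)
  # PC (2 chains, PM) vs TAG (3 chains, storage): 2 / (2 + 3)
  tab <- toy_lipidome(c("PC", "TAG"), c(34, 52), c(1, 2), c(1, 1))
  expect_equal(pm_fa_fraction(tab, "s1")$mean, 0.4, tolerance = 1e-12)
  # brute-force chain-count oracle on a mixed synthetic table
  g <- generate_lipidome(lipidome_spec(abundance_noise_cv = 0, seed = 7,
                                       sample_name = "s"))
  one <- g$table[g$table$replicate == 1, ]
  cpl <- chains_per_lipid()
  pmset <- setdiff(lipid_class_vocabulary(), c("TAG", "EE", "PG", "CL"))
  oracle <- sum(one$abundance[one$lipid_class %in% pmset] *
                  cpl[one$lipid_class[one$lipid_class %in% pmset]]) /
    sum(one$abundance * cpl[one$lipid_class])
  expect_equal(pm_fa_fraction(g$table, "s")$mean, oracle, tolerance = 1e-12)
})

test_that("metrics are invariant to per-replicate abundance rescaling", {
  g <- generate_lipidome(lipidome_spec(abundance_noise_cv = 0.05, seed = 8,
                                       sample_name = "s"))
  scaled <- g$table
  for (r in unique(scaled$replicate)) {
    scale_factor <- r * 7.3
    scaled$abundance[scaled$replicate == r] <-
      scaled$abundance[scaled$replicate == r] * scale_factor
  }
  expect_equal(mean_gpl_carbons_lipidomics(scaled, "s"),
               mean_gpl_carbons_lipidomics(g$table, "s"), tolerance = 1e-12)
  expect_equal(pm_fa_fraction(scaled, "s"), pm_fa_fraction(g$table, "s"),
               tolerance = 1e-12)
  sf1 <- shape_class_fractions(scaled, "s")$shape
  sf2 <- shape_class_fractions(g$table, "s")$shape
  expect_equal(sf1$mean, sf2$mean, tolerance = 1e-12)
})

test_that("strain contrasts use a Welch test with sane degenerate behaviour", {
  same <- compare_strains(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$difference, 0)
  expect_false(same$significant)
  # clearly separated strains: |t| = 10 / (0.1 * sqrt(2/3)) ~ 122, df ~ 4
  apart <- compare_strains(c(10.0, 10.1, 9.9), c(20.0, 20.1, 19.9))
  expect_true(apart$significant)
  expect_lt(apart$p_value, 1e-6)
  expect_equal(apart$difference, -10)
  # zero variance in both groups
  expect_equal(compare_strains(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(compare_strains(c(2, 2), c(3, 3))$p_value, 0)
  expect_error(compare_strains(1, c(1, 2)), class = "insufficient_replicates")
  # metric results can be passed directly
  g <- generate_lipidome(lipidome_spec(seed = 9, sample_name = "a"))
  h <- generate_lipidome(lipidome_spec(seed = 10, sample_name = "b"))
  both <- rbind(g$table, h$table)
  class(both) <- class(g$table)
  cmp <- compare_strains(mean_gpl_carbons_lipidomics(both, "a"),
                         mean_gpl_carbons_lipidomics(both, "b"))
  expect_true(is.finite(cmp$p_value))
})
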