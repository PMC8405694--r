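# Strain-level summaries of shotgun-lipidomics species tables.
#
# All per-replicate summaries are abundance-weighted (mole-weighted under
# protein-normalised abundances); across replicates the sample mean and
# sample sd are reported. Fractions are scale-invariant per replicate.

#' Parse a delimited lipidomics species table
#'
#' @param path delimited text file.
#' @param column_map named character vector mapping the standard fields
#'   (`sample`, `replicate`, `lipid_class`, `total_carbons`,
#'   `total_double_bonds`, `abundance`) to the file's column names; defaults
#'   to identity.
#' @param sep field separator (default comma).
#' @return a `lipidome_table` data frame. Rows with non-positive abundance
#'   are dropped with a warning reporting the count; unknown lipid classes
#'   are an error naming the offending values.
#' @export
parse_lipidome <- function(path, column_map = NULL, sep = ",") {
  std <- c("sample", "replicate", "lipid_class", "total_carbons",
           "total_double_bonds", "abundance")
  if (is.null(column_map)) column_map <- stats::setNames(std, std)
  if (!all(std %in% names(column_map)))
    abort2(paste0("column_map must map all of: ", paste(std, collapse = ", ")),
           "schema_error")
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
  missing <- setdiff(unname(column_map[std]), names(df))
  if (length(missing) > 0L)
    abort2(paste0("mapped column(s) absent from file: ",
                  paste(missing, collapse = ", ")), "schema_error")
  out <- df[, unname(column_map[std])]
  names(out) <- std
  # tolerate hydroxylation suffixes such as "IPC;2" on the class label
  out$lipid_class <- sub(";.*$", "", trimws(out$lipid_class))
  unknown <- setdiff(unique(out$lipid_class), lipid_class_vocabulary())
  if (length(unknown) > 0L)
    abort2(paste0("unknown lipid class(es): ", paste(unknown, collapse = ", ")),
           "vocabulary_error")
  out$total_carbons <- as.integer(out$total_carbons)
  out$total_double_bonds <- as.integer(out$total_double_bonds)
  out$abundance <- as.numeric(out$abundance)
  bad <- !is.finite(out$abundance) | out$abundance <= 0
  if (any(bad)) {
    warning(sprintf("dropped %d row(s) with non-positive abundance", sum(bad)),
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("lipidome_table", "data.frame")
  out
}

# rows of one strain; error if absent
strain_rows <- function(table, strain) {
  stopifnot(is.data.frame(table))
  rows <- table[table$sample == strain, , drop = FALSE]
  if (nrow(rows) == 0L)
    abort2(paste0("no records for strain ", strain), "undefined_metric")
  rows
}

# apply fn(replicate rows) -> scalar, over replicates; mean/sd across
replicate_metric <- function(rows, fn) {
  reps <- sort(unique(rows$replicate))
  vals <- vapply(reps, function(r) fn(rows[rows$replicate == r, , drop = FALSE]),
                 numeric(1))
  names(vals) <- reps
  list(mean = mean(vals), sd = if (length(vals) > 1L) stats::sd(vals) else 0,
       replicates = vals)
}

#' Mean glycerophospholipid chain carbons of a strain
#'
#' Abundance-weighted mean of total acyl carbons over the two-chain GPL
#' classes (PC, PE, PI, PS, PA), per replicate; mean and sd across
#' replicates. Lyso species and CDP-DAG are excluded.
#'
#' @param table a `lipidome_table`.
#' @param strain sample identifier.
#' @return list with `mean`, `sd` and per-`replicates` values.
#' @export
mean_gpl_carbons_lipidomics <- function(table, strain) {
  rows <- strain_rows(table, strain)
  replicate_metric(rows, function(d) {
    g <- d[d$lipid_class %in% gpl_classes(), , drop = FALSE]
    if (nrow(g) == 0L) abort2("no GPL records", "undefined_metric")
    sum(g$abundance * g$total_carbons) / sum(g$abundance)
  })
}

#' Mean double bonds per membrane lipid
#'
#' Abundance-weighted mean of total double bonds over membrane lipids
#' (storage classes TAG and EE excluded).
#'
#' @inheritParams mean_gpl_carbons_lipidomics
#' @return list with `mean`, `sd`, `replicates`.
#' @export
mean_double_bonds_membrane <- function(table, strain) {
  rows <- strain_rows(table, strain)
  replicate_metric(rows, function(d) {
    m <- d[d$lipid_class %in% membrane_classes(), , drop = FALSE]
    if (nrow(m) == 0L) abort2("no membrane-lipid records", "undefined_metric")
    sum(m$abundance * m$total_double_bonds) / sum(m$abundance)
  })
}

#' Headgroup shape-class fractions over plasma-membrane lipids
#'
#' Abundance fractions over PM lipids (membrane lipids minus PG/CL) per
#' geometric shape class and per individual headgroup class, per replicate;
#' mean and sd across replicates.
#'
#' @inheritParams mean_gpl_carbons_lipidomics
#' @return list with `shape` and `headgroup` data frames (`group`, `mean`,
#'   `sd`) and `shape_replicates` / `headgroup_replicates` matrices
#'   (group x replicate).
#' @export
shape_class_fractions <- function(table, strain) {
  rows <- strain_rows(table, strain)
  pm <- rows[rows$lipid_class %in% pm_classes(), , drop = FALSE]
  if (nrow(pm) == 0L) abort2("no PM lipid records", "undefined_metric")
  tax <- shape_taxonomy()
  shape_groups <- setdiff(names(tax), c("storage", "mitochondrial_only"))
  shape_of <- vapply(pm$lipid_class, function(x)
    names(tax)[vapply(tax, function(v) x %in% v, logical(1))][1L], character(1))

  reps <- sort(unique(pm$replicate))
  frac_by <- function(keys, universe) {
    m <- sapply(reps, function(r) {
      d <- pm$replicate == r
      tot <- sum(pm$abundance[d])
      vapply(universe, function(g)
        sum(pm$abundance[d & keys == g]) / tot, numeric(1))
    })
    m <- matrix(m, nrow = length(universe),
                dimnames = list(universe, reps))
    m
  }
  sm <- frac_by(shape_of, shape_groups)
  hm <- frac_by(pm$lipid_class, sort(unique(pm$lipid_class)))
  summarize <- function(m) data.frame(
    group = rownames(m),
    mean = rowMeans(m),
    sd = apply(m, 1L, function(v) if (length(v) > 1L) stats::sd(v) else 0),
    row.names = NULL, stringsAsFactors = FALSE)
  list(shape = summarize(sm), headgroup = summarize(hm),
       shape_replicates = sm, headgroup_replicates = hm)
}

# chain-length bin of a GPL total-carbon count; out-of-range values clamp to
# the nearest bin with a warning
carbon_bin <- function(carbons, warn = TRUE) {
  out_of_range <- carbons < 24L | carbons > 48L
  if (warn && any(out_of_range))
    warning(sprintf("%d GPL record(s) outside C24-C48; assigned to nearest bin",
                    sum(out_of_range)), call. = FALSE)
  ifelse(carbons <= 31L, "medium", ifelse(carbons <= 36L, "long", "very_long"))
}

#' Chain-length bin fractions of glycerophospholipids
#'
#' Abundance fractions of GPLs in the inclusive bins medium (C24-31), long
#' (C32-36) and very-long (C37-48) total acyl carbons; carbons outside
#' 24-48 are clamped to the nearest bin with a warning.
#'
#' @inheritParams mean_gpl_carbons_lipidomics
#' @return data frame (`bin`, `mean`, `sd`) with a `replicates` attribute
#'   (bin x replicate matrix).
#' @export
chain_bin_fractions <- function(table, strain) {
  rows <- strain_rows(table, strain)
  g <- rows[rows$lipid_class %in% gpl_classes(), , drop = FALSE]
  if (nrow(g) == 0L) abort2("no GPL records", "undefined_metric")
  bins <- carbon_bin(g$total_carbons)
  levels <- c("medium", "long", "very_long")
  reps <- sort(unique(g$replicate))
  m <- sapply(reps, function(r) {
    d <- g$replicate == r
    tot <- sum(g$abundance[d])
    vapply(levels, function(b) sum(g$abundance[d & bins == b]) / tot, numeric(1))
  })
  m <- matrix(m, nrow = length(levels), dimnames = list(levels, reps))
  out <- data.frame(bin = levels, mean = rowMeans(m),
                    sd = apply(m, 1L, function(v) if (length(v) > 1L) stats::sd(v) else 0),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "replicates") <- m
  out
}

#' Fractions of glycerophospholipid abundance above/below a carbon threshold
#'
#' Reports both tails around a total-carbon threshold (default 36), per
#' replicate, as a check on very-long-chain enrichment statements.
#'
#' @inheritParams mean_gpl_carbons_lipidomics
#' @param threshold total-carbon cut (exclusive on both tails).
#' @return list of two `replicate_metric` results, `below` and `above`.
#' @export
gpl_chain_tail_fractions <- function(table, strain, threshold = 36L) {
  rows <- strain_rows(table, strain)
  tail_fn <- function(cmp) function(d) {
    g <- d[d$lipid_class %in% gpl_classes(), , drop = FALSE]
    if (nrow(g) == 0L) abort2("no GPL records", "undefined_metric")
    sum(g$abundance[cmp(g$total_carbons, threshold)]) / sum(g$abundance)
  }
  list(below = replicate_metric(rows, tail_fn(`<`)),
       above = replicate_metric(rows, tail_fn(`>`)))
}

#' Fraction of fatty-acid chains residing in plasma-membrane lipids
#'
#' Weights each species' abundance by its acyl chains per molecule (see
#' [chains_per_lipid()]) and reports the PM share of all chains.
#'
#' @inheritParams mean_gpl_carbons_lipidomics
#' @return list with `mean`, `sd`, `replicates`.
#' @export
pm_fa_fraction <- function(table, strain) {
  rows <- strain_rows(table, strain)
  cpl <- chains_per_lipid()
  replicate_metric(rows, function(d) {
    chains <- d$abundance * cpl[d$lipid_class]
    sum(chains[d$lipid_class %in% pm_classes()]) / sum(chains)
  })
}

#' Full strain profile
#'
#' Bundles the strain-level summaries into one object.
#'
#' @inheritParams mean_gpl_carbons_lipidomics
#' @return object of class `strain_profile`.
#' @export
strain_profile <- function(table, strain) {
  structure(list(
    strain = strain,
    mean_gpl_carbons = mean_gpl_carbons_lipidomics(table, strain),
    mean_double_bonds_membrane = mean_double_bonds_membrane(table, strain),
    shape = shape_class_fractions(table, strain),
    chain_bins = chain_bin_fractions(table, strain),
    pm_fa = pm_fa_fraction(table, strain)
  ), class = "strain_profile")
}

#' @export
print.strain_profile <- function(x, ...) {
  cat("Strain profile:", x$strain, "\n")
  cat(sprintf("  mean GPL carbons:        %.2f (sd %.3f)\n",
              x$mean_gpl_carbons$mean, x$mean_gpl_carbons$sd))
  cat(sprintf("  double bonds / membrane: %.2f (sd %.3f)\n",
              x$mean_double_bonds_membrane$mean, x$mean_double_bonds_membrane$sd))
  cat(sprintf("  PM FA fraction:          %.1f%% (sd %.2f)\n",
              100 * x$pm_fa$mean, 100 * x$pm_fa$sd))
  cat("  shape classes (% of PM lipids):\n")
  s <- x$shape$shape
  for (i in seq_len(nrow(s)))
    cat(sprintf("    %-20s %5.1f%% (sd %.2f)\n",
                s$group[i], 100 * s$mean[i], 100 * s$sd[i]))
  invisible(x)
}

#' Compare a metric between two strains
#'
#' Welch two-sample t-test on replicate-level metric values (the convention
#' used for 95 %-confidence contrasts between strains). Degenerate inputs
#' with zero variance in both groups give p = 1 when the means agree and
#' p = 0 otherwise.
#'
#' @param a,b numeric vectors of replicate values, or metric results
#'   carrying a `replicates` element.
#' @param alpha significance level (default 0.05).
#' @return list with `difference` (mean a - mean b), `p_value`,
#'   `significant`, `method`.
#' @export
compare_strains <- function(a, b, alpha = 0.05) {
  get_vals <- function(x) {
    if (is.list(x) && !is.null(x$replicates)) x <- x$replicates
    as.numeric(x)
  }
  va <- get_vals(a); vb <- get_vals(b)
  if (length(va) < 2L || length(vb) < 2L)
    abort2("need at least 2 replicates per strain", "insufficient_replicates")
  diff <- mean(va) - mean(vb)
  if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
    p <- if (diff == 0) 1 else 0
  } else {
    p <- stats::t.test(va, vb, var.equal = FALSE)$p.value
  }
  list(difference = diff, p_value = p, significant = p < alpha,
       method = "Welch two-sample t-test")
}
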