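read_tsv_checked <- function(path, required) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file ", path, " lacks required columns: ",
         paste(missing, collapse = ", "))
  df
}

#' Read a kinetics assay TSV
#'
#' Expected columns: `substrate_id`, `acceptor_conc_uM`, `replicate`,
#' `luminescence`, `is_blank`.
#' @param path TSV file.
#' @param ... assay geometry passed to [kinetics_dataset()].
#' @return a `kinetics_dataset`.
#' @export
read_kinetics_tsv <- function(path, ...) {
  kinetics_dataset(read_tsv_checked(path, c("substrate_id", "acceptor_conc_uM",
                                            "replicate", "luminescence",
                                            "is_blank")), ...)
}

#' Read an ITC titration TSV
#'
#' Expected columns: `injection_index`, `injection_volume_uL`, `heat_ucal`.
#' Cell/syringe concentrations, cell volume and temperature are arguments
#' (they describe the instrument setup, not per-injection data).
#' @param path TSV file.
#' @param cell_conc_uM,syringe_conc_uM,cell_volume_uL,temperature_K setup.
#' @return a `titration_series`.
#' @export
read_itc_tsv <- function(path, cell_conc_uM, syringe_conc_uM,
                         cell_volume_uL = 200, temperature_K = 298.15) {
  df <- read_tsv_checked(path, c("injection_index", "injection_volume_uL",
                                 "heat_ucal"))
  df <- df[order(df$injection_index), ]
  titration_series(df$heat_ucal, df$injection_volume_uL, cell_volume_uL,
                   cell_conc_uM, syringe_conc_uM, temperature_K)
}

#' Read STD build-up series from TSV
#'
#' Expected columns: `proton_id`, `condition`, `sat_time_s`, `std_amplitude`.
#' @param path TSV file.
#' @return named list of [buildup_series()] (one per proton x condition).
#' @export
read_std_tsv <- function(path) {
  df <- read_tsv_checked(path, c("proton_id", "condition", "sat_time_s",
                                 "std_amplitude"))
  keys <- unique(df[, c("proton_id", "condition")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    s <- df[df$proton_id == keys$proton_id[i] &
              df$condition == keys$condition[i], ]
    s <- s[order(s$sat_time_s), ]
    buildup_series(keys$proton_id[i], keys$condition[i], s$sat_time_s,
                   s$std_amplitude)
  })
  setNames(out, keys$proton_id)
}

#' Read NOESY build-up curves from TSV
#'
#' Expected columns: `pair_id`, `mixing_time_ms`, `integral`.
#' @param path TSV file.
#' @return named list of [noe_buildup()].
#' @export
read_noesy_tsv <- function(path) {
  df <- read_tsv_checked(path, c("pair_id", "mixing_time_ms", "integral"))
  out <- lapply(unique(df$pair_id), function(p) {
    s <- df[df$pair_id == p, ]
    s <- s[order(s$mixing_time_ms), ]
    noe_buildup(p, s$mixing_time_ms, s$integral)
  })
  setNames(out, unique(df$pair_id))
}

#' Read a glycopeptide precursor feature TSV
#'
#' Expected columns: `feature_id`, `mz`, `charge`, `rt_min`, `intensity`,
#' `sample_id`, `glycosite`.
#' @param path TSV file.
#' @return data frame of features.
#' @export
read_features_tsv <- function(path) {
  read_tsv_checked(path, c("feature_id", "mz", "charge", "rt_min",
                           "intensity", "sample_id", "glycosite"))
}

#' Reference kinetic constants for FUT8 substrates
#'
#' The published Michaelis-Menten constants of FUT8 for its donor (GDP-Fuc,
#' determined at saturating G0) and acceptor substrates, including the
#' substrates for which the hyperbola could not be fitted (linear velocity
#' over the tested range). Shipped as a plain-text table; used as reference
#' input for consistency checks and worked examples.
#'
#' @return data frame with columns `substrate`, `Km_uM`, `Vmax`, `kcat`,
#'   `efficiency` (each with `_se` where published), `saturable`, `note`.
#' @export
fut8_kinetic_constants <- function() {
  read.delim(system.file("extdata", "fut8_kinetic_constants.tsv",
                         package = "corefuc"), sep = "\t",
             stringsAsFactors = FALSE)
}

#' Reference binding thermodynamics for FUT8 ligands
#'
#' The published one-site ITC constants (25 C) for FUT8 binding GDP and the
#' N-glycan/glycopeptide ligands, with the Gibbs-energy dissection
#' (`dG`, `dH`, `-TdS` in kcal/mol) and stoichiometry; ligands whose binding
#' was not measurable are flagged.
#'
#' @return data frame with columns `ligand`, `Kd_uM`, `dG`, `dH`, `minusTdS`,
#'   `n`, `measurable` (and `_se` columns).
#' @export
fut8_binding_constants <- function() {
  read.delim(system.file("extdata", "fut8_binding_constants.tsv",
                         package = "corefuc"), sep = "\t",
             stringsAsFactors = FALSE)
}
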