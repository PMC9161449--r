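#' Default glycan building-block set
#'
#' Monoisotopic residue masses (Da) of the monosaccharide building blocks used
#' for compositional assignment -- Hex, HexNAc, dHex (fucose), NeuAc and
#' phosphate -- with default count bounds reflecting mammalian N-glycan
#' biology. Masses are sums of standard atomic monoisotopic masses for the
#' residues (dehydrated monomers; HPO3 for phosphate).
#'
#' @param max_counts named integer overrides of the per-block count bounds
#'   (defaults: Hex 9, HexNAc 7, dHex 2, NeuAc 4, P 2).
#' @return data frame with columns `block`, `mass`, `max_count`.
#' @export
default_building_blocks <- function(max_counts = NULL) {
  blocks <- data.frame(
    block = c("Hex", "HexNAc", "dHex", "NeuAc", "P"),
    mass = c(162.05282, 203.07937, 146.05791, 291.09542, 79.96633),
    max_count = c(9L, 7L, 2L, 4L, 2L))
  if (!is.null(max_counts)) {
    i <- match(names(max_counts), blocks$block)
    if (anyNA(i)) stop("unknown building block in max_counts")
    blocks$max_count[i] <- as.integer(max_counts)
  }
  if (any(blocks$mass <= 0) || any(blocks$max_count < 0))
    stop("block masses must be positive and bounds non-negative")
  blocks
}

#' Parse a glycan composition string into block counts
#'
#' @param x composition string such as `"Hex5HexNAc2dHex1"`.
#' @param blocks a building-block set; see [default_building_blocks()].
#' @return named integer vector of counts over all blocks.
#' @export
parse_composition <- function(x, blocks = default_building_blocks()) {
  counts <- setNames(integer(length(blocks$block)), blocks$block)
  rest <- x
  # longest names first so Hex does not swallow HexNAc/dHex
  pat <- paste0("^(", paste(blocks$block[order(-nchar(blocks$block))],
                            collapse = "|"), ")([0-9]*)")
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec(pat, rest))[[1]]
    if (length(m) == 0) stop("unknown building block in composition: ", x)
    n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    counts[m[2]] <- counts[m[2]] + n
    rest <- substring(rest, nchar(m[1]) + 1)
  }
  counts
}

# Canonical composition string from a count vector (zero counts dropped).
composition_string <- function(counts) {
  nz <- counts[counts > 0]
  if (length(nz) == 0) return("")
  paste0(names(nz), nz, collapse = "")
}

#' Render a glycoform class label
#'
#' Conventional display form for an N-glycan composition: Hex rendered as Man,
#' HexNAc as GlcNAc, dHex as Fuc (counts of 1 unnumbered), joined by dashes --
#' `{Hex:5, HexNAc:2, dHex:1}` becomes `"Man5-GlcNAc2-Fuc"`. This is a label
#' convention only; compositions do not distinguish isobaric structures.
#'
#' @param counts named counts (as from [parse_composition()]).
#' @return label string.
#' @export
glycoform_label <- function(counts) {
  display <- c(Hex = "Man", HexNAc = "GlcNAc", dHex = "Fuc",
               NeuAc = "NeuAc", P = "P")
  nz <- counts[counts > 0]
  if (length(nz) == 0) return("unglycosylated")
  nm <- ifelse(is.na(display[names(nz)]), names(nz), display[names(nz)])
  paste0(nm, ifelse(nz == 1, "", nz), collapse = "-")
}

#' Neutral mass from m/z and charge
#'
#' Protonated-species convention: `M = mz*z - z*1.0072765`.
#'
#' @param mz observed m/z (Th).
#' @param charge charge state (>= 1).
#' @return neutral monoisotopic mass (Da).
#' @export
neutral_mass <- function(mz, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  mz * charge - charge * .PROTON_MASS
}

# Monoisotopic residue masses of the 20 standard amino acids.
.AA_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water.
#'
#' @param sequence amino-acid string (standard one-letter codes).
#' @return monoisotopic mass (Da).
#' @examples
#' peptide_mass("KVANKT")  # 659.39661
#' @export
peptide_mass <- function(sequence) {
  if (!nzchar(sequence)) return(.WATER_MASS)
  aa <- strsplit(toupper(sequence), "")[[1]]
  m <- .AA_MASS[aa]
  if (anyNA(m)) stop("unknown residue: ",
                     paste(unique(aa[is.na(m)]), collapse = ", "))
  sum(m) + .WATER_MASS
}

#' Bounded combinatorial mass decomposition of a glycopeptide
#'
#' For each candidate peptide backbone, exhaustively enumerates every
#' composition over the building blocks (depth-first over block counts with
#' branch-and-bound on the remaining mass) whose theoretical mass
#' `peptide + sum(count * block mass)` matches the observed neutral mass
#' within the ppm tolerance. The ppm error is computed against the theoretical
#' mass. Candidates are ranked by `|ppm_error|`, ties broken lexicographically
#' on the composition count vector, so the ordering is deterministic.
#'
#' @param mass observed neutral mass (Da).
#' @param peptide_candidates data frame with columns `peptide_id` and `mass`
#'   (Da); an empty frame yields an empty result.
#' @param blocks building-block set; see [default_building_blocks()].
#' @param tolerance_ppm mass tolerance (default 5 ppm).
#' @param max_nodes enumeration-node budget; exceeding it is an error advising
#'   tighter bounds (default 1e6).
#' @return data frame: `peptide_id`, one count column per block, `glycoform`,
#'   `theoretical_mass`, `ppm_error`.
#' @examples
#' pep <- data.frame(peptide_id = "KVANKT", mass = peptide_mass("KVANKT"))
#' decompose_mass(1957.87255, pep)  # Hex3HexNAc4, the G0 composition
#' @export
decompose_mass <- function(mass, peptide_candidates,
                           blocks = default_building_blocks(),
                           tolerance_ppm = 5, max_nodes = 1e6) {
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be positive")
  empty <- data.frame(peptide_id = character(0))
  if (is.null(peptide_candidates) || nrow(peptide_candidates) == 0)
    return(empty)
  stopifnot(all(c("peptide_id", "mass") %in% names(peptide_candidates)))

  nb <- nrow(blocks)
  # suffix sums of the maximal achievable mass from block i onward
  max_add <- rev(cumsum(rev(blocks$mass * blocks$max_count)))
  nodes <- 0L
  results <- list()

  for (pi in seq_len(nrow(peptide_candidates))) {
    pep_id <- peptide_candidates$peptide_id[pi]
    pep_mass <- peptide_candidates$mass[pi]
    # theoretical glycan mass window implied by |ppm(obs vs theo)| <= tol
    lo <- mass / (1 + tolerance_ppm * 1e-6) - pep_mass
    hi <- mass / (1 - tolerance_ppm * 1e-6) - pep_mass
    if (hi < -1e-9) next
    counts <- integer(nb)
    dfs <- function(i, partial) {
      nodes <<- nodes + 1L
      if (nodes > max_nodes)
        stop("enumeration exceeded ", max_nodes,
             " nodes; tighten the block count bounds")
      if (i > nb) {
        if (partial >= lo && partial <= hi) {
          theo <- pep_mass + partial
          results[[length(results) + 1]] <<- data.frame(
            peptide_id = pep_id, t(counts),
            theoretical_mass = theo,
            ppm_error = 1e6 * (mass - theo) / theo)
        }
        return(invisible(NULL))
      }
      remaining_max <- if (i < nb) max_add[i + 1] else 0
      cmax <- min(blocks$max_count[i],
                  floor((hi - partial) / blocks$mass[i] + 1e-9))
      if (cmax >= 0)
        for (ci in 0:cmax) {
          p2 <- partial + ci * blocks$mass[i]
          if (p2 + remaining_max < lo - 1e-9) next  # cannot reach window
          counts[i] <<- ci
          dfs(i + 1, p2)
        }
      counts[i] <<- 0L
      invisible(NULL)
    }
    dfs(1, 0)
  }
  if (length(results) == 0) return(empty)
  out <- do.call(rbind, results)
  names(out)[2:(1 + nb)] <- blocks$block
  cnt <- as.matrix(out[, blocks$block, drop = FALSE])
  ord <- do.call(order, c(list(abs(out$ppm_error)),
                          lapply(seq_len(nb), function(j) cnt[, j])))
  out <- out[ord, , drop = FALSE]
  out$glycoform <- apply(out[, blocks$block, drop = FALSE], 1, function(r)
    composition_string(setNames(as.integer(r), blocks$block)))
  rownames(out) <- NULL
  out
}

#' Assign glycopeptide compositions to a precursor feature table
#'
#' Computes the neutral mass of every feature ([neutral_mass()]) and keeps the
#' top-ranked in-tolerance composition from [decompose_mass()]. Assignment
#' depends only on the neutral mass, so the same species observed at
#' different charge states receives the same composition.
#'
#' @param features data frame with columns `feature_id`, `mz`, `charge`,
#'   `intensity`, `glycosite` (e.g. from [gen_glycopeptide_features()]).
#' @param peptides data frame with `peptide_id`, `mass` and optionally
#'   `glycosite` (restricting candidates per site).
#' @param blocks,tolerance_ppm passed to [decompose_mass()].
#' @return data frame of assignments (one row per assignable feature):
#'   feature columns plus `peptide_id`, block counts, `glycoform`,
#'   `theoretical_mass`, `ppm_error`.
#' @export
assign_glycopeptides <- function(features, peptides,
                                 blocks = default_building_blocks(),
                                 tolerance_ppm = 5) {
  stopifnot(all(c("feature_id", "mz", "charge", "intensity") %in%
                  names(features)))
  rows <- list()
  for (i in seq_len(nrow(features))) {
    cand <- peptides
    if ("glycosite" %in% names(peptides) && "glycosite" %in% names(features))
      cand <- peptides[peptides$glycosite == features$glycosite[i], ]
    hits <- decompose_mass(neutral_mass(features$mz[i], features$charge[i]),
                           cand, blocks, tolerance_ppm)
    if (nrow(hits) == 0) next
    top <- hits[1, , drop = FALSE]
    keep <- intersect(c("feature_id", "mz", "charge", "intensity",
                        "glycosite", "sample_id"), names(features))
    rows[[length(rows) + 1]] <- cbind(features[i, keep, drop = FALSE], top)
  }
  if (length(rows) == 0)
    return(data.frame(feature_id = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect glycosite-bearing peptides from PNGase F deamidation
#'
#' PNGase F removal of an N-glycan converts the glycosylated Asn to Asp,
#' leaving a +0.98402 Da deamidation mark. Peptides whose deamidated form
#' increases in yield after treatment beyond a fold threshold are flagged as
#' glycosite evidence.
#'
#' @param before,after data frames with columns `peptide_id`, `deamidated`
#'   (logical), `abundance`, measured before and after PNGase F treatment.
#' @param fold_threshold minimal after/before deamidated-yield ratio to flag
#'   (default 2).
#' @return data frame: `peptide_id`, `deamidated_before`, `deamidated_after`,
#'   `ratio`, `glycosite_evidence`. Peptides lacking deamidated rows in either
#'   table are skipped with a warning.
#' @export
detect_glycosite_peptides <- function(before, after, fold_threshold = 2) {
  need <- c("peptide_id", "deamidated", "abundance")
  stopifnot(all(need %in% names(before)), all(need %in% names(after)))
  ids <- union(before$peptide_id, after$peptide_id)
  rows <- list(); skipped <- character(0)
  for (id in ids) {
    b <- before$abundance[before$peptide_id == id & before$deamidated]
    a <- after$abundance[after$peptide_id == id & after$deamidated]
    if (length(b) == 0 || length(a) == 0) {
      skipped <- c(skipped, id)
      next
    }
    ratio <- sum(a) / sum(b)
    rows[[length(rows) + 1]] <- data.frame(
      peptide_id = id, deamidated_before = sum(b), deamidated_after = sum(a),
      ratio = ratio, glycosite_evidence = is.finite(ratio) &&
        ratio > fold_threshold || (sum(b) == 0 && sum(a) > 0))
  }
  if (length(skipped))
    warning("no deamidated counterpart rows; skipped: ",
            paste(skipped, collapse = ", "))
  if (length(rows) == 0) return(data.frame(peptide_id = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The deamidation mass delta left by PNGase F
#' @return +0.98402 Da (Asn to Asp).
#' @export
deamidation_delta <- function() 0.98402

#' Per-glycosite glycoform report
#'
#' Quantifies the glycoform distribution at one glycosite over the `top_n`
#' most intense assigned features: fractions are intensity shares over the
#' top-n total, aggregated by glycoform class, and the core-fucosylated
#' fraction is the intensity share of assignments carrying at least one dHex.
#'
#' @param assignments assignment table from [assign_glycopeptides()] (needs
#'   `glycosite`, `intensity`, `glycoform`, `dHex` columns).
#' @param site_id glycosite to report.
#' @param top_n number of most intense features forming the denominator
#'   (default 5, the usual site-specific quantification rule).
#' @return object of class `glycosite_report`: `site_id`, `table` (glycoform,
#'   `label`, `intensity`, `fraction`), `fucosylated_fraction`, `top_n_used`.
#' @export
site_report <- function(assignments, site_id, top_n = 5) {
  sub <- assignments[assignments$glycosite == site_id, , drop = FALSE]
  if (nrow(sub) == 0) stop("no assignments for site ", site_id)
  sub <- sub[order(-sub$intensity), , drop = FALSE]
  sub <- head(sub, top_n)
  total <- sum(sub$intensity)
  agg <- tapply(sub$intensity, sub$glycoform, sum)
  has_fuc <- tapply(sub$dHex, sub$glycoform, function(z) z[1] >= 1)
  tab <- data.frame(glycoform = names(agg),
                    intensity = as.numeric(agg),
                    fraction = as.numeric(agg) / total,
                    fucosylated = as.logical(has_fuc[names(agg)]),
                    row.names = NULL)
  tab$label <- vapply(tab$glycoform, function(g)
    glycoform_label(parse_composition(g)), character(1))
  tab <- tab[order(-tab$fraction), c("glycoform", "label", "intensity",
                                     "fraction", "fucosylated")]
  structure(list(site_id = site_id, table = tab,
                 fucosylated_fraction = sum(sub$intensity[sub$dHex >= 1]) / total,
                 top_n_used = nrow(sub)),
            class = "glycosite_report")
}

#' @export
print.glycosite_report <- function(x, ...) {
  cat(sprintf("Glycosite %s (top %d features): core-fucosylated fraction %.2f\n",
              x$site_id, x$top_n_used, x$fucosylated_fraction))
  print(x$table, row.names = FALSE)
  invisible(x)
}
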