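#' Percent of input chromatin from Ct values
#'
#' Dilution-adjusted delta-Ct quantification:
#' `% = 100 * input_fraction * efficiency^(ct_input - ct_ip)`.
#' With equal Cts and the whole input used the result is 100%; a 5-cycle
#' deficit at efficiency 2 gives `100 * 2^-5 = 3.125%`. Adding a constant
#' to both Cts leaves the result unchanged.
#'
#' @param ct_ip Ct of the immunoprecipitated (or FAIRE aqueous-phase)
#'   DNA.
#' @param ct_input Ct of the input aliquot.
#' @param input_fraction fraction of chromatin in the input aliquot, in
#'   (0, 1].
#' @param efficiency per-cycle amplification factor (> 1; default 2,
#'   perfect doubling).
#' @return Percent of input (numeric, vectorized).
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction, efficiency = 2) {
  if (any(efficiency <= 1)) {
    stop("amplification efficiency must be > 1", call. = FALSE)
  }
  if (any(input_fraction <= 0 | input_fraction > 1)) {
    stop("input_fraction must be in (0, 1]", call. = FALSE)
  }
  if (any(c(ct_ip, ct_input) <= 0)) {
    stop("Ct values must be > 0", call. = FALSE)
  }
  100 * input_fraction * efficiency^(ct_input - ct_ip)
}

#' FAIRE signal as percent of input
#'
#' Identical arithmetic to [percent_input()] with the open-chromatin
#' (FAIRE aqueous phase) DNA as numerator, normalized against the
#' non-cross-linked input DNA.
#'
#' @param ct_faire Ct of the FAIRE (aqueous-phase) DNA.
#' @inheritParams percent_input
#' @export
faire_signal <- function(ct_faire, ct_input, input_fraction,
                         efficiency = 2) {
  percent_input(ct_faire, ct_input, input_fraction,
                efficiency = efficiency)
}

# min/max ratio propagation for mean-and-range summaries
ratio_with_range <- function(num, den, num_range = NULL, den_range = NULL) {
  if (any(den <= 0)) {
    return(list(ratio = NA_real_, lo = NA_real_, hi = NA_real_,
                note = "zero denominator"))
  }
  out <- list(ratio = num / den, lo = NA_real_, hi = NA_real_, note = "")
  if (!is.null(num_range) && !is.null(den_range)) {
    out$lo <- num_range[1] / den_range[2]
    out$hi <- num_range[2] / den_range[1]
  }
  out
}

#' Fold enrichment over a control region
#'
#' Plain ratio of percent-of-input at a target region over a control
#' region; when replicate ranges are supplied the ratio range is
#' propagated by min/max arithmetic (matching mean-and-range reporting of
#' duplicate PCR reactions). A zero denominator yields a flagged NA.
#'
#' @param percent_target percent of input at the target region.
#' @param percent_control percent of input at the control region.
#' @param target_range,control_range optional `c(lo, hi)` replicate
#'   ranges.
#' @return List with `ratio`, `lo`, `hi`, `note`.
#' @export
fold_enrichment <- function(percent_target, percent_control,
                            target_range = NULL, control_range = NULL) {
  ratio_with_range(percent_target, percent_control, target_range,
                   control_range)
}

#' Induction fold between treatment and vehicle
#'
#' @param percent_treated percent of input after treatment.
#' @param percent_vehicle percent of input in the vehicle control.
#' @param treated_range,vehicle_range optional `c(lo, hi)` ranges.
#' @return List with `ratio`, `lo`, `hi`, `note`.
#' @export
induction_fold <- function(percent_treated, percent_vehicle,
                           treated_range = NULL, vehicle_range = NULL) {
  ratio_with_range(percent_treated, percent_vehicle, treated_range,
                   vehicle_range)
}

#' Reference-normalized relative expression (delta-delta-Ct)
#'
#' `fold = 2^-( (ct_target - ct_ref)_A - (ct_target - ct_ref)_B )`:
#' expression of condition A relative to condition B, both normalized to
#' a reference transcript (e.g. GAPDH). Swapping the two conditions
#' inverts the fold exactly.
#'
#' @param ct_target_a,ct_ref_a target and reference Cts in condition A.
#' @param ct_target_b,ct_ref_b target and reference Cts in condition B.
#' @param efficiency per-cycle amplification factor (default 2).
#' @return Fold change of A relative to B.
#' @export
relative_expression <- function(ct_target_a, ct_ref_a, ct_target_b,
                                ct_ref_b, efficiency = 2) {
  if (any(is.na(c(ct_ref_a, ct_ref_b)))) {
    stop("missing reference-gene measurement", call. = FALSE)
  }
  if (any(efficiency <= 1)) {
    stop("amplification efficiency must be > 1", call. = FALSE)
  }
  dct_a <- ct_target_a - ct_ref_a
  dct_b <- ct_target_b - ct_ref_b
  efficiency^(-(dct_a - dct_b))
}

ct_required_cols <- c("region", "assay", "condition", "replicate", "ct",
                      "input_fraction")

#' Read a qPCR Ct table from TSV
#'
#' Expects columns `region`, `assay` (CHIP/FAIRE/INPUT/RT), `condition`,
#' `replicate`, `ct`, `input_fraction`, optionally `position_bp`. Missing
#' required columns are reported by name.
#'
#' @param path TSV path.
#' @return data.frame of Ct records.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(ct_required_cols, names(df))
  if (length(missing)) {
    stop("Ct table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(df$ct <= 0)) stop("Ct values must be > 0", call. = FALSE)
  if (any(df$input_fraction <= 0 | df$input_fraction > 1)) {
    stop("input_fraction must be in (0, 1]", call. = FALSE)
  }
  df
}

#' Quantify an IP-type assay against its input as percent of input
#'
#' Pairs each CHIP or FAIRE replicate with the matching `INPUT` replicate
#' for the same region and condition, computes per-replicate percent of
#' input ([percent_input()]) and summarizes as mean and replicate range.
#'
#' @param ct_table Ct record data.frame (see [read_ct_table()]).
#' @param assay `"CHIP"` or `"FAIRE"`.
#' @param efficiency amplification factor (default 2).
#' @return data.frame: `region`, `position_bp`, `condition`, `mean`,
#'   `lo`, `hi`, `n_replicates`.
#' @export
percent_input_table <- function(ct_table, assay = "CHIP", efficiency = 2) {
  missing <- setdiff(ct_required_cols, names(ct_table))
  if (length(missing)) {
    stop("Ct table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ip <- ct_table[ct_table$assay == assay, ]
  inp <- ct_table[ct_table$assay == "INPUT", ]
  if (nrow(ip) == 0L) stop("no ", assay, " records", call. = FALSE)
  if (nrow(inp) == 0L) stop("no INPUT records", call. = FALSE)
  keys <- unique(ip[, c("region", "condition")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    a <- ip[ip$region == k$region & ip$condition == k$condition, ]
    b <- inp[inp$region == k$region & inp$condition == k$condition, ]
    if (nrow(b) == 0L) {
      stop("no INPUT measurement for region '", k$region,
           "', condition '", k$condition, "'", call. = FALSE)
    }
    reps <- intersect(a$replicate, b$replicate)
    vals <- if (length(reps)) {
      vapply(reps, function(r) {
        percent_input(a$ct[a$replicate == r][1], b$ct[b$replicate == r][1],
                      b$input_fraction[b$replicate == r][1],
                      efficiency = efficiency)
      }, 0)
    } else {          # unpaired replicates: compare means
      percent_input(mean(a$ct), mean(b$ct), b$input_fraction[1],
                    efficiency = efficiency)
    }
    pos <- if ("position_bp" %in% names(a)) a$position_bp[1] else NA_real_
    data.frame(region = k$region, position_bp = pos,
               condition = k$condition, mean = mean(vals),
               lo = min(vals), hi = max(vals), n_replicates = length(vals),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Quantify relative expression from an RT Ct table
#'
#' For every target region (gene) and condition, the delta-Ct against the
#' reference gene is formed per replicate and expression is reported
#' relative to `baseline` condition via [relative_expression()].
#'
#' @param ct_table Ct record data.frame with `assay == "RT"` rows.
#' @param reference_gene region name of the normalizer (e.g. "GAPDH").
#' @param baseline condition used as the comparison baseline.
#' @param efficiency amplification factor.
#' @return data.frame: `region`, `condition`, `fold`, `lo`, `hi`.
#' @export
relative_expression_table <- function(ct_table, reference_gene,
                                      baseline, efficiency = 2) {
  rt <- ct_table[ct_table$assay == "RT", ]
  if (nrow(rt) == 0L) stop("no RT records", call. = FALSE)
  if (!reference_gene %in% rt$region) {
    stop("reference gene '", reference_gene, "' absent from the table",
         call. = FALSE)
  }
  targets <- setdiff(unique(rt$region), reference_gene)
  conds <- unique(rt$condition)
  if (!baseline %in% conds) {
    stop("baseline condition '", baseline, "' absent", call. = FALSE)
  }
  dct <- function(gene, cond) {
    tc <- rt$ct[rt$region == gene & rt$condition == cond]
    rc <- rt$ct[rt$region == reference_gene & rt$condition == cond]
    if (length(tc) == 0L || length(rc) == 0L) return(NULL)
    n <- min(length(tc), length(rc))
    tc[seq_len(n)] - rc[seq_len(n)]
  }
  rows <- list()
  for (g in targets) {
    d0 <- dct(g, baseline)
    if (is.null(d0)) next
    for (cond in conds) {
      d1 <- dct(g, cond)
      if (is.null(d1)) next
      folds <- efficiency^(-(outer(d1, d0, `-`)))
      rows[[length(rows) + 1L]] <- data.frame(
        region = g, condition = cond,
        fold = efficiency^(-(mean(d1) - mean(d0))),
        lo = min(folds), hi = max(folds), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Locus-scanning profile across primer positions
#'
#' Orders quantified values by primer position (e.g. 1-kb steps across a
#' locus) into a profile of mean and replicate range per position.
#' Duplicate positions carrying conflicting region names are rejected.
#'
#' @param quantified data.frame from [percent_input_table()] (or any
#'   table with `region`, `position_bp`, `mean`, `lo`, `hi`).
#' @return data.frame of class `locus_profile`, sorted by strictly
#'   increasing `position_bp`.
#' @export
locus_scan_profile <- function(quantified) {
  stopifnot(all(c("region", "position_bp", "mean") %in% names(quantified)))
  if (any(is.na(quantified$position_bp))) {
    stop("every record needs a position_bp for locus scanning",
         call. = FALSE)
  }
  if (length(unique(quantified$position_bp)) < 2L) {
    stop("locus scanning needs at least 2 distinct positions",
         call. = FALSE)
  }
  chk <- unique(quantified[, c("position_bp", "region")])
  if (anyDuplicated(chk$position_bp)) {
    dup <- chk$position_bp[duplicated(chk$position_bp)][1]
    stop("conflicting region names at position ", dup, call. = FALSE)
  }
  out <- quantified[order(quantified$position_bp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("locus_profile", "data.frame")
  out
}
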