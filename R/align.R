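#' Align a bisulfite clone to its amplicon reference
#'
#' Global alignment with free end gaps against the fully converted
#' reference ([convert_reference()]). A clone `C` or `T` aligned to a
#' reference-cytosine column scores as a match (C/T degeneracy, top strand
#' only); alignment identity is assessed over the non-degenerate columns
#' (reference bases other than C), where the clone must match the original
#' reference base.
#'
#' @param clone_seq clone DNA sequence (character).
#' @param reference an [amplicon_reference()].
#' @param clone_id identifier used in reports.
#' @param max_length_frac clone length must be within this fraction of the
#'   reference length (default 0.2, i.e. +/- 20 percent).
#' @param min_identity minimum identity over non-degenerate columns below
#'   which the clone is rejected (default 0.8).
#' @param gap_opening,gap_extension affine gap penalties.
#' @param match,mismatch substitution scores (C/T pairs always score as
#'   match).
#' @return Object of class `clone_alignment`: list with `clone_id`, `map`
#'   (character vector over reference positions giving the aligned clone
#'   base, `NA` where gapped/uncovered), `identity`, `n_compared`,
#'   `rejected` (FALSE or a reason string).
#' @export
align_clone <- function(clone_seq, reference, clone_id = "clone",
                        max_length_frac = 0.2, min_identity = 0.8,
                        gap_opening = 6, gap_extension = 2,
                        match = 1, mismatch = -2) {
  stopifnot(inherits(reference, "amplicon_reference"))
  clone_seq <- toupper(as.character(clone_seq))
  L <- nchar(reference$sequence)
  if (abs(nchar(clone_seq) - L) > max_length_frac * L) {
    return(structure(list(clone_id = clone_id, map = rep(NA_character_, L),
                          identity = NA_real_, n_compared = 0L,
                          rejected = "length"),
                     class = "clone_alignment"))
  }
  conv <- convert_reference(reference)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  bases <- c("A", "C", "G", "T")
  mat <- mat[bases, bases]
  mat["C", "T"] <- mat["T", "C"] <- match   # bisulfite degeneracy
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(conv), Biostrings::DNAString(clone_seq),
    substitutionMatrix = mat, type = "overlap",
    gapOpening = gap_opening, gapExtension = gap_extension)

  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  map <- rep(NA_character_, L)
  refpos <- Biostrings::start(Biostrings::pattern(al)) - 1L  # 0-based - 1
  for (k in seq_along(p)) {
    if (p[k] != "-") {
      refpos <- refpos + 1L              # now 1-based reference index
      if (s[k] != "-") map[refpos] <- s[k]
    }
  }

  refchars <- strsplit(reference$sequence, "", fixed = TRUE)[[1]]
  nondeg <- which(refchars != "C" & !is.na(map))
  n_compared <- length(nondeg)
  identity <- if (n_compared > 0) mean(map[nondeg] == refchars[nondeg])
              else NA_real_
  rejected <- FALSE
  if (is.na(identity) || identity < min_identity) rejected <- "identity"
  structure(list(clone_id = clone_id, map = map, identity = identity,
                 n_compared = n_compared, rejected = rejected),
            class = "clone_alignment")
}

#' @export
print.clone_alignment <- function(x, ...) {
  if (!isFALSE(x$rejected)) {
    cat(sprintf("Clone alignment '%s': REJECTED (%s)\n", x$clone_id,
                x$rejected))
  } else {
    cat(sprintf("Clone alignment '%s': identity %.3f over %d columns\n",
                x$clone_id, x$identity, x$n_compared))
  }
  invisible(x)
}

#' Call methylation-protection states at registry sites for one clone
#'
#' At every cytosine of the registry the aligned clone base is interpreted
#' as `RETAINED` (read `C`: protected from conversion, i.e. methylated),
#' `CONVERTED` (read `T`) or `AMBIGUOUS` (gap or any other base). GCG
#' sites are always `AMBIGUOUS` because exogenous GpC and endogenous CpG
#' methylation are confounded there. The per-clone conversion efficiency
#' is the converted fraction of CH cytosines (which carry no methylation).
#'
#' @param alignment a [align_clone()] result.
#' @param registry a `site_registry` from [classify_sites()].
#' @return List with `calls` (named character vector, names = 0-based site
#'   positions), `class` (site classes), `conversion_efficiency`,
#'   `mismatch_rate`.
#' @export
call_sites <- function(alignment, registry) {
  stopifnot(inherits(alignment, "clone_alignment"))
  if (!isFALSE(alignment$rejected)) {
    stop("cannot call sites on a rejected alignment (", alignment$rejected,
         ")", call. = FALSE)
  }
  s <- registry_sites(registry)
  base <- alignment$map[s$pos + 1L]
  calls <- ifelse(is.na(base), "AMBIGUOUS",
           ifelse(base == "C", "RETAINED",
           ifelse(base == "T", "CONVERTED", "AMBIGUOUS")))
  calls[s$class == "GCG"] <- "AMBIGUOUS"
  names(calls) <- s$pos
  ch <- s$class == "CH"
  n_conv <- sum(calls[ch] == "CONVERTED")
  n_ret <- sum(calls[ch] == "RETAINED")
  eff <- if (n_conv + n_ret > 0) n_conv / (n_conv + n_ret) else NA_real_
  list(calls = calls, class = s$class,
       conversion_efficiency = eff,
       mismatch_rate = 1 - alignment$identity)
}
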