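#' Build a clone call matrix from clone sequences
#'
#' Aligns every clone to the reference ([align_clone()]), calls all
#' registry sites ([call_sites()]) and assembles the per-clone by per-site
#' call matrix with clone-level QC metrics. Clones whose alignment is
#' rejected (length or identity) are dropped and recorded.
#'
#' @param clones named character vector of clone sequences.
#' @param reference an [amplicon_reference()].
#' @param condition condition label carried through to statistics.
#' @param ... passed to [align_clone()].
#' @return Object of class `clone_calls`: list with `calls` (character
#'   matrix, clones x sites, values `RETAINED`/`CONVERTED`/`AMBIGUOUS`),
#'   `sites` (0-based positions), `site_class`, `conversion_efficiency`,
#'   `mismatch_rate`, `ambiguous_frac` (per clone, over GCH+HCG sites),
#'   `rejected` (data.frame clone/reason), `condition`, `reference_name`.
#' @export
call_clones <- function(clones, reference, condition = "sample", ...) {
  stopifnot(inherits(reference, "amplicon_reference"))
  if (is.null(names(clones))) {
    names(clones) <- sprintf("clone%02d", seq_along(clones))
  }
  reg <- reference$sites
  s <- registry_sites(reg)
  rows <- list(); eff <- c(); mm <- c(); rej <- list()
  for (id in names(clones)) {
    al <- align_clone(clones[[id]], reference, clone_id = id, ...)
    if (!isFALSE(al$rejected)) {
      rej[[length(rej) + 1L]] <- data.frame(clone = id, reason = al$rejected,
                                            stringsAsFactors = FALSE)
      next
    }
    cs <- call_sites(al, reg)
    rows[[id]] <- cs$calls
    eff[id] <- cs$conversion_efficiency
    mm[id] <- cs$mismatch_rate
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    matrix(character(0), 0, length(s$pos),
           dimnames = list(NULL, s$pos))
  scored <- s$class %in% c("GCH", "HCG")
  amb <- if (nrow(calls) && any(scored)) {
    rowMeans(calls[, scored, drop = FALSE] == "AMBIGUOUS")
  } else stats::setNames(numeric(nrow(calls)), rownames(calls))
  structure(list(calls = calls, sites = s$pos, site_class = s$class,
                 conversion_efficiency = eff, mismatch_rate = mm,
                 ambiguous_frac = amb,
                 rejected = if (length(rej)) do.call(rbind, rej) else
                   data.frame(clone = character(0), reason = character(0)),
                 condition = condition,
                 reference_name = reference$name),
            class = "clone_calls")
}

#' @export
print.clone_calls <- function(x, ...) {
  cat(sprintf("Clone call matrix '%s' (%s): %d clones x %d sites\n",
              x$condition, x$reference_name, nrow(x$calls),
              length(x$sites)))
  tab <- table(factor(x$site_class, c("GCH", "HCG", "GCG", "CH")))
  cat(sprintf("  sites: %d GCH, %d HCG, %d GCG, %d CH; %d clone(s) rejected\n",
              tab["GCH"], tab["HCG"], tab["GCG"], tab["CH"],
              nrow(x$rejected)))
  if (length(x$conversion_efficiency)) {
    cat(sprintf("  conversion efficiency: median %.3f (range %.3f-%.3f)\n",
                stats::median(x$conversion_efficiency, na.rm = TRUE),
                suppressWarnings(min(x$conversion_efficiency, na.rm = TRUE)),
                suppressWarnings(max(x$conversion_efficiency, na.rm = TRUE))))
  }
  invisible(x)
}

# subset a clone_calls object to a set of clone ids
subset_clones <- function(x, keep) {
  x$calls <- x$calls[keep, , drop = FALSE]
  x$conversion_efficiency <- x$conversion_efficiency[keep]
  x$mismatch_rate <- x$mismatch_rate[keep]
  x$ambiguous_frac <- x$ambiguous_frac[keep]
  x
}

#' Filter clones on conversion efficiency and ambiguity
#'
#' Removes clones whose bisulfite conversion efficiency (over CH control
#' cytosines) falls below `min_conversion` or whose ambiguous-call
#' fraction (over GCH+HCG sites) exceeds `max_ambiguous`, and reports the
#' removals with reasons. Clones with no assessable CH site are kept
#' (efficiency undefined).
#'
#' @param x a `clone_calls` object.
#' @param min_conversion minimum conversion efficiency (default 0.95).
#' @param max_ambiguous maximum ambiguous fraction (default 0.2).
#' @return The filtered `clone_calls`, with a `qc` data.frame attached
#'   (columns clone, conversion_efficiency, ambiguous_frac, kept, reason).
#' @export
filter_clones <- function(x, min_conversion = 0.95, max_ambiguous = 0.2) {
  stopifnot(inherits(x, "clone_calls"))
  check_prob(min_conversion, "min_conversion")
  check_prob(max_ambiguous, "max_ambiguous")
  ids <- rownames(x$calls)
  low_conv <- !is.na(x$conversion_efficiency) &
    x$conversion_efficiency < min_conversion
  high_amb <- x$ambiguous_frac > max_ambiguous
  reason <- rep("", length(ids))
  reason[high_amb] <- "ambiguous"
  reason[low_conv] <- ifelse(high_amb[low_conv], "conversion;ambiguous",
                             "conversion")
  kept <- !(low_conv | high_amb)
  qc <- data.frame(clone = ids,
                   conversion_efficiency = unname(x$conversion_efficiency),
                   ambiguous_frac = unname(x$ambiguous_frac),
                   kept = kept, reason = reason, stringsAsFactors = FALSE)
  if (!any(kept)) {
    stop("all clones removed by QC filtering (min_conversion = ",
         min_conversion, ", max_ambiguous = ", max_ambiguous, ")",
         call. = FALSE)
  }
  out <- subset_clones(x, which(kept))
  out$qc <- qc
  out
}

# single-letter encoding used in the TSV interchange format:
# GCH sites: A = accessible (RETAINED), I = inaccessible (CONVERTED), N;
# HCG sites: M = methylated (RETAINED), U = unmethylated (CONVERTED), N;
# GCG/CH sites: R/C/N (raw retained/converted).
encode_call <- function(call, class) {
  class <- rep(class, length.out = length(call))
  ifelse(call == "AMBIGUOUS", "N",
  ifelse(class == "GCH", ifelse(call == "RETAINED", "A", "I"),
  ifelse(class == "HCG", ifelse(call == "RETAINED", "M", "U"),
         ifelse(call == "RETAINED", "R", "C"))))
}

decode_call <- function(code) {
  ifelse(code == "N", "AMBIGUOUS",
  ifelse(code %in% c("A", "M", "R"), "RETAINED", "CONVERTED"))
}

#' Write / read a clone call matrix as TSV
#'
#' Columns are named `<CLASS>_<position>`; calls are encoded one letter
#' per cell (`A`/`I`/`N` at GCH sites for accessible / inaccessible /
#' ambiguous, `M`/`U`/`N` at HCG sites, `R`/`C`/`N` at GCG and CH sites).
#' Clone-level QC metrics ride along as the final columns.
#'
#' @param x a `clone_calls` object.
#' @param path output TSV path.
#' @export
write_call_matrix <- function(x, path) {
  stopifnot(inherits(x, "clone_calls"))
  enc <- x$calls
  for (j in seq_along(x$sites)) {
    enc[, j] <- encode_call(x$calls[, j], x$site_class[j])
  }
  df <- data.frame(clone = rownames(x$calls),
                   condition = x$condition,
                   as.data.frame(enc, stringsAsFactors = FALSE),
                   conversion_efficiency = unname(x$conversion_efficiency),
                   ambiguous_frac = unname(x$ambiguous_frac),
                   check.names = FALSE)
  names(df)[3:(2 + length(x$sites))] <-
    paste0(x$site_class, "_", x$sites)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_call_matrix
#' @param reference_name optional reference name restored on read.
#' @export
read_call_matrix <- function(path, reference_name = "unknown") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  sitecols <- grep("^(GCH|HCG|GCG|CH)_[0-9]+$", names(df), value = TRUE)
  if (length(sitecols) == 0L) {
    stop("no site columns found in ", path, call. = FALSE)
  }
  cls <- sub("_.*$", "", sitecols)
  pos <- as.integer(sub("^[A-Z]+_", "", sitecols))
  o <- order(pos)
  sitecols <- sitecols[o]; cls <- cls[o]; pos <- pos[o]
  calls <- as.matrix(df[, sitecols, drop = FALSE])
  calls[] <- decode_call(calls)
  rownames(calls) <- df$clone
  colnames(calls) <- pos
  structure(list(calls = calls, sites = pos, site_class = cls,
                 conversion_efficiency =
                   stats::setNames(df$conversion_efficiency, df$clone),
                 mismatch_rate =
                   stats::setNames(rep(NA_real_, nrow(df)), df$clone),
                 ambiguous_frac = stats::setNames(df$ambiguous_frac,
                                                  df$clone),
                 rejected = data.frame(clone = character(0),
                                       reason = character(0)),
                 condition = if (nrow(df)) df$condition[1] else "sample",
                 reference_name = reference_name),
            class = "clone_calls")
}

#' Write a clone QC report as TSV
#' @param x a filtered `clone_calls` (from [filter_clones()]).
#' @param path output TSV path.
#' @export
write_qc_report <- function(x, path) {
  qc <- x$qc
  if (is.null(qc)) {
    qc <- data.frame(clone = rownames(x$calls),
                     conversion_efficiency =
                       unname(x$conversion_efficiency),
                     ambiguous_frac = unname(x$ambiguous_frac),
                     kept = TRUE, reason = "", stringsAsFactors = FALSE)
  }
  if (nrow(x$rejected)) {
    qc <- rbind(qc, data.frame(clone = x$rejected$clone,
                               conversion_efficiency = NA_real_,
                               ambiguous_frac = NA_real_, kept = FALSE,
                               reason = paste0("alignment:",
                                               x$rejected$reason)))
  }
  utils::write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
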