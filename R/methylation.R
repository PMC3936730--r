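#' Endogenous CpG methylation map
#'
#' Restricts a clone call matrix to its HCG sites and re-labels the calls
#' in methylation polarity: a retained cytosine at an HCG site was
#' protected from bisulfite conversion by endogenous CpG methylation
#' (METHYLATED); a converted one was unmethylated. The same alignment and
#' calling machinery serves NOMe-seq and genomic-bisulfite inputs; only
#' the interpreted site class differs.
#'
#' @param x a `clone_calls` object.
#' @param sample sample label (cell line / region); defaults to the call
#'   matrix condition.
#' @return Object of class `methylation_map`: list with `calls` (clone x
#'   HCG-site matrix of `METHYLATED`/`UNMETHYLATED`/`AMBIGUOUS`), `sites`
#'   (ordered 0-based positions), `sample`.
#' @export
methylation_map <- function(x, sample = NULL) {
  stopifnot(inherits(x, "clone_calls"))
  hcg_idx <- which(x$site_class == "HCG")
  m <- x$calls[, hcg_idx, drop = FALSE]
  calls <- ifelse(m == "RETAINED", "METHYLATED",
           ifelse(m == "CONVERTED", "UNMETHYLATED", "AMBIGUOUS"))
  colnames(calls) <- x$sites[hcg_idx]
  structure(list(calls = calls, sites = x$sites[hcg_idx],
                 sample = sample %||% x$condition),
            class = "methylation_map")
}

#' @export
print.methylation_map <- function(x, ...) {
  pct <- methylation_percent(x)
  cat(sprintf("Methylation map '%s': %d clones x %d CpG (HCG) sites\n",
              x$sample, nrow(x$calls), length(x$sites)))
  if (length(pct$percent_methylated)) {
    cat(sprintf("  mean methylation: %.1f%%\n",
                mean(pct$percent_methylated, na.rm = TRUE)))
  }
  invisible(x)
}

#' Per-site percent methylation
#'
#' `100 * n_methylated / (n_methylated + n_unmethylated)` over determinate
#' calls only; sites with no determinate call are flagged undefined.
#'
#' @param map a [methylation_map()].
#' @param sites HCG positions (default all).
#' @return data.frame: `pos`, `n_methylated`, `n_unmethylated`,
#'   `n_ambiguous`, `percent_methylated`, `defined`.
#' @export
methylation_percent <- function(map, sites = NULL) {
  stopifnot(inherits(map, "methylation_map"))
  sites <- sites %||% map$sites
  if (!all(sites %in% map$sites)) {
    stop("site(s) not in the HCG registry: ",
         paste(setdiff(sites, map$sites), collapse = ", "), call. = FALSE)
  }
  idx <- match(sites, map$sites)
  m <- map$calls[, idx, drop = FALSE]
  n_me <- colSums(m == "METHYLATED")
  n_un <- colSums(m == "UNMETHYLATED")
  n_am <- colSums(m == "AMBIGUOUS")
  pct <- ifelse(n_me + n_un > 0, 100 * n_me / (n_me + n_un), NA_real_)
  data.frame(pos = sites, n_methylated = unname(n_me),
             n_unmethylated = unname(n_un), n_ambiguous = unname(n_am),
             percent_methylated = unname(pct),
             defined = unname(n_me + n_un > 0))
}

#' Plot-ready lollipop structure (filled/open circles)
#'
#' Filled circles are methylated CpG sites, open circles unmethylated;
#' circle order follows genomic coordinate.
#'
#' @param map a [methylation_map()].
#' @return Object of class `lollipop_matrix`: list with `sites`, `clones`,
#'   `states` (`filled`/`open`/`missing`).
#' @export
lollipop_matrix <- function(map) {
  stopifnot(inherits(map, "methylation_map"))
  states <- ifelse(map$calls == "METHYLATED", "filled",
            ifelse(map$calls == "UNMETHYLATED", "open", "missing"))
  structure(list(sites = map$sites, clones = rownames(map$calls),
                 states = states, sample = map$sample),
            class = "lollipop_matrix")
}

#' Serialize / restore a lollipop matrix (JSON)
#' @param l a `lollipop_matrix`.
#' @export
lollipop_to_json <- function(l) {
  jsonlite::toJSON(list(sites = l$sites, clones = l$clones,
                        states = apply(l$states, 1, paste, collapse = ","),
                        sample = l$sample),
                   auto_unbox = FALSE, digits = NA)
}

#' @rdname lollipop_to_json
#' @param json JSON produced by [lollipop_to_json()].
#' @export
lollipop_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  states <- do.call(rbind, strsplit(x$states, ",", fixed = TRUE))
  rownames(states) <- x$clones
  colnames(states) <- x$sites
  structure(list(sites = as.integer(x$sites), clones = x$clones,
                 states = states, sample = x$sample[1]),
            class = "lollipop_matrix")
}

#' Compare two methylation maps site by site
#'
#' Per-site methylation difference (`sample A - sample B`, percentage
#' points) over the shared HCG registry, with determinate-call counts. No
#' statistical test is attached by default.
#'
#' @param mapA,mapB [methylation_map()] objects with overlapping site
#'   registries (disjoint registries are rejected).
#' @return data.frame: `pos`, `percent_a`, `percent_b`, `delta`,
#'   `n_determinate_a`, `n_determinate_b`, `defined` (FALSE where either
#'   map has no determinate call).
#' @export
compare_profiles <- function(mapA, mapB) {
  stopifnot(inherits(mapA, "methylation_map"),
            inherits(mapB, "methylation_map"))
  shared <- intersect(mapA$sites, mapB$sites)
  if (length(shared) == 0L) {
    stop("the two maps have disjoint site registries", call. = FALSE)
  }
  pa <- methylation_percent(mapA, shared)
  pb <- methylation_percent(mapB, shared)
  data.frame(pos = shared,
             percent_a = pa$percent_methylated,
             percent_b = pb$percent_methylated,
             delta = pa$percent_methylated - pb$percent_methylated,
             n_determinate_a = pa$n_methylated + pa$n_unmethylated,
             n_determinate_b = pb$n_methylated + pb$n_unmethylated,
             defined = pa$defined & pb$defined)
}

# window statistics used by the island scan: counts of C, G and CpG
# (dinucleotide fully inside the window [s, s+len) )
cpg_window_stats <- function(chars, cg_starts, s0, len) {
  # chars: character vector; cg_starts: 0-based start positions of "CG"
  idx <- (s0 + 1L):(s0 + len)
  nC <- sum(chars[idx] == "C")
  nG <- sum(chars[idx] == "G")
  nCpG <- sum(cg_starts >= s0 & cg_starts <= s0 + len - 2L)
  gc_pct <- 100 * (nC + nG) / len
  oe <- if (nC == 0L || nG == 0L) 0 else nCpG * len / (nC * nG)
  c(gc_pct = gc_pct, obs_exp = oe, n_cpg = nCpG)
}

#' Scan a sequence for CpG-rich regions
#'
#' Sliding-window scan in the style of the classic CpG-island search:
#' windows (default 200 bp, step 1) meeting both the %GC and the
#' observed/expected-CpG thresholds are merged when overlapping; each
#' merged region is trimmed so that it begins and ends with a CpG
#' dinucleotide (regions containing no CpG are left untrimmed) and then
#' re-checked against all three thresholds, including the minimum length.
#' `obs/exp = (n_CpG * L) / (n_C * n_G)`, defined as 0 when a window has
#' no C or no G.
#'
#' @param sequence DNA string (or [amplicon_reference()]).
#' @param min_gc minimum %GC (default 55).
#' @param min_oe minimum observed/expected CpG ratio (default 0.65).
#' @param min_len minimum region length in bp (default 500).
#' @param window window width in bp (default 200).
#' @param step window step in bp (default 1).
#' @return data.frame of class `cpg_regions`: `start`, `end` (0-based
#'   half-open), `length`, `gc_pct`, `obs_exp`.
#' @export
cpg_island_scan <- function(sequence, min_gc = 55, min_oe = 0.65,
                            min_len = 500, window = 200, step = 1) {
  seq <- if (inherits(sequence, "amplicon_reference")) sequence$sequence
         else toupper(sequence)
  L <- nchar(seq)
  if (L < window) stop("sequence shorter than the scan window",
                       call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  # cumulative counts for O(1) window statistics
  cumC <- cumsum(chars == "C")
  cumG <- cumsum(chars == "G")
  is_cg <- chars[-L] == "C" & chars[-1] == "G"
  cg_starts <- which(is_cg) - 1L                 # 0-based
  cumCG <- c(0L, cumsum(is_cg))
  starts <- seq.int(0L, L - window, by = step)
  cumC0 <- c(0L, cumC); cumG0 <- c(0L, cumG)
  nC <- cumC0[starts + window + 1L] - cumC0[starts + 1L]
  nG <- cumG0[starts + window + 1L] - cumG0[starts + 1L]
  nCpG <- cumCG[starts + window] - cumCG[starts + 1L]
  gc_pct <- 100 * (nC + nG) / window
  oe <- ifelse(nC == 0L | nG == 0L, 0, nCpG * window / (nC * nG))
  pass <- gc_pct >= min_gc & oe >= min_oe
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), gc_pct = numeric(0),
                      obs_exp = numeric(0))
  class(empty) <- c("cpg_regions", "data.frame")
  if (!any(pass)) return(empty)
  # merge overlapping passing windows
  ps <- starts[pass]
  gaps <- which(diff(ps) >= window)
  reg_start <- ps[c(1L, gaps + 1L)]
  reg_end <- ps[c(gaps, length(ps))] + window    # half-open
  rows <- list()
  for (i in seq_along(reg_start)) {
    s0 <- reg_start[i]; e0 <- reg_end[i]
    inreg <- cg_starts[cg_starts >= s0 & cg_starts <= e0 - 2L]
    if (length(inreg)) {                 # trim to first/last CpG
      s0 <- inreg[1]
      e0 <- inreg[length(inreg)] + 2L
    }
    len <- e0 - s0
    st <- cpg_window_stats(chars, cg_starts, s0, len)
    if (st["gc_pct"] >= min_gc && st["obs_exp"] >= min_oe &&
        len >= min_len) {
      rows[[length(rows) + 1L]] <-
        data.frame(start = s0, end = e0, length = len,
                   gc_pct = unname(st["gc_pct"]),
                   obs_exp = unname(st["obs_exp"]))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  class(out) <- c("cpg_regions", "data.frame")
  out
}

#' Write CpG-rich regions as BED
#' @param regions a `cpg_regions` data.frame.
#' @param path output BED path.
#' @param chrom sequence name for column 1.
#' @export
write_cpg_bed <- function(regions, path, chrom = "amplicon") {
  df <- data.frame(chrom = rep(chrom, nrow(regions)),
                   start = regions$start,
                   end = regions$end,
                   name = sprintf("CpG_rich_%d", seq_len(nrow(regions))),
                   score = round(regions$obs_exp * 100),
                   strand = rep("+", nrow(regions)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
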