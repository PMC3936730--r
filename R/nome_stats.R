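#' Per-site inaccessibility statistics
#'
#' At each GCH site, the percentage of inaccessibility is
#' `100 * n_inaccessible / (n_inaccessible + n_accessible)`: the number of
#' molecules the GpC methyltransferase could not methylate over the total
#' number of molecules with a determinate call at that site. A RETAINED
#' call at a GCH site means the enzyme reached (methylated) the site, i.e.
#' the molecule was accessible there; CONVERTED means inaccessible.
#' Ambiguous molecules are excluded from the denominator; a site where all
#' molecules are ambiguous is flagged undefined rather than reported as 0.
#'
#' @param x a `clone_calls` object (usually after [filter_clones()]).
#' @param sites GCH positions to evaluate (default: all GCH sites).
#' @return data.frame of class `site_stats`: columns `pos`,
#'   `n_inaccessible`, `n_accessible`, `n_ambiguous`,
#'   `percent_inaccessible` (NA when undefined), `defined`.
#' @export
site_stats <- function(x, sites = NULL) {
  stopifnot(inherits(x, "clone_calls"))
  gch <- x$sites[x$site_class == "GCH"]
  sites <- sites %||% gch
  if (!all(sites %in% gch)) {
    stop("site(s) not in the GCH registry: ",
         paste(setdiff(sites, gch), collapse = ", "), call. = FALSE)
  }
  idx <- match(sites, x$sites)
  m <- x$calls[, idx, drop = FALSE]
  n_in <- colSums(m == "CONVERTED")
  n_ac <- colSums(m == "RETAINED")
  n_am <- colSums(m == "AMBIGUOUS")
  pct <- ifelse(n_in + n_ac > 0, 100 * n_in / (n_in + n_ac), NA_real_)
  out <- data.frame(pos = sites, n_inaccessible = unname(n_in),
                    n_accessible = unname(n_ac),
                    n_ambiguous = unname(n_am),
                    percent_inaccessible = unname(pct),
                    defined = unname(n_in + n_ac > 0))
  class(out) <- c("site_stats", "data.frame")
  out
}

#' @rdname site_stats
#' @param site a single GCH position.
#' @export
percent_inaccessible <- function(x, site) {
  st <- site_stats(x, sites = site)
  if (!st$defined) {
    warning("all molecules ambiguous at site ", site,
            "; percentage undefined", call. = FALSE)
  }
  st
}

#' 100-bp windowed inaccessibility profile
#'
#' Per-site inaccessibility percentages are averaged over fixed-width
#' windows tiling the amplicon (unweighted mean over the GCH sites whose
#' position falls in each window). Windows containing no defined site are
#' flagged empty, never interpolated.
#'
#' @param stats a `site_stats` data.frame.
#' @param window window width in bp (default 100).
#' @param region_length amplicon length; defaults to covering the last
#'   site.
#' @return data.frame of class `window_profile`: `start`, `end`, `center`,
#'   `mean_percent_inaccessible`, `n_sites`, `empty`.
#' @export
window_profile <- function(stats, window = 100, region_length = NULL) {
  stopifnot(inherits(stats, "data.frame"), nrow(stats) >= 1L)
  window <- check_count(window, "window")
  L <- region_length %||% (max(stats$pos) + 1L)
  starts <- seq.int(0L, L - 1L, by = window)
  rows <- lapply(starts, function(s0) {
    in_w <- stats$pos >= s0 & stats$pos < s0 + window & stats$defined
    vals <- stats$percent_inaccessible[in_w]
    data.frame(start = s0, end = s0 + window, center = s0 + window / 2,
               mean_percent_inaccessible =
                 if (length(vals)) mean(vals) else NA_real_,
               n_sites = sum(in_w), empty = length(vals) == 0L)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("window_profile", "data.frame")
  out
}

#' Select one GCH test site per stride window
#'
#' Within each `stride`-bp window that contains at least one GCH site,
#' returns the site nearest the window center (ties broken toward the
#' smaller coordinate); windows without sites are skipped. Used to pick
#' the "one GpC site every 100 bp" tested between conditions.
#'
#' @param registry a `site_registry`, `amplicon_reference` or
#'   `clone_calls` object.
#' @param stride window width in bp (default 100).
#' @return Integer vector of selected GCH positions.
#' @export
select_test_sites <- function(registry, stride = 100) {
  stride <- check_count(stride, "stride")
  gch <- if (inherits(registry, "site_registry")) registry$gch
         else if (inherits(registry, "amplicon_reference")) registry$sites$gch
         else if (inherits(registry, "clone_calls")) {
           registry$sites[registry$site_class == "GCH"]
         } else stop("unsupported registry object", call. = FALSE)
  if (length(gch) == 0L) return(integer(0))
  gch <- sort(gch)
  win <- gch %/% stride
  out <- vapply(split(gch, win), function(s) {
    center <- (s[1] %/% stride) * stride + stride / 2
    d <- abs(s - center)
    s[which(d == min(d))[1]]          # tie -> smaller coordinate
  }, integer(1))
  unname(out)
}

#' Pearson chi-square on a 2x2 count table
#'
#' Rows are conditions, columns accessible/inaccessible counts; df = 1,
#' continuity correction off by default. A zero margin makes the
#' statistic undefined and is flagged in `note`.
#'
#' @param tab 2x2 count matrix.
#' @param correct apply the continuity correction.
#' @return List with `statistic`, `p_value`, `note`.
#' @export
chisq_2x2 <- function(tab, correct = FALSE) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                note = "zero margin"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       note = "")
}

#' Mid-p exact test for a 2x2 table
#'
#' Conditional exact test on the hypergeometric distribution of the
#' top-left cell given the margins, two-sided by summing outcome
#' probabilities not exceeding that of the observed table. The mid-p
#' variant (default) counts only half the probability of the outcomes
#' exactly as probable as the observed one, which restores a
#' near-nominal type-I error at clone-level sample sizes where the plain
#' conditional test is markedly conservative.
#'
#' @param tab 2x2 count matrix.
#' @param midp use the mid-p correction (default TRUE); FALSE gives the
#'   standard conditional two-sided exact p-value.
#' @return List with `p_value` and `note`.
#' @export
exact_test_2x2 <- function(tab, midp = TRUE) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p_value = NA_real_, note = "zero margin"))
  }
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  xs <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  eps <- 1e-9 * p_obs
  smaller <- probs < p_obs - eps
  equal <- abs(probs - p_obs) <= eps
  p <- if (midp) sum(probs[smaller]) + 0.5 * sum(probs[equal])
       else sum(probs[smaller | equal])
  list(p_value = min(1, p), note = "")
}

#' Compare accessibility between two conditions site by site
#'
#' For each test site (by default one GCH site per 100 bp, chosen by
#' [select_test_sites()]), builds the 2x2 table of condition by
#' accessible/inaccessible counts (ambiguous molecules excluded) and tests
#' independence with a Pearson chi-square (df = 1, no continuity
#' correction by default) or, with `exact = TRUE`, the mid-p exact test
#' suited to small clone counts. P-values are reported per site without
#' multiple-testing adjustment unless `p_adjust` is set.
#'
#' @param xa,xb `clone_calls` objects for the two conditions sharing the
#'   site registry.
#' @param sites test sites (default [select_test_sites()] at `stride`).
#' @param stride stride for default site selection.
#' @param exact use the exact (mid-p) test instead of chi-square.
#' @param midp mid-p correction for the exact test.
#' @param correct continuity correction for the chi-square.
#' @param p_adjust multiple-testing adjustment method (see
#'   [stats::p.adjust()]; default `"none"`).
#' @return data.frame of class `condition_comparison` with per-site counts
#'   (`a_acc`, `a_inacc`, `b_acc`, `b_inacc`), `statistic` (NA for the
#'   exact test), `df`, `p_value`, `method`, `note`.
#' @export
compare_conditions <- function(xa, xb, sites = NULL, stride = 100,
                               exact = FALSE, midp = TRUE, correct = FALSE,
                               p_adjust = "none") {
  stopifnot(inherits(xa, "clone_calls"), inherits(xb, "clone_calls"))
  if (!identical(xa$sites, xb$sites) ||
      !identical(xa$site_class, xb$site_class)) {
    stop("the two call matrices do not share a site registry",
         call. = FALSE)
  }
  sites <- sites %||% select_test_sites(xa, stride = stride)
  sa <- site_stats(xa, sites); sb <- site_stats(xb, sites)
  rows <- lapply(seq_along(sites), function(i) {
    tab <- matrix(c(sa$n_accessible[i], sa$n_inaccessible[i],
                    sb$n_accessible[i], sb$n_inaccessible[i]),
                  2, 2, byrow = TRUE,
                  dimnames = list(c("A", "B"),
                                  c("accessible", "inaccessible")))
    if (exact) {
      r <- exact_test_2x2(tab, midp = midp)
      data.frame(pos = sites[i],
                 a_acc = tab[1, 1], a_inacc = tab[1, 2],
                 b_acc = tab[2, 1], b_inacc = tab[2, 2],
                 statistic = NA_real_, df = NA_integer_,
                 p_value = r$p_value,
                 method = if (midp) "exact_midp" else "exact",
                 note = r$note, stringsAsFactors = FALSE)
    } else {
      r <- chisq_2x2(tab, correct = correct)
      data.frame(pos = sites[i],
                 a_acc = tab[1, 1], a_inacc = tab[1, 2],
                 b_acc = tab[2, 1], b_inacc = tab[2, 2],
                 statistic = r$statistic, df = 1L, p_value = r$p_value,
                 method = "chisq", note = r$note, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (p_adjust != "none") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  class(out) <- c("condition_comparison", "data.frame")
  out
}

# shared run caller: maximal runs of `target` calls along the GCH sites of
# one clone; AMBIGUOUS does not break a run but never extends its ends.
runs_one_clone <- function(calls, pos, target) {
  det <- calls != "AMBIGUOUS"
  p <- pos[det]; c0 <- calls[det]
  if (length(c0) == 0L) return(NULL)
  r <- rle(c0 == target)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0L) return(NULL)
  data.frame(start = p[starts[keep]], end = p[ends[keep]],
             n_sites = r$lengths[keep])
}

#' Call per-molecule inaccessible footprints
#'
#' On each clone, maximal runs of consecutive inaccessible GCH sites are
#' reported as footprints (ambiguous sites do not break a run but do not
#' extend its ends). The span is measured between the outermost
#' inaccessible sites, inclusive; footprints with span at least `min_span`
#' are classed `NUCLEOSOME_SIZED` (large enough to accommodate a
#' nucleosome, ~150 bp), smaller ones `SUBTHRESHOLD`.
#'
#' @param x a filtered `clone_calls` object.
#' @param min_span minimum span in bp for the nucleosome-sized class
#'   (default 150).
#' @return data.frame of class `footprint_set`: `clone`, `start`, `end`
#'   (0-based inclusive site positions), `span`, `n_sites`, `class`.
#' @export
call_footprints <- function(x, min_span = 150) {
  footprint_runs(x, target = "CONVERTED", min_span = min_span,
                 big = "NUCLEOSOME_SIZED")
}

#' Call per-molecule accessible runs (NDR candidates)
#'
#' The polarity mirror of [call_footprints()]: maximal runs of accessible
#' GCH sites per clone; runs spanning at least `min_span` bp (default 147,
#' one nucleosome) are classed `NDR_SIZED`.
#'
#' @param x a filtered `clone_calls` object.
#' @param min_span minimum span in bp for the NDR-sized class (default
#'   147).
#' @return data.frame of class `footprint_set` (see [call_footprints()]).
#' @export
call_open_runs <- function(x, min_span = 147) {
  footprint_runs(x, target = "RETAINED", min_span = min_span,
                 big = "NDR_SIZED")
}

footprint_runs <- function(x, target, min_span, big) {
  stopifnot(inherits(x, "clone_calls"))
  gch_idx <- which(x$site_class == "GCH")
  pos <- x$sites[gch_idx]
  rows <- lapply(rownames(x$calls), function(id) {
    r <- runs_one_clone(x$calls[id, gch_idx], pos, target)
    if (is.null(r)) return(NULL)
    r$clone <- id
    r
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), n_sites = integer(0),
               clone = character(0))
  out$span <- if (nrow(out)) out$end - out$start + 1L else integer(0)
  out$class <- ifelse(out$span >= min_span, big, "SUBTHRESHOLD")
  out <- out[, c("clone", "start", "end", "span", "n_sites", "class")]
  rownames(out) <- NULL
  attr(out, "min_span") <- min_span
  class(out) <- c("footprint_set", "data.frame")
  out
}

#' Write footprints or open runs as BED
#'
#' 0-based half-open intervals; name = clone id, score = span; the class
#' rides in column 7.
#'
#' @param fp a `footprint_set`.
#' @param path output BED path.
#' @param chrom chromosome/sequence name for column 1.
#' @export
write_footprints_bed <- function(fp, path, chrom = "amplicon") {
  df <- data.frame(chrom = rep(chrom, nrow(fp)), start = fp$start,
                   end = fp$end + 1L, name = fp$clone, score = fp$span,
                   strand = rep("+", nrow(fp)), class = fp$class)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Plot-ready bubble-chart structure
#'
#' Per molecule, the ordered GCH site states (filled = accessible to the
#' enzyme, open = inaccessible, missing = ambiguous) plus one bar interval
#' per nucleosome-sized footprint, matching the bubble-chart encoding of
#' single-molecule accessibility figures.
#'
#' @param x a `clone_calls` object.
#' @param footprints a `footprint_set` from [call_footprints()]; computed
#'   with defaults when omitted.
#' @return Object of class `bubble_matrix`: list with `sites`, `clones`,
#'   `states` (character matrix: `filled`/`open`/`missing`), `bars`
#'   (data.frame clone/start/end).
#' @export
bubble_matrix <- function(x, footprints = NULL) {
  stopifnot(inherits(x, "clone_calls"))
  footprints <- footprints %||% call_footprints(x)
  gch_idx <- which(x$site_class == "GCH")
  m <- x$calls[, gch_idx, drop = FALSE]
  states <- ifelse(m == "RETAINED", "filled",
            ifelse(m == "CONVERTED", "open", "missing"))
  colnames(states) <- x$sites[gch_idx]
  bars <- footprints[footprints$class != "SUBTHRESHOLD",
                     c("clone", "start", "end"), drop = FALSE]
  rownames(bars) <- NULL
  structure(list(sites = x$sites[gch_idx], clones = rownames(m),
                 states = states, bars = bars),
            class = "bubble_matrix")
}

#' Serialize / restore a bubble matrix (JSON)
#' @param b a `bubble_matrix`.
#' @export
bubble_to_json <- function(b) {
  jsonlite::toJSON(list(sites = b$sites, clones = b$clones,
                        states = apply(b$states, 1, paste, collapse = ","),
                        bars = b$bars),
                   auto_unbox = FALSE, digits = NA)
}

#' @rdname bubble_to_json
#' @param json JSON produced by [bubble_to_json()].
#' @export
bubble_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  states <- do.call(rbind, strsplit(x$states, ",", fixed = TRUE))
  rownames(states) <- x$clones
  colnames(states) <- x$sites
  bars <- as.data.frame(x$bars)
  if (nrow(bars) == 0L) {
    bars <- data.frame(clone = character(0), start = integer(0),
                       end = integer(0))
  }
  structure(list(sites = as.integer(x$sites), clones = x$clones,
                 states = states, bars = bars),
            class = "bubble_matrix")
}

#' Write site statistics / window profiles / comparisons as TSV
#' @param x a data.frame produced by this module.
#' @param path output TSV path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
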