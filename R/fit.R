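#' Fit a single-molecule accessibility profile from bisulfite clones
#'
#' The high-level entry point of the package: aligns bisulfite clone
#' sequences to the amplicon reference, calls every cytosine context,
#' applies clone QC, and derives the accessibility summaries of a
#' clone-based NOMe-seq experiment — per-GCH-site percent inaccessibility,
#' the 100-bp windowed profile, per-molecule nucleosome-sized footprints
#' and accessible (NDR-candidate) runs, and the endogenous CpG methylation
#' map.
#'
#' @param clones named character vector of clone sequences, or a path to
#'   a clone FASTA file.
#' @param reference an [amplicon_reference()] or path to a reference
#'   FASTA.
#' @param condition condition label.
#' @param min_conversion,max_ambiguous clone QC thresholds
#'   (see [filter_clones()]).
#' @param window averaging window for the profile (bp).
#' @param min_span minimum footprint span for the nucleosome-sized class
#'   (bp).
#' @param ndr_min_span minimum accessible-run span for the NDR-sized
#'   class (bp).
#' @param ... passed to [align_clone()].
#' @return Object of class `nome_fit` with components `calls` (filtered
#'   `clone_calls`), `site_stats`, `profile`, `footprints`, `open_runs`,
#'   `methylation`, `params`.
#' @examples
#' ref <- make_reference(400, 20, seed = 42)
#' sim <- simulate_clones(ref,
#'   uniform_state_model(list(c(120, 280)), linker_accessibility = 0.9),
#'   noise = perfect_noise(), n_clones = 15, seed = 7)
#' fit <- nome_fit(sim$clones, ref)
#' fit
#' head(coef(fit))
#' @export
nome_fit <- function(clones, reference, condition = "sample",
                     min_conversion = 0.95, max_ambiguous = 0.2,
                     window = 100, min_span = 150, ndr_min_span = 147,
                     ...) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    reference <- read_reference_fasta(reference)
  }
  if (is.character(clones) && length(clones) == 1L &&
      file.exists(clones)) {
    clones <- read_clones_fasta(clones)
  }
  calls <- call_clones(clones, reference, condition = condition, ...)
  if (nrow(calls$calls) == 0L) {
    stop("no clone passed alignment", call. = FALSE)
  }
  calls <- filter_clones(calls, min_conversion = min_conversion,
                         max_ambiguous = max_ambiguous)
  st <- site_stats(calls)
  prof <- window_profile(st, window = window,
                         region_length = nchar(reference$sequence))
  fp <- call_footprints(calls, min_span = min_span)
  op <- call_open_runs(calls, min_span = ndr_min_span)
  meth <- methylation_map(calls)
  structure(list(calls = calls, site_stats = st, profile = prof,
                 footprints = fp, open_runs = op, methylation = meth,
                 reference = reference,
                 params = list(condition = condition,
                               min_conversion = min_conversion,
                               max_ambiguous = max_ambiguous,
                               window = window, min_span = min_span,
                               ndr_min_span = ndr_min_span)),
            class = "nome_fit")
}

#' @export
print.nome_fit <- function(x, ...) {
  cat(sprintf("NOMe-seq fit '%s' on %s: %d clones retained, %d GCH sites\n",
              x$params$condition, x$reference$name, nrow(x$calls$calls),
              sum(x$calls$site_class == "GCH")))
  ok <- x$site_stats$defined
  cat(sprintf("  mean inaccessibility %.1f%% (range %.1f-%.1f%%)\n",
              mean(x$site_stats$percent_inaccessible[ok]),
              min(x$site_stats$percent_inaccessible[ok]),
              max(x$site_stats$percent_inaccessible[ok])))
  nfp <- sum(x$footprints$class == "NUCLEOSOME_SIZED")
  cat(sprintf("  %d nucleosome-sized footprint(s), %d NDR-sized open run(s)\n",
              nfp, sum(x$open_runs$class == "NDR_SIZED")))
  invisible(x)
}

#' @method summary nome_fit
#' @export
summary.nome_fit <- function(object, ...) {
  out <- list(
    condition = object$params$condition,
    n_clones = nrow(object$calls$calls),
    n_rejected = nrow(object$calls$rejected),
    conversion_efficiency =
      stats::median(object$calls$conversion_efficiency, na.rm = TRUE),
    site_stats = object$site_stats,
    profile = object$profile,
    footprint_classes = table(object$footprints$class),
    open_run_classes = table(object$open_runs$class))
  class(out) <- "summary.nome_fit"
  out
}

#' @export
print.summary.nome_fit <- function(x, ...) {
  cat(sprintf("NOMe-seq fit summary ('%s')\n", x$condition))
  cat(sprintf("  clones: %d retained, %d rejected; median conversion %.3f\n",
              x$n_clones, x$n_rejected, x$conversion_efficiency))
  cat("  windowed inaccessibility profile:\n")
  p <- x$profile[!x$profile$empty, ]
  print(data.frame(window = sprintf("[%d,%d)", p$start, p$end),
                   mean_pct = round(p$mean_percent_inaccessible, 1),
                   n_sites = p$n_sites), row.names = FALSE)
  invisible(x)
}

#' @method coef nome_fit
#' @export
coef.nome_fit <- function(object, ...) {
  stats::setNames(object$site_stats$percent_inaccessible,
                  object$site_stats$pos)
}

#' Bubble-chart plot of a NOMe-seq fit
#'
#' One row per molecule; filled circles mark GCH sites accessible to the
#' GpC methyltransferase, open circles inaccessible sites, and horizontal
#' bars the nucleosome-sized inaccessible regions.
#'
#' @param x a `nome_fit`.
#' @param ... passed to [graphics::plot()].
#' @method plot nome_fit
#' @export
plot.nome_fit <- function(x, ...) {
  b <- bubble_matrix(x$calls, x$footprints)
  n <- length(b$clones)
  graphics::plot(NA, xlim = range(b$sites) + c(-5, 5),
                 ylim = c(0.5, n + 0.5),
                 xlab = "position (bp)", ylab = "molecule", yaxt = "n",
                 main = sprintf("%s: single-molecule accessibility",
                                x$params$condition), ...)
  graphics::axis(2, at = seq_len(n), labels = b$clones, las = 2,
                 cex.axis = 0.6)
  for (i in seq_len(n)) {
    y <- n - i + 1
    bars <- b$bars[b$bars$clone == b$clones[i], , drop = FALSE]
    if (nrow(bars)) {
      graphics::rect(bars$start, y - 0.3, bars$end, y + 0.3,
                     col = "pink", border = NA)
    }
    st <- b$states[i, ]
    graphics::points(b$sites, rep(y, length(b$sites)),
                     pch = ifelse(st == "filled", 19,
                           ifelse(st == "open", 1, 4)),
                     cex = 0.8,
                     col = ifelse(st == "missing", "grey", "black"))
  }
  invisible(x)
}
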