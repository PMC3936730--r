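# Minimal deterministic SVG emission for bubble charts and lollipop maps.
# Hand-emitted markup keeps pipeline outputs byte-identical across runs.

svg_header <- function(width, height) {
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    '<rect width="100%" height="100%" fill="white"/>')
}

#' Write a bubble chart as SVG
#'
#' Filled (teal) circles mark sites accessible to the GpC
#' methyltransferase; open circles inaccessible sites; pink bars the
#' nucleosome-sized inaccessible regions; grey crosses ambiguous calls.
#'
#' @param b a [bubble_matrix()].
#' @param path output SVG path.
#' @param scale horizontal pixels per bp.
#' @param row_height vertical pixels per molecule.
#' @export
write_bubble_svg <- function(b, path, scale = 1, row_height = 14) {
  stopifnot(inherits(b, "bubble_matrix"))
  pad <- 20
  xmax <- (max(b$sites) + 10) * scale + 2 * pad
  n <- length(b$clones)
  h <- n * row_height + 2 * pad
  lines <- svg_header(ceiling(xmax), ceiling(h))
  xs <- function(p) pad + p * scale
  for (i in seq_len(n)) {
    y <- pad + (i - 0.5) * row_height
    bars <- b$bars[b$bars$clone == b$clones[i], , drop = FALSE]
    for (j in seq_len(nrow(bars))) {
      lines <- c(lines, sprintf(
        '<rect x="%.1f" y="%.1f" width="%.1f" height="%.1f" fill="pink"/>',
        xs(bars$start[j]), y - row_height * 0.35,
        (bars$end[j] - bars$start[j]) * scale, row_height * 0.7))
    }
    for (k in seq_along(b$sites)) {
      st <- b$states[i, k]
      if (st == "filled") {
        lines <- c(lines, sprintf(
          '<circle cx="%.1f" cy="%.1f" r="4" fill="teal"/>',
          xs(b$sites[k]), y))
      } else if (st == "open") {
        lines <- c(lines, sprintf(
          '<circle cx="%.1f" cy="%.1f" r="4" fill="white" stroke="steelblue"/>',
          xs(b$sites[k]), y))
      } else {
        lines <- c(lines, sprintf(
          '<text x="%.1f" y="%.1f" font-size="8" fill="grey" text-anchor="middle">x</text>',
          xs(b$sites[k]), y + 3))
      }
    }
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}

#' Write a methylation lollipop map as SVG
#'
#' Filled (black) circles are methylated CpG sites, open circles
#' unmethylated, ordered by genomic coordinate; one row per clone.
#'
#' @param l a [lollipop_matrix()].
#' @param path output SVG path.
#' @param scale horizontal pixels per bp.
#' @param row_height vertical pixels per clone.
#' @export
write_lollipop_svg <- function(l, path, scale = 1, row_height = 14) {
  stopifnot(inherits(l, "lollipop_matrix"))
  pad <- 20
  xmax <- (max(l$sites) + 10) * scale + 2 * pad
  n <- length(l$clones)
  h <- n * row_height + 2 * pad
  lines <- svg_header(ceiling(xmax), ceiling(h))
  xs <- function(p) pad + p * scale
  for (i in seq_len(n)) {
    y <- pad + (i - 0.5) * row_height
    lines <- c(lines, sprintf(
      '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="grey"/>',
      xs(min(l$sites)), y, xs(max(l$sites)), y))
    for (k in seq_along(l$sites)) {
      st <- l$states[i, k]
      fill <- if (st == "filled") "black" else "white"
      if (st == "missing") next
      lines <- c(lines, sprintf(
        '<circle cx="%.1f" cy="%.1f" r="4" fill="%s" stroke="black"/>',
        xs(l$sites[k]), y, fill))
    }
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}
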