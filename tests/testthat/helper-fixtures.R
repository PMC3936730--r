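# Shared fixtures: mock call matrices, simulation shortcuts, CLI runner.

# Build a clone_calls object from a compact state matrix.
# `states`: character matrix (clones x sites) with entries "A"/"I"/"N"
# (accessible / inaccessible / ambiguous at GCH sites; at HCG sites "A"
# maps to RETAINED = methylated).
mock_calls <- function(states, pos = NULL, class = "GCH",
                       condition = "sample") {
  states <- as.matrix(states)
  n_sites <- ncol(states)
  pos <- pos %||% (seq_len(n_sites) * 20L - 10L)
  class <- rep(class, length.out = n_sites)
  calls <- matrix(ifelse(states == "A", "RETAINED",
                  ifelse(states == "I", "CONVERTED", "AMBIGUOUS")),
                  nrow(states), n_sites)
  rownames(calls) <- sprintf("clone%03d", seq_len(nrow(states)))
  colnames(calls) <- pos
  scored <- class %in% c("GCH", "HCG")
  amb <- if (any(scored)) rowMeans(calls[, scored, drop = FALSE] ==
                                     "AMBIGUOUS") else
    numeric(nrow(calls))
  structure(list(calls = calls, sites = as.integer(pos),
                 site_class = class,
                 conversion_efficiency =
                   stats::setNames(rep(1, nrow(calls)), rownames(calls)),
                 mismatch_rate =
                   stats::setNames(rep(0, nrow(calls)), rownames(calls)),
                 ambiguous_frac = amb,
                 rejected = data.frame(clone = character(0),
                                       reason = character(0)),
                 condition = condition, reference_name = "mock"),
            class = "clone_calls")
}

# counts -> one-site call matrix
mock_counts <- function(n_accessible, n_inaccessible, n_ambiguous = 0,
                        pos = 50L, class = "GCH") {
  mock_calls(matrix(rep(c("A", "I", "N"),
                        c(n_accessible, n_inaccessible, n_ambiguous)),
                    ncol = 1),
             pos = pos, class = class)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Run the installed CLI in a child Rscript; returns status and output.
run_cli <- function(...) {
  cli <- system.file("cli", "nomeclone.R", package = "nomeclone")
  stopifnot(nzchar(cli))
  rlibs <- paste(.libPaths(), collapse = .Platform$path.sep)
  out <- suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"), c(shQuote(cli), c(...)),
    stdout = TRUE, stderr = TRUE,
    env = c(paste0("R_LIBS=", rlibs), "R_TESTS=")))
  list(status = attr(out, "status") %||% 0L,
       output = paste(out, collapse = "\n"))
}
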