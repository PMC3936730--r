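#' Amplicon reference sequence
#'
#' Container for a PCR-amplicon reference analysed at single-molecule
#' resolution. Coordinates are 0-based half-open throughout the package;
#' `genomic_offset` places position 0 relative to an anchor (typically the
#' TSS) so display labels can be rendered in signed-kb style (e.g.
#' `"-9.9 kb"`).
#'
#' @param name identifier of the amplicon.
#' @param sequence uppercase DNA string over `A`, `C`, `G`, `T`.
#' @param genomic_offset signed bp offset of position 0 relative to the
#'   anchor.
#' @return An object of class `amplicon_reference` with the cytosine-context
#'   registry filled in by [classify_sites()].
#' @export
amplicon_reference <- function(name, sequence, genomic_offset = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty reference sequence", call. = FALSE)
  bad <- regexpr("[^ACGT]", sequence)
  if (bad > 0) {
    stop(sprintf("invalid character '%s' at position %d (0-based) of '%s'",
                 substr(sequence, bad, bad), bad - 1L, name), call. = FALSE)
  }
  ref <- structure(
    list(name = name, sequence = sequence,
         genomic_offset = as.numeric(genomic_offset), sites = NULL),
    class = "amplicon_reference")
  ref$sites <- classify_sites(ref)
  ref
}

#' @export
print.amplicon_reference <- function(x, ...) {
  s <- x$sites
  cat(sprintf("Amplicon reference '%s': %d bp (offset %+d bp)\n",
              x$name, nchar(x$sequence), as.integer(x$genomic_offset)))
  cat(sprintf("  sites: %d GCH, %d HCG, %d GCG, %d CH\n",
              length(s$gch), length(s$hcg), length(s$gcg), length(s$ch)))
  invisible(x)
}

#' Classify cytosine contexts of a reference
#'
#' Every cytosine of the reference is assigned to exactly one of four
#' disjoint context classes (positions are 0-based indices of the C itself):
#'
#' * `gch` — `GpC` not followed by `G`: reporter of exogenous GpC
#'   methyltransferase accessibility;
#' * `hcg` — `CpG` not preceded by `G`: reporter of endogenous CpG
#'   methylation;
#' * `gcg` — `G.C.G`, where the two signals are confounded (excluded from
#'   analysis as ambiguous);
#' * `ch` — all remaining cytosines, used as bisulfite-conversion controls.
#'
#' @param reference an [amplicon_reference()] or a plain DNA string.
#' @return A `site_registry`: list of integer vectors `gch`, `hcg`, `gcg`,
#'   `ch` partitioning all cytosine positions.
#' @export
classify_sites <- function(reference) {
  seq <- if (inherits(reference, "amplicon_reference")) reference$sequence
         else toupper(reference)
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0) {
    stop(sprintf("invalid character '%s' at position %d (0-based)",
                 substr(seq, bad, bad), bad - 1L), call. = FALSE)
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  cpos <- which(ch == "C")                   # 1-based
  prevG <- cpos > 1L & ch[pmax(cpos - 1L, 1L)] == "G"
  nextG <- cpos < n & ch[pmin(cpos + 1L, n)] == "G"
  registry <- structure(list(
    gch = as.integer(cpos[prevG & !nextG] - 1L),
    hcg = as.integer(cpos[!prevG & nextG] - 1L),
    gcg = as.integer(cpos[prevG & nextG] - 1L),
    ch  = as.integer(cpos[!prevG & !nextG] - 1L)),
    class = "site_registry")
  registry
}

#' @export
print.site_registry <- function(x, ...) {
  cat(sprintf("Site registry: %d GCH, %d HCG, %d GCG, %d CH\n",
              length(x$gch), length(x$hcg), length(x$gcg), length(x$ch)))
  invisible(x)
}

# all cytosine positions of a registry, sorted, with class labels
registry_sites <- function(registry) {
  pos <- c(registry$gch, registry$hcg, registry$gcg, registry$ch)
  cls <- rep(c("GCH", "HCG", "GCG", "CH"),
             c(length(registry$gch), length(registry$hcg),
               length(registry$gcg), length(registry$ch)))
  o <- order(pos)
  list(pos = pos[o], class = cls[o])
}

#' Fully bisulfite-convert a reference in silico
#'
#' Returns the sequence with every cytosine converted (`C` to `T`), the
#' alignment target emulating complete conversion of an unmethylated
#' molecule.
#'
#' @param reference an [amplicon_reference()] or DNA string.
#' @return Character string of the same length.
#' @export
convert_reference <- function(reference) {
  seq <- if (inherits(reference, "amplicon_reference")) reference$sequence
         else toupper(reference)
  chartr("C", "T", seq)
}

#' Read an amplicon reference from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @param genomic_offset signed bp offset of position 0 (see
#'   [amplicon_reference()]).
#' @export
read_reference_fasta <- function(path, genomic_offset = 0) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("no sequences in ", path, call. = FALSE)
  amplicon_reference(names(x)[1], as.character(x[[1]]), genomic_offset)
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector of DNA sequences.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read clone sequences from FASTA
#'
#' @param path FASTA file of bisulfite clone sequences.
#' @return Named character vector (one element per clone).
#' @export
read_clones_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("no sequences in ", path, call. = FALSE)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Write a site registry as TSV
#' @param registry a `site_registry`.
#' @param path output TSV.
#' @export
write_site_registry <- function(registry, path) {
  s <- registry_sites(registry)
  utils::write.table(data.frame(position = s$pos, class = s$class),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
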