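#' Chromatin state model for the clone simulator
#'
#' A mixture over per-cell chromatin states. Each state carries a mixing
#' weight, a set of protected (nucleosome/protein-occupied) intervals in
#' reference coordinates, and two accessibility probabilities: one for GpC
#' sites in linker/NDR DNA outside protected intervals and one for GpC
#' sites inside them (enzyme leakage). A mixture with and without a
#' nucleosome-depleted region emulates the situation where an NDR is
#' present in only some of the cells.
#'
#' @param states list of states, each a list with elements `weight`,
#'   `protected_intervals` (list of `c(start, end)` 0-based half-open, may
#'   be empty), `linker_accessibility`, `occluded_accessibility`.
#' @param reference_length amplicon length used to bound-check intervals
#'   (optional).
#' @return Object of class `chromatin_state_model`.
#' @export
chromatin_state_model <- function(states, reference_length = NULL) {
  stopifnot(is.list(states), length(states) >= 1L)
  w <- vapply(states, function(s) as.numeric(s$weight %||% NA_real_), 0)
  if (anyNA(w) || any(w < 0)) stop("state weights must be >= 0", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9) {
    stop("state weights must sum to 1 (within 1e-9)", call. = FALSE)
  }
  states <- lapply(states, function(s) {
    s$linker_accessibility <- check_prob(s$linker_accessibility %||% 1,
                                         "linker_accessibility")
    s$occluded_accessibility <- check_prob(s$occluded_accessibility %||% 0,
                                           "occluded_accessibility")
    s$protected_intervals <- lapply(s$protected_intervals %||% list(),
                                    function(iv) {
      iv <- as.numeric(iv)
      if (length(iv) != 2L || iv[1] < 0 || iv[2] <= iv[1]) {
        stop("protected interval must be c(start, end) with end > start >= 0",
             call. = FALSE)
      }
      if (!is.null(reference_length) && iv[2] > reference_length) {
        stop("protected interval exceeds reference bounds", call. = FALSE)
      }
      iv
    })
    s
  })
  structure(list(states = states), class = "chromatin_state_model")
}

#' Single-state convenience constructor
#'
#' @param protected_intervals list of `c(start, end)` protected intervals.
#' @param linker_accessibility accessibility of GpC sites outside protected
#'   intervals.
#' @param occluded_accessibility leakage accessibility inside protected
#'   intervals.
#' @rdname chromatin_state_model
#' @export
uniform_state_model <- function(protected_intervals = list(),
                                linker_accessibility = 1,
                                occluded_accessibility = 0) {
  chromatin_state_model(list(list(
    weight = 1,
    protected_intervals = protected_intervals,
    linker_accessibility = linker_accessibility,
    occluded_accessibility = occluded_accessibility)))
}

#' Noise model for enzyme treatment, bisulfite conversion and sequencing
#'
#' The two sequential enzyme incubations of the assay are collapsed into a
#' single per-site success probability (`enzyme_efficiency`); clone
#' sampling, enzyme action and conversion are independent Bernoulli events.
#'
#' @param enzyme_efficiency probability that an enzyme-accessible GpC is
#'   methylated.
#' @param bisulfite_conversion_rate probability an unmethylated C reads T.
#' @param inappropriate_conversion_rate probability a methylated C reads T.
#' @param seq_error_rate per-base substitution probability applied last.
#' @param seed default RNG seed for simulations using this model.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(enzyme_efficiency = 0.95,
                        bisulfite_conversion_rate = 0.995,
                        inappropriate_conversion_rate = 0.005,
                        seq_error_rate = 0.001,
                        seed = NULL) {
  structure(list(
    enzyme_efficiency = check_prob(enzyme_efficiency, "enzyme_efficiency"),
    bisulfite_conversion_rate =
      check_prob(bisulfite_conversion_rate, "bisulfite_conversion_rate"),
    inappropriate_conversion_rate =
      check_prob(inappropriate_conversion_rate,
                 "inappropriate_conversion_rate"),
    seq_error_rate = check_prob(seq_error_rate, "seq_error_rate"),
    seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "noise_model")
}

#' Noiseless model (perfect enzyme, complete conversion, no errors)
#' @rdname noise_model
#' @export
perfect_noise <- function(seed = NULL) {
  noise_model(1, 1, 0, 0, seed = seed)
}

#' Construct a synthetic amplicon reference
#'
#' Plans GpC (GCH) sites at a fixed spacing and CpG (HCG) sites inside
#' requested blocks; all other bases are drawn from `{A, T}` so no
#' accidental cytosine contexts arise. CpG positions inside a block are
#' sampled on a 3-bp grid (which keeps each CpG in HCG context); if the
#' requested density exceeds the grid capacity the whole grid is used.
#'
#' @param length amplicon length in bp.
#' @param gpc_spacing distance between planned GpC sites (>= 3 so the
#'   following base can stay A/T).
#' @param cpg_blocks optional data.frame with columns `start`, `end`
#'   (0-based half-open) and `density` (expected CpG dinucleotides per bp).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return An [amplicon_reference()].
#' @export
make_reference <- function(length, gpc_spacing, cpg_blocks = NULL, seed = 1,
                           name = "synthetic_amplicon", genomic_offset = 0) {
  length <- check_count(length, "length")
  gpc_spacing <- check_count(gpc_spacing, "gpc_spacing", min = 2L)
  if (gpc_spacing < 3L) {
    stop("gpc_spacing too small to honour site contexts (minimum 3 bp)",
         call. = FALSE)
  }
  if (!is.null(cpg_blocks)) {
    stopifnot(all(c("start", "end", "density") %in% names(cpg_blocks)))
    if (any(cpg_blocks$start < 0) || any(cpg_blocks$end > length) ||
        any(cpg_blocks$end <= cpg_blocks$start)) {
      stop("cpg block out of reference bounds", call. = FALSE)
    }
    o <- order(cpg_blocks$start)
    cpg_blocks <- cpg_blocks[o, , drop = FALSE]
    if (nrow(cpg_blocks) > 1L &&
        any(cpg_blocks$start[-1] < cpg_blocks$end[-nrow(cpg_blocks)])) {
      stop("overlapping cpg blocks", call. = FALSE)
    }
  }
  with_seed(seed, {
    chars <- sample(c("A", "T"), length, replace = TRUE)
    # planned GpC sites: G at g, C at g+1 (0-based), followed by A/T filler
    gstart <- gpc_spacing %/% 2L
    gpos <- if (gstart <= length - 2L) {
      seq.int(gstart, length - 2L, by = gpc_spacing)
    } else integer(0)
    chars[gpos + 1L] <- "G"
    chars[gpos + 2L] <- "C"
    if (!is.null(cpg_blocks)) {
      for (i in seq_len(nrow(cpg_blocks))) {
        b <- cpg_blocks[i, ]
        n_want <- max(0L, round(b$density * (b$end - b$start)))
        if (n_want == 0L) next
        # candidate C positions on a 3-bp grid, >= 1 from start of sequence,
        # kept clear of planned GpC dinucleotides
        cand <- seq.int(max(b$start, 1L), b$end - 2L, by = 3L)
        if (length(gpos)) {
          keep <- vapply(cand, function(p) all(abs(p - gpos) >= 3L), TRUE)
          cand <- cand[keep]
        }
        if (length(cand) == 0L) next
        sel <- if (n_want >= length(cand)) cand
               else sort(sample(cand, n_want))
        chars[sel + 1L] <- "C"
        chars[sel + 2L] <- "G"
      }
    }
    amplicon_reference(name, paste(chars, collapse = ""), genomic_offset)
  })
}

#' Simulate bisulfite-sequenced clones from a chromatin model
#'
#' Each clone (sequenced molecule) is drawn i.i.d.: a cell state is sampled
#' by weight; every GpC-context cytosine is enzyme-methylated with the
#' state- and noise-dependent probability; every HCG cytosine is
#' endogenously methylated per the methylation profile; bisulfite
#' conversion then reads every unmethylated C as T (with the stated rate)
#' and every methylated C as T with the inappropriate-conversion rate;
#' per-base substitution errors are applied last. Clones model the top
#' (bisulfite-converted sense) strand only.
#'
#' Ground truth is returned as a sidecar table keyed by clone id so that
#' downstream calls can be verified without re-inferring it from sequence.
#'
#' @param reference an [amplicon_reference()].
#' @param model a [chromatin_state_model()].
#' @param meth optional endogenous methylation profile: named numeric
#'   vector of per-site methylation probabilities keyed by HCG position
#'   (character names of 0-based positions), or a single probability
#'   applied to all HCG sites. Default 0 (unmethylated).
#' @param noise a [noise_model()].
#' @param n_clones number of clones; the default of 15 reflects the usual
#'   minimum sequencing depth per amplicon and experiment.
#' @param condition label encoded into clone ids.
#' @param seed RNG seed (defaults to `noise$seed`).
#' @return Object of class `nome_simulation`: list with `clones` (named
#'   character vector), `states` (per-clone state index), `truth`
#'   (data.frame: clone, state, pos, class, protected, accessible,
#'   methylated), and the inputs.
#' @export
simulate_clones <- function(reference, model, meth = 0,
                            noise = perfect_noise(), n_clones = 15,
                            condition = "sim", seed = NULL) {
  stopifnot(inherits(reference, "amplicon_reference"),
            inherits(model, "chromatin_state_model"),
            inherits(noise, "noise_model"))
  n_clones <- check_count(n_clones, "n_clones")
  seed <- seed %||% noise$seed
  reg <- reference$sites
  sites <- registry_sites(reg)
  npos <- length(sites$pos)
  L <- nchar(reference$sequence)
  refchars <- strsplit(reference$sequence, "", fixed = TRUE)[[1]]
  is_gpc <- sites$class %in% c("GCH", "GCG")
  is_hcg <- sites$class == "HCG"

  # per-HCG-site methylation probabilities
  mprob <- rep(0, npos)
  if (length(meth) == 1L && is.null(names(meth))) {
    mprob[is_hcg] <- check_prob(meth, "meth")
  } else {
    if (is.null(names(meth))) stop("meth must be named by HCG position",
                                   call. = FALSE)
    bad <- setdiff(as.integer(names(meth)), sites$pos[is_hcg])
    if (length(bad)) {
      stop("meth profile keyed on non-HCG position(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    idx <- match(as.integer(names(meth)), sites$pos)
    mprob[idx] <- vapply(as.numeric(meth), check_prob, 0, name = "meth")
  }

  with_seed(seed, {
    w <- vapply(model$states, `[[`, 0, "weight")
    state <- sample.int(length(w), n_clones, replace = TRUE, prob = w)

    # per-state protection indicator at each site
    prot_by_state <- vapply(model$states, function(s) {
      p <- rep(FALSE, npos)
      for (iv in s$protected_intervals) {
        p <- p | (sites$pos >= iv[1] & sites$pos < iv[2])
      }
      p
    }, logical(npos))
    prot_by_state <- matrix(prot_by_state, nrow = npos)

    linker <- vapply(model$states, `[[`, 0, "linker_accessibility")
    occl <- vapply(model$states, `[[`, 0, "occluded_accessibility")

    # clones x sites matrices
    protected <- t(prot_by_state)[state, , drop = FALSE]
    p_access <- ifelse(protected, occl[state], linker[state])
    p_access[, !is_gpc] <- 0
    accessible <- matrix(stats::runif(n_clones * npos) < p_access,
                         n_clones, npos)
    enz_meth <- accessible &
      matrix(stats::runif(n_clones * npos) < noise$enzyme_efficiency,
             n_clones, npos)
    endo_meth <- matrix(stats::runif(n_clones * npos) <
                          rep(mprob, each = n_clones), n_clones, npos)
    endo_meth[, !is_hcg] <- FALSE
    methylated <- enz_meth | endo_meth

    u <- matrix(stats::runif(n_clones * npos), n_clones, npos)
    converted <- ifelse(methylated,
                        u < noise$inappropriate_conversion_rate,
                        u < noise$bisulfite_conversion_rate)

    ids <- sprintf("%s_clone%02d", condition, seq_len(n_clones))
    clones <- character(n_clones)
    col1 <- sites$pos + 1L                       # 1-based C positions
    for (k in seq_len(n_clones)) {
      ch <- refchars
      ch[col1[converted[k, ]]] <- "T"
      if (noise$seq_error_rate > 0) {
        err <- which(stats::runif(L) < noise$seq_error_rate)
        if (length(err)) {
          ch[err] <- vapply(ch[err], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1L)
          }, "")
        }
      }
      clones[k] <- paste(ch, collapse = "")
    }
    names(clones) <- ids

    truth <- data.frame(
      clone = rep(ids, each = npos),
      state = rep(state, each = npos),
      pos = rep(sites$pos, n_clones),
      class = rep(sites$class, n_clones),
      protected = ifelse(rep(is_gpc, n_clones), as.vector(t(protected)), NA),
      accessible = ifelse(rep(is_gpc, n_clones), as.vector(t(accessible)), NA),
      methylated = as.vector(t(methylated)),
      stringsAsFactors = FALSE)

    structure(list(clones = clones, states = state, truth = truth,
                   reference = reference, model = model, noise = noise,
                   condition = condition, seed = seed),
              class = "nome_simulation")
  })
}

#' @export
print.nome_simulation <- function(x, ...) {
  cat(sprintf("NOMe-seq simulation '%s': %d clones over %d bp (%d sites)\n",
              x$condition, length(x$clones), nchar(x$reference$sequence),
              length(unique(x$truth$pos))))
  invisible(x)
}

#' Write simulation outputs
#'
#' Writes clone sequences as FASTA (one record per clone; ids encode
#' condition and replicate), ground truth as TSV and the parameters as a
#' plain-text config file.
#'
#' @param sim a `nome_simulation`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "nome_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    reference = file.path(dir, "reference.fasta"),
    clones = file.path(dir, "clones.fasta"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "params.txt"))
  write_fasta(stats::setNames(sim$reference$sequence, sim$reference$name),
              paths["reference"])
  write_fasta(sim$clones, paths["clones"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- c(
    sprintf("condition = %s", sim$condition),
    sprintf("n_clones = %d", length(sim$clones)),
    sprintf("seed = %s", format(sim$seed %||% NA)),
    sprintf("enzyme_efficiency = %g", sim$noise$enzyme_efficiency),
    sprintf("bisulfite_conversion_rate = %g",
            sim$noise$bisulfite_conversion_rate),
    sprintf("inappropriate_conversion_rate = %g",
            sim$noise$inappropriate_conversion_rate),
    sprintf("seq_error_rate = %g", sim$noise$seq_error_rate))
  writeLines(cfg, paths["config"])
  invisible(paths)
}

#' Simulate a qPCR Ct table with known ground truth
#'
#' Ct values follow `Ct = baseline_ct - log2(quantity) + N(0, noise_sd)`.
#' For `INPUT` rows the quantity is the input aliquot fraction of the
#' region's chromatin (total 1); for `CHIP`/`FAIRE` rows it is the
#' simulated recovery fraction; for `RT` rows the relative expression
#' level. With `noise_sd = 0`, [percent_input()] downstream recovers the
#' simulated recovery fraction exactly.
#'
#' @param truth data.frame with columns `region`, `condition`, `assay`,
#'   `quantity` (> 0) giving the simulated recovery/expression per
#'   non-input assay row; optional `position_bp`.
#' @param assay_spec data.frame with columns `region`, `assay`,
#'   `input_fraction`; rows with `assay == "INPUT"` generate the matched
#'   input measurements.
#' @param noise_sd Gaussian Ct noise standard deviation (cycles).
#' @param n_replicates PCR replicates per measurement (default 2,
#'   duplicate reactions).
#' @param baseline_ct Ct of one unit of quantity.
#' @param seed RNG seed.
#' @return data.frame with columns `region`, `position_bp`, `assay`,
#'   `condition`, `replicate`, `ct`, `input_fraction`.
#' @export
simulate_ct_table <- function(truth, assay_spec, noise_sd = 0,
                              n_replicates = 2, baseline_ct = 24,
                              seed = 1) {
  stopifnot(all(c("region", "condition", "assay", "quantity") %in%
                  names(truth)),
            all(c("region", "assay", "input_fraction") %in%
                  names(assay_spec)))
  if (any(truth$quantity <= 0)) {
    stop("simulated quantities must be > 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  conditions <- unique(truth$condition)
  rows <- list()
  for (i in seq_len(nrow(assay_spec))) {
    a <- assay_spec[i, ]
    for (cond in conditions) {
      if (a$assay == "INPUT") {
        q <- a$input_fraction
      } else {
        j <- which(truth$region == a$region & truth$condition == cond &
                     truth$assay == a$assay)
        if (length(j) == 0L) next
        q <- truth$quantity[j[1]]
      }
      pos <- if ("position_bp" %in% names(assay_spec)) a$position_bp
             else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        region = a$region, position_bp = pos, assay = a$assay,
        condition = cond, replicate = seq_len(n_replicates),
        true_ct = baseline_ct - log2(q),
        input_fraction = a$input_fraction, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  with_seed(seed, {
    out$ct <- out$true_ct + stats::rnorm(nrow(out), sd = noise_sd)
  })
  out$true_ct <- NULL
  out[, c("region", "position_bp", "assay", "condition", "replicate",
          "ct", "input_fraction")]
}
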