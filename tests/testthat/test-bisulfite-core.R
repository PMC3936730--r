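test_that("cytosine contexts are classified by definition", {
  r <- classify_sites("TGCAT")
  expect_identical(r$gch, 2L)
  expect_identical(r$hcg, integer(0))
  r <- classify_sites("TACGT")
  expect_identical(r$hcg, 2L)
  r <- classify_sites("AGCGT")
  expect_identical(r$gcg, 2L)
  expect_identical(r$gch, integer(0))
  r <- classify_sites("ACCAT")
  expect_identical(r$ch, c(1L, 2L))
  expect_error(classify_sites("ACGNX"), "position 3")
})

test_that("the four context classes partition all cytosines", {
  set.seed(11)
  for (i in 1:1000) {
    seq <- random_dna(sample(20:120, 1))
    r <- classify_sites(seq)
    all_sites <- sort(c(r$gch, r$hcg, r$gcg, r$ch))
    cpos <- which(strsplit(seq, "")[[1]] == "C") - 1L
    expect_identical(all_sites, cpos)
    expect_equal(length(all_sites),
                 length(r$gch) + length(r$hcg) + length(r$gcg) +
                   length(r$ch))
  }
})

test_that("in-silico conversion replaces every cytosine", {
  expect_identical(convert_reference("ACGT"), "ATGT")
  expect_identical(convert_reference("AGTT"), "AGTT")
  seq <- random_dna(200)
  conv <- convert_reference(seq)
  c_in <- which(strsplit(seq, "")[[1]] == "C")
  changed <- which(strsplit(seq, "")[[1]] != strsplit(conv, "")[[1]])
  expect_identical(changed, c_in)
})

test_that("clone alignment handles degeneracy, rejection and indels", {
  ref <- make_reference(300, 20, seed = 5)
  conv <- convert_reference(ref)

  al <- align_clone(conv, ref)               # fully converted clone
  expect_false(isTRUE(al$rejected != FALSE))
  expect_equal(al$identity, 1)
  expect_false(anyNA(al$map))

  al2 <- align_clone(ref$sequence, ref)      # all cytosines retained
  expect_equal(al2$identity, 1)
  cs <- sort(c(ref$sites$gch, ref$sites$hcg, ref$sites$gcg, ref$sites$ch))
  expect_true(all(al2$map[cs + 1] == "C"))

  # clones far off in length are rejected before alignment
  expect_identical(align_clone(substr(conv, 1, 100), ref)$rejected,
                   "length")
  # random sequence fails the identity threshold
  set.seed(2)
  expect_identical(align_clone(random_dna(300), ref)$rejected, "identity")
})

test_that("a small indel in site-free filler leaves all site calls intact", {
  ref <- make_reference(300, 30, seed = 9)
  sim <- simulate_clones(ref, uniform_state_model(list(c(100, 200))),
                         noise = perfect_noise(), n_clones = 1, seed = 4)
  clone <- unname(sim$clones[1])
  reg <- ref$sites
  sites <- sort(c(reg$gch, reg$hcg, reg$gcg, reg$ch))
  # pick a 2-bp deletion spot at least 5 bp from any site or its G
  gap <- 40
  stopifnot(all(abs(gap - sites) > 5))
  clone_del <- paste0(substr(clone, 1, gap), substr(clone, gap + 3,
                                                    nchar(clone)))
  calls_full <- call_sites(align_clone(clone, ref), reg)
  calls_del <- call_sites(align_clone(clone_del, ref), reg)
  expect_identical(calls_del$calls, calls_full$calls)
})

test_that("site calls are stable under site-free flanking sequence", {
  ref <- make_reference(240, 20, seed = 3)
  sim <- simulate_clones(ref, uniform_state_model(list(c(80, 160))),
                         noise = perfect_noise(), n_clones = 1, seed = 8)
  clone <- unname(sim$clones[1])
  flank <- strrep("AT", 15)
  ref2 <- amplicon_reference("flanked",
                             paste0(flank, ref$sequence, flank))
  clone2 <- paste0(flank, clone, flank)
  c1 <- call_sites(align_clone(clone, ref), ref$sites)
  c2 <- call_sites(align_clone(clone2, ref2), ref2$sites)
  shift <- nchar(flank)
  expect_identical(unname(c2$calls),
                   unname(c1$calls))
  expect_identical(as.integer(names(c2$calls)),
                   as.integer(names(c1$calls)) + shift)
})

test_that("per-clone calls follow base identity and polarity", {
  # reference with GCH sites and 20 CH control cytosines
  seq <- paste0(strrep("ACT", 20), strrep("TTGCAT", 5))
  ref <- amplicon_reference("mix", seq)
  expect_length(ref$sites$ch, 20)
  expect_length(ref$sites$gch, 5)

  # fully accessible, fully converted at CH: C retained at GCH, T at CH
  chars <- strsplit(seq, "")[[1]]
  clone <- chars
  clone[ref$sites$ch + 1] <- "T"
  cs <- call_sites(align_clone(paste(clone, collapse = ""), ref),
                   ref$sites)
  expect_true(all(cs$calls[as.character(ref$sites$gch)] == "RETAINED"))
  expect_true(all(cs$calls[as.character(ref$sites$ch)] == "CONVERTED"))
  expect_equal(cs$conversion_efficiency, 1)

  # fully protected clone: everything converted
  clone2 <- chars
  clone2[sort(c(ref$sites$gch, ref$sites$ch)) + 1] <- "T"
  cs2 <- call_sites(align_clone(paste(clone2, collapse = ""), ref),
                    ref$sites)
  expect_true(all(cs2$calls[as.character(ref$sites$gch)] == "CONVERTED"))

  # one unconverted CH out of 20 -> efficiency 0.95
  clone3 <- clone
  clone3[ref$sites$ch[1] + 1] <- "C"
  cs3 <- call_sites(align_clone(paste(clone3, collapse = ""), ref),
                    ref$sites)
  expect_equal(cs3$conversion_efficiency, 0.95)
})

test_that("GCG sites are always ambiguous", {
  ref <- amplicon_reference("gcg", "TTAGCGATTGCATT")
  expect_identical(ref$sites$gcg, 4L)
  cs <- call_sites(align_clone(ref$sequence, ref), ref$sites)
  expect_identical(unname(cs$calls["4"]), "AMBIGUOUS")
})

test_that("clone QC filters on conversion efficiency with reasons", {
  ref <- amplicon_reference("qc", paste0(strrep("ACT", 20),
                                         strrep("TTGCAT", 5)))
  mkclone <- function(n_unconverted) {
    chars <- strsplit(ref$sequence, "")[[1]]
    conv_at <- ref$sites$ch
    if (n_unconverted > 0) conv_at <- conv_at[-seq_len(n_unconverted)]
    chars[conv_at + 1] <- "T"
    paste(chars, collapse = "")
  }
  clones <- c(good1 = mkclone(0), good2 = mkclone(1),  # eff 1, 0.95
              bad = mkclone(2))                        # eff 0.90
  m <- call_clones(clones, ref)
  f <- filter_clones(m)
  expect_identical(rownames(f$calls), c("good1", "good2"))
  expect_identical(f$qc$reason[f$qc$clone == "bad"], "conversion")

  # all clones perfect: identity
  m2 <- call_clones(clones[1:2], ref)
  f2 <- filter_clones(m2)
  expect_identical(f2$calls, m2$calls)

  # all clones failing: explicit error
  m_bad <- call_clones(clones["bad"], ref)
  expect_error(filter_clones(m_bad), "all clones")
})

test_that("simulated low-conversion clones are exactly the ones removed", {
  ref <- amplicon_reference(
    "qcsim", paste0(strrep("ACT", 30), strrep("TTAGCATT", 6)))
  good <- simulate_clones(ref, uniform_state_model(),
                          noise = noise_model(1, 1, 0, 0),
                          n_clones = 18, condition = "good", seed = 21)
  bad <- simulate_clones(ref, uniform_state_model(),
                         noise = noise_model(1, 0.5, 0, 0),
                         n_clones = 2, condition = "lowconv", seed = 22)
  m <- call_clones(c(good$clones, bad$clones), ref)
  f <- filter_clones(m)
  removed <- f$qc$clone[!f$qc$kept]
  expect_setequal(removed, names(bad$clones))
})

test_that("zero-noise simulation round-trips through align and call", {
  ref <- make_reference(500, 25,
                        cpg_blocks = data.frame(start = 150, end = 300,
                                                density = 0.03),
                        seed = 13)
  model <- chromatin_state_model(list(
    list(weight = 0.5, protected_intervals = list(c(100, 260)),
         linker_accessibility = 1, occluded_accessibility = 0),
    list(weight = 0.5, protected_intervals = list(),
         linker_accessibility = 1, occluded_accessibility = 0)))
  meth <- 1   # all HCG sites methylated
  sim <- simulate_clones(ref, model, meth = meth,
                         noise = perfect_noise(), n_clones = 25, seed = 31)
  m <- call_clones(sim$clones, ref)
  expect_equal(nrow(m$calls), 25)
  truth <- sim$truth
  for (k in rownames(m$calls)) {
    tk <- truth[truth$clone == k, ]
    for (cls in c("GCH", "HCG", "CH")) {
      ti <- tk[tk$class == cls, ]
      if (nrow(ti) == 0) next
      got <- m$calls[k, as.character(ti$pos)]
      want <- ifelse(ti$methylated, "RETAINED", "CONVERTED")
      expect_identical(unname(got), want)
    }
  }
})

test_that("call matrices survive the TSV interchange round trip", {
  ref <- make_reference(400, 20,
                        cpg_blocks = data.frame(start = 100, end = 220,
                                                density = 0.02),
                        seed = 17)
  sim <- simulate_clones(ref, uniform_state_model(list(c(120, 280)),
                                                  linker_accessibility = 0.8),
                         noise = perfect_noise(), n_clones = 12, seed = 5)
  m <- call_clones(sim$clones, ref, condition = "rt")
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_call_matrix(m, path)
  m2 <- read_call_matrix(path)
  expect_identical(m2$calls, m$calls)
  expect_identical(m2$sites, m$sites)
  expect_identical(m2$site_class, m$site_class)
  expect_identical(m2$condition, "rt")
})
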