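test_that("percent inaccessibility follows the counting formula", {
  st <- percent_inaccessible(mock_counts(9, 6), 50)
  expect_equal(st$percent_inaccessible, 40)
  expect_equal(percent_inaccessible(mock_counts(15, 0), 50)$
                 percent_inaccessible, 0)
  expect_equal(percent_inaccessible(mock_counts(0, 15), 50)$
                 percent_inaccessible, 100)

  # ambiguous molecules leave the denominator
  st2 <- percent_inaccessible(mock_counts(6, 6, 3), 50)
  expect_equal(st2$percent_inaccessible, 50)
  expect_equal(st2$n_ambiguous, 3)

  # all-ambiguous site is flagged undefined, not zero
  expect_warning(st3 <- percent_inaccessible(mock_counts(0, 0, 15), 50),
                 "undefined")
  expect_true(is.na(st3$percent_inaccessible))
  expect_false(st3$defined)

  expect_error(site_stats(mock_counts(5, 5), sites = 999), "registry")
})

test_that("counts at every site are conserved and order-invariant", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    k <- sample(3:12, 1)
    states <- matrix(sample(c("A", "I", "N"), n * k, replace = TRUE),
                     n, k)
    m <- mock_calls(states)
    st <- site_stats(m)
    expect_true(all(st$n_accessible + st$n_inaccessible +
                      st$n_ambiguous == n))
    # clone reordering leaves the statistics unchanged
    m2 <- mock_calls(states[sample(n), , drop = FALSE])
    expect_equal(st$percent_inaccessible,
                 site_stats(m2)$percent_inaccessible)
  }
})

test_that("window averaging is an unweighted mean over in-window sites", {
  st <- site_stats(mock_calls(
    rbind(c("I", "I", "I"), c("I", "I", "A"), c("A", "I", "A"),
          c("A", "I", "A"), c("A", "I", "A")),
    pos = c(10, 50, 150)))
  # sites at 10 bp (40%) and 50 bp (100%) share window [0,100)
  prof <- window_profile(st, window = 100, region_length = 300)
  expect_equal(prof$mean_percent_inaccessible[1], 70)
  # single site in a window: window value equals the site value
  expect_equal(prof$mean_percent_inaccessible[2], 20)
  expect_true(prof$empty[3])
  expect_true(is.na(prof$mean_percent_inaccessible[3]))

  # all-zero profile is conserved
  st0 <- site_stats(mock_calls(matrix("A", 4, 3), pos = c(10, 50, 150)))
  prof0 <- window_profile(st0, window = 100, region_length = 200)
  expect_true(all(prof0$mean_percent_inaccessible == 0))
})

test_that("one test site per stride window, nearest the center", {
  reg <- structure(list(gch = c(20L, 60L, 140L), hcg = integer(0),
                        gcg = integer(0), ch = integer(0)),
                   class = "site_registry")
  expect_identical(select_test_sites(reg, 100), c(60L, 140L))
  # one site per window already: identity
  reg2 <- structure(list(gch = c(50L, 150L, 250L), hcg = integer(0),
                         gcg = integer(0), ch = integer(0)),
                    class = "site_registry")
  expect_identical(select_test_sites(reg2, 100), c(50L, 150L, 250L))
  # ties break toward the smaller coordinate
  reg3 <- structure(list(gch = c(40L, 60L), hcg = integer(0),
                         gcg = integer(0), ch = integer(0)),
                    class = "site_registry")
  expect_identical(select_test_sites(reg3, 100), 40L)
  reg4 <- structure(list(gch = integer(0), hcg = integer(0),
                         gcg = integer(0), ch = integer(0)),
                    class = "site_registry")
  expect_identical(select_test_sites(reg4, 100), integer(0))
})

test_that("chi-square comparison matches the hand-computed 2x2", {
  a <- mock_counts(12, 3)
  b <- mock_counts(4, 11)
  cmp <- compare_conditions(a, b, sites = 50)
  # expected counts (8,7,8,7): X^2 = 2*(16/8) + 2*(16/7) = 60/7
  expect_equal(cmp$statistic, 60 / 7, tolerance = 1e-12)
  expect_equal(round(cmp$statistic, 3), 8.571)
  expect_equal(cmp$p_value,
               pchisq(60 / 7, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(cmp$p_value, 4), 0.0034)

  # identical counts: statistic 0, p 1
  cmp0 <- compare_conditions(a, mock_counts(12, 3), sites = 50)
  expect_equal(cmp0$statistic, 0)
  expect_equal(cmp0$p_value, 1)

  # zero margin: undefined, flagged
  cmpz <- compare_conditions(mock_counts(15, 0), mock_counts(15, 0),
                             sites = 50)
  expect_true(is.na(cmpz$statistic))
  expect_identical(cmpz$note, "zero margin")
})

test_that("exact and chi-square engines agree with direct computation", {
  set.seed(7)
  for (i in 1:200) {
    n1 <- sample(1:20, 1); n2 <- sample(1:20, 1)
    a <- sample(0:n1, 1); c <- sample(0:n2, 1)
    tab <- matrix(c(a, n1 - a, c, n2 - c), 2, 2, byrow = TRUE)
    imp <- chisq_2x2(tab)
    orc <- oracle_chisq_2x2(tab)
    expect_equal(imp$statistic, orc$stat, tolerance = 1e-10)
    expect_equal(imp$p_value, orc$p, tolerance = 1e-10)
    if (n1 <= 12 && n2 <= 12) {
      expect_equal(exact_test_2x2(tab, midp = TRUE)$p_value,
                   oracle_exact_2x2(tab, midp = TRUE), tolerance = 1e-9)
      expect_equal(exact_test_2x2(tab, midp = FALSE)$p_value,
                   oracle_exact_2x2(tab, midp = FALSE), tolerance = 1e-9)
    }
  }
})

test_that("footprints follow the run rules and the span threshold", {
  pos <- c(60, seq(100, 260, by = 40), 290)
  clone_fp <- c("A", "I", "I", "I", "I", "I", "A")
  m <- mock_calls(rbind(clone_fp), pos = pos)
  fp <- call_footprints(m)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$start, 100)
  expect_equal(fp$end, 260)
  expect_equal(fp$span, 161)
  expect_identical(fp$class, "NUCLEOSOME_SIZED")

  # span 141 stays subthreshold
  pos2 <- c(60, seq(100, 240, by = 35), 290)
  m2 <- mock_calls(rbind(c("A", "I", "I", "I", "I", "I", "A")),
                   pos = pos2)
  fp2 <- call_footprints(m2)
  expect_equal(fp2$span, 141)
  expect_identical(fp2$class, "SUBTHRESHOLD")

  # fully accessible clone: no footprints
  expect_equal(nrow(call_footprints(mock_calls(matrix("A", 1, 7),
                                               pos = pos))), 0)

  # ambiguous sites bridge a run without extending its ends
  m3 <- mock_calls(rbind(c("A", "I", "N", "I", "A")),
                   pos = c(10, 100, 150, 200, 300))
  fp3 <- call_footprints(m3)
  expect_equal(nrow(fp3), 1)
  expect_equal(c(fp3$start, fp3$end), c(100, 200))
})

test_that("open runs mirror footprints with reversed polarity", {
  pos <- c(60, seq(100, 260, by = 40), 290)
  m <- mock_calls(rbind(c("I", "A", "A", "A", "A", "A", "I")), pos = pos)
  op <- call_open_runs(m)
  expect_equal(c(op$start, op$end, op$span), c(100, 260, 161))
  expect_identical(op$class, "NDR_SIZED")

  # duality: footprints of the flipped matrix equal open runs
  set.seed(9)
  states <- matrix(sample(c("A", "I"), 20 * 12, replace = TRUE), 20, 12)
  flipped <- ifelse(states == "A", "I", "A")
  m1 <- mock_calls(states, pos = seq(10, 230, by = 20))
  m2 <- mock_calls(flipped, pos = seq(10, 230, by = 20))
  op1 <- call_open_runs(m1, min_span = 150)
  fp2 <- call_footprints(m2, min_span = 150)
  expect_equal(op1[, c("clone", "start", "end", "span", "n_sites")],
               fp2[, c("clone", "start", "end", "span", "n_sites")])

  # min_span beyond the amplicon: nothing qualifies as NDR-sized
  opL <- call_open_runs(m, min_span = 1000)
  expect_false(any(opL$class == "NDR_SIZED"))
})

test_that("a simulated NDR is recovered in every molecule", {
  ref <- make_reference(600, 10, seed = 8)
  ndr <- c(200, 400)
  model <- uniform_state_model(list(c(0, 200), c(400, 600)))
  sim <- simulate_clones(ref, model, noise = perfect_noise(),
                         n_clones = 50, seed = 14)
  m <- call_clones(sim$clones, ref)
  op <- call_open_runs(m, min_span = 147)
  big <- op[op$class == "NDR_SIZED", ]
  expect_identical(sort(unique(big$clone)), sort(rownames(m$calls)))
  for (i in seq_len(nrow(big))) {
    ov <- min(big$end[i] + 1, ndr[2]) - max(big$start[i], ndr[1])
    expect_gte(ov, 0.8 * (ndr[2] - ndr[1]))
  }
})

test_that("two-condition simulation recovers accessibility differences", {
  ref <- make_reference(600, 20, seed = 10)
  open <- simulate_clones(ref,
                          uniform_state_model(linker_accessibility = 0.8),
                          noise = perfect_noise(), n_clones = 200,
                          condition = "open", seed = 15)
  shut <- simulate_clones(ref,
                          uniform_state_model(linker_accessibility = 0.2),
                          noise = perfect_noise(), n_clones = 200,
                          condition = "closed", seed = 16)
  mo <- call_clones(open$clones, ref, condition = "open")
  ms <- call_clones(shut$clones, ref, condition = "closed")
  for (x in list(list(m = mo, p = 0.2), list(m = ms, p = 0.8))) {
    st <- site_stats(x$m)
    se <- 100 * sqrt(x$p * (1 - x$p) / 200)
    within <- abs(st$percent_inaccessible - 100 * x$p) <= 3 * se
    expect_gte(mean(within), 0.95)
  }
  cmp <- compare_conditions(mo, ms)
  expect_gte(mean(cmp$p_value < 0.01), 0.9)
})

test_that("bubble structures carry states and bars and round-trip", {
  m <- mock_calls(matrix("A", 2, 3), pos = c(10, 50, 90))
  b <- bubble_matrix(m)
  expect_equal(sum(b$states == "filled"), 6)
  expect_equal(nrow(b$bars), 0)

  pos <- c(60, seq(100, 260, by = 40), 290)
  m2 <- mock_calls(rbind(c("A", "I", "I", "I", "I", "I", "A")),
                   pos = pos)
  b2 <- bubble_matrix(m2)
  expect_equal(nrow(b2$bars), 1)
  expect_equal(c(b2$bars$start, b2$bars$end), c(100, 260))

  b3 <- bubble_from_json(bubble_to_json(b2))
  expect_equal(b3$sites, b2$sites)
  expect_identical(unname(b3$states), unname(b2$states))
  expect_equal(b3$bars$start, b2$bars$start)

  # SVG rendering writes well-formed deterministic markup
  p1 <- tempfile(fileext = ".svg"); p2 <- tempfile(fileext = ".svg")
  on.exit(unlink(c(p1, p2)))
  write_bubble_svg(b2, p1)
  write_bubble_svg(b2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_match(readLines(p1)[1], "<svg")
})
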