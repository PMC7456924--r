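region40 <- coil_region(5, 34)
tpl30 <- build_ideal_template(n_slots = 30)

test_that("thread_dimer places residues at slot k + shift and truncates overhangs", {
  s <- protein_seq("x", strrep("A", 40))
  m0 <- thread_dimer(s, s, region40, tpl30, 0, 0)
  expect_equal(m0$chainA$slot[1], 0L)
  expect_equal(m0$chainA$pos[1], 5L)
  expect_equal(nrow(m0$chainA), 30L)

  m2 <- thread_dimer(s, s, region40, tpl30, 2, 0)
  expect_equal(m2$chainA$slot[1], 2L)
  expect_equal(nrow(m2$chainA), 28L)  # two residues overhang and drop
  expect_equal(nrow(m2$chainB), 30L)
  expect_equal(m2$delta_shift, 2L)

  expect_error(thread_dimer(s, s, region40, tpl30, 29, 0), "degenerate")
})

test_that("identical sequences at shift (s,s) are congruent to (0,0) up to slot relabeling", {
  s <- protein_seq("x", paste0("MAAA", strrep("ALKEAQE", 5), "A"))
  m0 <- thread_dimer(s, s, region40, tpl30, 0, 0)
  m3 <- thread_dimer(s, s, region40, tpl30, 3, 3)
  # residues placed in both models pair to anchors whose mutual distances agree
  common <- intersect(m0$chainA$pos, m3$chainA$pos)
  a0 <- lsukit:::model_anchor_coords(m0, "A")[match(common, m0$chainA$pos), ]
  b0 <- lsukit:::model_anchor_coords(m0, "B")[match(common, m0$chainB$pos), ]
  a3 <- lsukit:::model_anchor_coords(m3, "A")[match(common, m3$chainA$pos), ]
  b3 <- lsukit:::model_anchor_coords(m3, "B")[match(common, m3$chainB$pos), ]
  # cross-chain distance matrices are what scoring sees; they must drift only
  # by the small supercoil non-periodicity over 3 slots
  d0 <- as.matrix(stats::dist(rbind(a0, b0)))
  d3 <- as.matrix(stats::dist(rbind(a3, b3)))
  expect_equal(d0, d3, tolerance = 0.15, ignore_attr = TRUE)
  expect_equal(zipper_score(m0), zipper_score(m3))
})

test_that("zipper_score counts leucine side chains in cross-chain contact", {
  noL <- protein_seq("x", strrep("A", 40))
  polyL <- protein_seq("y", paste0("M", strrep("L", 39)))
  expect_equal(zipper_score(thread_dimer(noL, noL, region40, tpl30)), 0L)
  expect_equal(zipper_score(thread_dimer(noL, polyL, region40, tpl30)), 0L)

  # heptad sequence with L at every a and d position, in register:
  # score must equal the brute-force all-pairs count
  ch <- rep("A", 40)
  ch[5 + which(rep(1:7, 6)[1:30] %in% c(1, 4)) - 1] <- "L"
  hep <- protein_seq("h", paste(ch, collapse = ""))
  m <- thread_dimer(hep, hep, region40, tpl30, 0, 0)
  expect_equal(zipper_score(m), brute_zipper(m))
  expect_gt(zipper_score(m), 0L)
})

test_that("zipper_score equals the brute-force oracle on random models", {
  set.seed(101)
  for (i in 1:25) {
    sA <- random_seq(40, "a")
    sB <- random_seq(40, "b")
    sh <- sample(-5:5, 2)
    m <- thread_dimer(sA, sB, region40, tpl30, sh[1], sh[2])
    expect_equal(zipper_score(m), brute_zipper(m))
  }
})

test_that("scan grid has exactly (2W+1)^2 entries", {
  s <- protein_seq("x", strrep("A", 40))
  expect_equal(n_models(scan_register_shifts(s, s, region40, tpl30, 0)), 1L)
  expect_equal(n_models(scan_register_shifts(s, s, region40, tpl30, 1)), 9L)
  g <- scan_register_shifts(s, s, region40, tpl30, 25)
  expect_equal(n_models(g), 2601L)
  expect_equal(dim(g$score), c(51L, 51L))
  finite <- g$score[is.finite(g$score)]
  expect_true(all(finite >= 0))
  expect_error(scan_register_shifts(s, s, region40, tpl30, -1), "non-negative")
})

test_that("scan scores agree with per-model zipper_score", {
  set.seed(77)
  sA <- random_seq(40, "a"); sB <- random_seq(40, "b")
  g <- scan_register_shifts(sA, sB, region40, tpl30, 3)
  for (sa in -3:3) for (sb in -3:3) {
    expected <- tryCatch(
      zipper_score(thread_dimer(sA, sB, region40, tpl30, sa, sb)),
      error = function(e) -Inf)
    expect_equal(g$score[as.character(sa), as.character(sb)], expected)
  }
})

test_that("select_best equals exhaustive argmax and orders ties deterministically", {
  set.seed(2024)
  for (i in 1:10) {
    sA <- random_seq(40, "a"); sB <- random_seq(40, "b")
    g <- scan_register_shifts(sA, sB, region40, tpl30, 3)
    best <- select_best(g, sA, sB, tpl30)
    oracle <- brute_best_shifts(sA, sB, region40, tpl30, 3)
    expect_equal(attr(best, "best_score"), oracle$score)
    got <- t(vapply(best, function(m) c(m$shiftA, m$shiftB), integer(2)))
    expect_setequal(paste(got[, 1], got[, 2]),
                    paste(oracle$shifts[, 1], oracle$shifts[, 2]))
    # tie ordering: |delta| ascending, then shiftA, then shiftB
    key <- order(abs(got[, 1] - got[, 2]), got[, 1], got[, 2])
    expect_equal(key, seq_len(nrow(got)))
  }
})

test_that("homodimer tie set is symmetric under shift swap", {
  seqs <- make_lsu_like_sequences(seed = 5)
  reg <- coil_region(7, 65)
  tpl <- build_ideal_template(59)
  g <- scan_register_shifts(seqs$LSU1, seqs$LSU1, reg, tpl, 10)
  expect_equal(g$score, t(g$score), ignore_attr = TRUE)
  best <- select_best(g, seqs$LSU1, seqs$LSU1, tpl)
  pairs <- vapply(best, function(m) paste(m$shiftA, m$shiftB), character(1))
  swapped <- vapply(best, function(m) paste(m$shiftB, m$shiftA), character(1))
  expect_setequal(pairs, swapped)
})

test_that("select_best errors on an all-degenerate grid", {
  g <- structure(list(idA = "a", idB = "b",
                      score = matrix(-Inf, 3, 3,
                                     dimnames = list(-1:1, -1:1)),
                      half_width = 1L, cutoff = 8.0,
                      region = region40, min_placed = 7L),
                 class = "shift_grid")
  s <- protein_seq("x", strrep("A", 40))
  expect_error(select_best(g, s, s, tpl30), "degenerate")
})

test_that("replacing a leucine by alanine never increases the score", {
  set.seed(11)
  for (i in 1:10) {
    sA <- random_seq(40, "a"); sB <- random_seq(40, "b")
    leu <- leucine_profile(sA)
    if (!length(leu)) next
    pos <- sample(leu, 1)
    ch <- strsplit(sA$residues, "")[[1]]; ch[pos] <- "A"
    sA2 <- protein_seq("a2", paste(ch, collapse = ""))
    g1 <- scan_register_shifts(sA, sB, region40, tpl30, 3)
    g2 <- scan_register_shifts(sA2, sB, region40, tpl30, 3)
    expect_true(all(g2$score <= g1$score))
  }
})

test_that("scores are invariant to translating region and shifts together", {
  set.seed(42)
  s <- random_seq(45, "t")
  tpl <- build_ideal_template(30)
  rA <- coil_region(8, 32)
  rB <- coil_region(10, 34)  # region translated by +2
  for (shift in -2:2) {
    # translating the region start by +2 and the shift by +2 leaves the
    # residue -> slot map unchanged where no truncation occurs
    mA <- thread_dimer(s, s, rA, tpl, shift + 3, shift + 3)
    mB <- thread_dimer(s, s, rB, tpl, shift + 5, shift + 5)
    commonA <- intersect(mA$chainA$pos, mB$chainA$pos)
    slotsA <- mA$chainA$slot[match(commonA, mA$chainA$pos)]
    slotsB <- mB$chainA$slot[match(commonA, mB$chainA$pos)]
    expect_equal(slotsA, slotsB)
  }
})

test_that("interface energy proxy matches brute-force summation and additivity", {
  # no contacts: opposite template ends
  s <- protein_seq("x", strrep("A", 40))
  m <- thread_dimer(s, s, region40, tpl30)
  expect_equal(interface_energy_proxy(m), 0.0)  # alanine: no scored contacts

  set.seed(9)
  for (i in 1:10) {
    sA <- random_seq(40, "a"); sB <- random_seq(40, "b")
    m <- thread_dimer(sA, sB, region40, tpl30, 0, 0)
    # oracle: direct all-pairs enumeration
    cbA <- lsukit:::model_anchor_coords(m, "A")
    cbB <- lsukit:::model_anchor_coords(m, "B")
    hyd <- c("L", "I", "V", "M", "F"); neg <- c("D", "E"); pos <- c("K", "R")
    e <- 0
    for (a in seq_len(nrow(cbA))) for (b in seq_len(nrow(cbB))) {
      if (sqrt(sum((cbA[a, ] - cbB[b, ])^2)) > 8.0 + 1e-9) next
      ra <- m$chainA$aa[a]; rb <- m$chainB$aa[b]
      if (ra %in% hyd && rb %in% hyd) e <- e - 1
      qa <- (ra %in% pos) - (ra %in% neg)
      qb <- (rb %in% pos) - (rb %in% neg)
      if (qa != 0 && qb != 0) e <- e + ifelse(qa == qb, 0.5, -0.5)
    }
    expect_equal(interface_energy_proxy(m), e)
  }

  # additivity: introducing one new Leu-Leu contact lowers the value by 1
  ch <- rep("A", 40)
  base <- protein_seq("b", paste(ch, collapse = ""))
  ch[20] <- "L"
  withL <- protein_seq("w", paste(ch, collapse = ""))
  m_ll <- thread_dimer(withL, withL, region40, tpl30, 0, 0)
  m_la <- thread_dimer(withL, base, region40, tpl30, 0, 0)
  n_new <- sum(lsukit:::cross_contacts(
    tpl30, m_ll$chainA$slot[m_ll$chainA$aa == "L"],
    m_ll$chainB$slot[m_ll$chainB$aa == "L"], 8.0))
  expect_equal(interface_energy_proxy(m_ll) - interface_energy_proxy(m_la),
               -1 * n_new)
})

test_that("scan_all_pairs covers all 16 ordered combinations", {
  seqs <- make_lsu_like_sequences(seed = 2)
  reg <- coil_region(7, 65)
  tpl <- build_ideal_template(59)
  res <- scan_all_pairs(seqs, reg, tpl, half_width = 5)
  expect_equal(nrow(res), 16L)
  expect_equal(nrow(unique(res[, c("idA", "idB")])), 16L)
  expect_true(all(res$best_score >= 0))
})

test_that("shift grid exports as a readable TSV matrix", {
  s <- protein_seq("x", strrep("A", 40))
  g <- scan_register_shifts(s, s, region40, tpl30, 2)
  f <- tempfile(fileext = ".tsv")
  write_shift_grid(g, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(dim(back), c(5L, 6L))
  expect_equal(back$shiftA, -2:2)
})
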