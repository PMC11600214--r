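test_that("sequence identity uses aligned columns", {
  expect_equal(sequence_identity("ACDEFGHIKL", "ACDEFGHIKL"), 1)
  expect_equal(sequence_identity("ACDEFGHIKL", "ACDEFGHIKV"), 0.9)
})

test_that("multi-state rules accept and reject correctly", {
  # identical structures: rmsd 0, not multi-state
  a <- random_test_structure(60, 1)
  same <- state_pair("same", a, a)
  d0 <- evaluate_ms_pair(same)
  expect_false(d0$is_ms)
  expect_equal(d0$rmsd_nm, 0)

  # 80-residue hinge with a large opening qualifies
  toy <- make_toy_two_state(80, 90, seed = 2)
  expect_gt(toy$known_rmsd, 0.5)
  d1 <- evaluate_ms_pair(toy$pair)
  expect_true(d1$is_ms)
  expect_equal(d1$seq_identity, 1)

  # a 25-residue unmapped stretch fails the gap rule
  m <- toy$pair$residue_map
  gappy <- state_pair("gap", toy$pair$state_a, toy$pair$state_b,
                      m[c(1:20, 46:80), ])
  d2 <- evaluate_ms_pair(gappy)
  expect_false(d2$is_ms)
  expect_true(any(grepl("gap", d2$reasons)))
  expect_equal(d2$longest_gap, 25)
})

test_that("single-state cluster rule needs >5 tight members", {
  st <- random_test_structure(30, 5)
  shorter <- ca_structure("short", substr(st$sequence, 1, 25),
                          st$coords[1:25, ])
  copies <- c(replicate(5, st, simplify = FALSE), list(shorter))
  rep_ <- evaluate_ss_cluster(copies)
  expect_equal(rep_$sequence, shorter$sequence) # shortest member

  expect_null(evaluate_ss_cluster(copies[1:5])) # only 5 members

  # one member perturbed beyond 0.2 nm breaks the cluster
  set.seed(9)
  noisy <- st
  noisy$coords <- st$coords + matrix(rnorm(90, 0, 0.25), 30)
  expect_gt(superpose_rmsd(st, noisy)$rmsd, 0.2)
  expect_null(evaluate_ss_cluster(c(copies[1:5], list(noisy))))
})

test_that("transition categories follow the secondary-structure rules", {
  toy <- make_toy_two_state(80, 90, seed = 3)
  a <- toy$pair$state_a
  b <- toy$pair$state_b
  n <- length(a)

  # six helix<->strand swaps: Category IV (checked before III)
  ssa <- strrep("H", n)
  ssb <- paste0(strrep("E", 6), strrep("H", n - 6))
  a4 <- a; a4$ss <- ssa
  b4 <- b; b4$ss <- ssb
  c4 <- classify_transition(state_pair("iv", a4, b4))
  expect_equal(c4$category, "IV")
  expect_equal(c4$n_helix_sheet_swap, 6)

  # six helix->loop changes: Category III
  ssb3 <- paste0(strrep("C", 6), strrep("H", n - 6))
  b3 <- b; b3$ss <- ssb3
  c3 <- classify_transition(state_pair("iii", a4, b3))
  expect_equal(c3$category, "III")
  expect_equal(c3$n_fold_to_loop, 6)

  # identical ss on a two-domain hinge: rigid-block heuristic gives I
  c1 <- classify_transition(toy$pair)
  expect_equal(c1$category, "I")

  # the same motion with arms below the block size gives II
  small <- make_toy_two_state(40, 90, seed = 3)
  expect_equal(classify_transition(small$pair)$category, "II")

  # purity: repeated calls identical
  expect_identical(classify_transition(toy$pair),
                   classify_transition(toy$pair))

  noss <- state_pair("x", random_test_structure(10, 1),
                     random_test_structure(10, 2))
  expect_error(classify_transition(noss), "ss")
})

test_that("contact frequencies match counting oracles", {
  # two ALA 0.5 nm apart: F(AA) = 1 / (2*2)
  two <- ca_structure("aa", "AA", rbind(c(0, 0, 0), c(0.5, 0, 0)))
  f <- contact_frequency(list(two))
  expect_equal(unname(f$F["AA"]), 0.25)
  expect_equal(sum(f$F), 0.25)

  far <- ca_structure("aa", "AA", rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(sum(contact_frequency(list(far))$F), 0)

  # vectorized result equals the brute-force double loop
  sts <- lapply(1:3, function(s) random_test_structure(25, s + 30))
  f2 <- contact_frequency(sts)
  brute <- Reduce(`+`, lapply(sts, brute_contact_freq)) / 3
  expect_equal(f2$F, brute)

  # invariance under dataset reordering
  expect_equal(contact_frequency(sts[c(3, 1, 2)])$F, f2$F)
})

test_that("frequency ratio has the right fixed points", {
  sts <- lapply(1:2, function(s) random_test_structure(20, s + 50))
  f <- contact_frequency(sts, "MS")
  r <- ms_frequency_ratio(f, f)
  expect_true(all(r[!is.na(r)] == 1))
  expect_true(all(is.na(r[f$F == 0])))

  zero <- contact_frequency(list(
    ca_structure("z", "AA", rbind(c(0, 0, 0), c(3, 0, 0)))), "SS")
  r2 <- ms_frequency_ratio(f, zero)
  expect_true(all(r2[f$F > 0] == 2))

  # hand arithmetic on a constructed pair of tiny datasets
  fa <- contact_frequency(list(
    ca_structure("x", "AC", rbind(c(0, 0, 0), c(0.5, 0, 0)))), "MS")
  fb <- contact_frequency(list(
    ca_structure("y", "AACC",
                 rbind(c(0, 0, 0), c(0.5, 0, 0), c(5, 0, 0),
                       c(10, 0, 0)))), "SS")
  # F_ms(AC) = 1/(1*1) = 1; F_ss(AA) = 1/4, others 0
  expect_equal(unname(ms_frequency_ratio(fa, fb)["AC"]), 2)
  expect_equal(unname(ms_frequency_ratio(fa, fb)["AA"]), 0)
})

test_that("changed-contact frequencies count the 0.5 nm rule", {
  # a 4-residue chain where only the terminal A-E distance changes
  mk <- function(d) ca_structure("p", "AGGE",
                                 rbind(c(0, 0, 0), c(0.38, 0, 0),
                                       c(0.76, 0, 0), c(d, 0, 0)))
  # distance shrinks 1.2 -> 0.6 nm: counted once as a new contact
  pair <- state_pair("p", mk(1.2), mk(0.6))
  f <- changed_contact_frequency(list(pair))
  expect_equal(unname(f$F["AE"]), 1) # N'_AE = 1, N_A = N_E = 1
  # the shrinking terminus also moves 0.5+ nm closer to the G's
  expect_equal(unname(f$F["EG"]), 0.5) # one changed pair / (1 * 2)

  # all changes below 0.5 nm: all-zero stats
  pair0 <- state_pair("p", mk(1.2), mk(0.9))
  expect_equal(sum(changed_contact_frequency(list(pair0))$F), 0)

  # brute-force oracle on a 2-protein dataset
  pairs <- lapply(1:2, function(s) {
    a <- random_test_structure(20, s + 70)
    b <- a
    set.seed(s)
    b$coords <- b$coords + matrix(rnorm(60, 0, 0.35), 20)
    state_pair(paste0("p", s), a, b)
  })
  f2 <- changed_contact_frequency(pairs)
  brute <- setNames(numeric(210), contact_types())
  for (p in pairs) {
    s <- strsplit(p$state_a$sequence, "")[[1]]
    da <- pairwise_ca_distances(p$state_a)
    db <- pairwise_ca_distances(p$state_b)
    nres <- table(s)
    fi <- setNames(numeric(210), contact_types())
    for (i in 1:19) for (j in (i + 1):20) {
      if (abs(db[i, j] - da[i, j]) >= 0.5) {
        tp <- paste(sort(c(s[i], s[j])), collapse = "")
        fi[tp] <- fi[tp] + 1 / (as.numeric(nres[s[i]]) *
                                  as.numeric(nres[s[j]]))
      }
    }
    brute <- brute + fi
  }
  expect_equal(f2$F, brute / 2)
})

test_that("the stats table writes all 210 types", {
  sts <- lapply(1:2, function(s) random_test_structure(15, s + 90))
  f <- contact_frequency(sts, "MS")
  path <- tempfile(fileext = ".tsv")
  df <- write_contact_stats(path, f_ms = f, f_ss = f)
  expect_equal(nrow(df), 210)
  expect_true(file.exists(path))
})
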