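test_that("patristic distances match hand values and the root-path oracle", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  d <- patristic_matrix(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_equal(diag(d), setNames(rep(0, 3), c("A", "B", "C")))

  star <- read_newick(text = "(A:1.5,B:1.5,C:1.5,D:1.5);")
  ds <- patristic_matrix(star)
  expect_true(all(ds[upper.tri(ds)] == 3))

  for (seed in 1:5) {
    tr <- random_tree(10, seed)
    expect_equal(patristic_matrix(tr),
                 oracle_patristic(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-12)
  }
})

test_that("patristic distances satisfy four-point additivity on quartets", {
  tr <- random_tree(12, 77)
  d <- patristic_matrix(tr)
  set.seed(7)
  for (i in 1:20) {
    q <- sample(rownames(d), 4)
    s <- sort(c(d[q[1], q[2]] + d[q[3], q[4]],
                d[q[1], q[3]] + d[q[2], q[4]],
                d[q[1], q[4]] + d[q[2], q[3]]))
    expect_lt(abs(s[2] - s[3]), 1e-9)  # two largest sums equal
  }
})

test_that("MPD and MNTD match hand values and the double-loop oracle", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  d <- patristic_matrix(tr)
  ab <- c(A = 1, B = 1, C = 1)
  expect_equal(unname(mpd_single(ab, d, weighted = FALSE)), 10 / 3)
  expect_equal(unname(mntd_single(ab, d, weighted = FALSE)), 8 / 3)
  # equal abundances: weighted equals unweighted
  expect_equal(unname(mpd_single(ab, d, weighted = TRUE)),
               unname(mpd_single(ab, d, weighted = FALSE)))
  # two-taxon sample: MNTD = MPD = d(A, B)
  ab2 <- c(A = 2, B = 5, C = 0)
  expect_equal(unname(mpd_single(ab2, d)), unname(mntd_single(ab2, d)))
  expect_equal(unname(mpd_single(ab2, d, weighted = FALSE)), 2)

  # weighted case against the oracle on random fixtures
  for (seed in 1:8) {
    tr <- random_tree(9, seed + 10)
    d <- patristic_matrix(tr)
    comm <- random_community(3, tr$tip.label, seed)
    for (s in 1:3) for (w in c(TRUE, FALSE)) {
      expect_equal(unname(mpd_single(comm[s, ], d, w)),
                   unname(oracle_mpd(comm[s, ], d, w)), tolerance = 1e-12)
      expect_equal(unname(mntd_single(comm[s, ], d, w)),
                   unname(oracle_mntd(comm[s, ], d, w)), tolerance = 1e-12)
    }
  }
})

test_that("MNTD never exceeds MPD and both scale with branch lengths", {
  tr <- random_tree(15, 42)
  d <- patristic_matrix(tr)
  comm <- random_community(6, tr$tip.label, 43)
  a <- ses_alpha(comm, d, n_reps = 99, seed = 1)
  expect_true(all(a$mntd_obs <= a$mpd_obs + 1e-12))
  expect_true(all(a$mpd_obs >= 0))

  a2 <- ses_alpha(comm, d * 3.7, n_reps = 99, seed = 1)
  expect_equal(a2$mpd_obs, a$mpd_obs * 3.7, tolerance = 1e-12)
  expect_equal(a2$mntd_obs, a$mntd_obs * 3.7, tolerance = 1e-12)
  expect_equal(a2$nri, a$nri, tolerance = 1e-9)
  expect_equal(a2$nti, a$nti, tolerance = 1e-9)
})

test_that("SES indices are zero when the null is shuffle-invariant", {
  tr <- random_tree(8, 5)
  d <- patristic_matrix(tr)
  # every sample holds the whole pool with equal abundance: shuffles change nothing
  comm <- matrix(1, 3, 8, dimnames = list(paste0("s", 1:3), tr$tip.label))
  a <- ses_alpha(comm, d, n_reps = 99, seed = 2)
  expect_equal(a$nri, rep(0, 3))
  expect_equal(a$nti, rep(0, 3))
  # samples with < 2 taxa give sentinel rows
  comm[1, ] <- 0; comm[1, 1] <- 5
  a2 <- ses_alpha(comm, d, n_reps = 99, seed = 2)
  expect_true(is.na(a2$nti[1]))
  expect_false(anyNA(a2$nti[-1]))
})

test_that("observed MPD/MNTD agree with picante", {
  skip_if_not_installed("picante")
  tr <- random_tree(25, 9)
  d <- patristic_matrix(tr)
  comm <- random_community(8, tr$tip.label, 10)
  a <- ses_alpha(comm, d, n_reps = 99, seed = 3)
  expect_equal(a$mntd_obs, unname(picante::mntd(comm, d, abundance.weighted = TRUE)),
               tolerance = 1e-12)
  # picante's weighted MPD keeps the diagonal in the weight normalization;
  # rescale to compare with the distinct-pair formula
  pm <- picante::mpd(comm, d, abundance.weighted = TRUE)
  w2 <- rowSums((comm / rowSums(comm))^2)
  expect_equal(a$mpd_obs, unname(pm / (1 - w2)), tolerance = 1e-12)
  au <- ses_alpha(comm, d, n_reps = 99, weighted = FALSE, seed = 3)
  expect_equal(au$mpd_obs, unname(picante::mpd(comm, d, abundance.weighted = FALSE)),
               tolerance = 1e-12)
  expect_equal(au$mntd_obs, unname(picante::mntd(comm, d, abundance.weighted = FALSE)),
               tolerance = 1e-12)
})
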