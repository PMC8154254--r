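toggling_trajectory <- function() {
  # H-bond bridge present in frames 1 and 3, broken (stretched to a space
  # jump of 4.5 A) in frame 2; closed-form scores for both routes
  s <- make_bridged_pair(2, 2, "hbond", 2.8)
  on_xyz <- model_xyz(s, 1)
  off_xyz <- on_xyz
  off_xyz[4:6, 1] <- off_xyz[4:6, 1] + 1.7
  coords <- array(c(on_xyz, off_xyz, on_xyz), dim = c(6, 3, 3))
  list(traj = et_trajectory(s, coords),
       ln_on = 4 * log(0.6) + log(0.36),
       ln_off = 4 * log(0.6) + log(0.6) - 1.7 * (4.5 - 1.4))
}

test_that("a constant trajectory yields identical per-frame paths", {
  s <- make_covalent_chain(4)
  traj <- constant_trajectory(s, 5)
  res <- per_frame_paths(traj, 1L, 5L)
  expect_length(res, 5)
  lnk <- vapply(res, `[[`, numeric(1), "ln_k")
  expect_equal(lnk, rep(4 * log(0.6), 5), tolerance = 1e-12)
  static <- best_path(transfer_graph(s), 1L, 5L)
  expect_identical(res[[1]]$atoms, static$atoms)
})

test_that("per-frame H-bond rebuilding tracks a toggling bridge", {
  tg <- toggling_trajectory()
  res <- per_frame_paths(tg$traj, 1L, 6L)
  lnk <- vapply(res, `[[`, numeric(1), "ln_k")
  expect_equal(lnk, c(tg$ln_on, tg$ln_off, tg$ln_on), tolerance = 1e-12)
  kinds <- vapply(res, function(p) p$kind_counts[["hbond"]], integer(1))
  expect_equal(kinds, c(1L, 0L, 1L))
})

test_that("frame subsampling analyzes every k-th frame", {
  tg <- toggling_trajectory()
  res <- per_frame_paths(tg$traj, 1L, 6L, subsample = 2L)
  expect_length(res, 2)
  expect_equal(vapply(res, `[[`, numeric(1), "ln_k"),
               c(tg$ln_on, tg$ln_on), tolerance = 1e-12)
})

test_that("participation fractions and bins follow the frame counts", {
  tg <- toggling_trajectory()
  res <- per_frame_paths(tg$traj, 1L, 6L)
  part <- participation_frequencies(res, n_atoms = 6)
  expect_equal(nrow(part), 6)
  expect_true(all(part$fraction >= 0 & part$fraction <= 1))
  # chain atoms sit on every optimal path; nothing else exists here
  expect_equal(part$fraction, rep(1, 6))
  expect_equal(part$bin, rep(">90%", 6))
})

test_that("participation bin labels are left-open right-closed", {
  mk <- function(f) participation_bin(f)
  expect_equal(mk(1.0), ">90%")
  expect_equal(mk(0.95), ">90%")
  expect_equal(mk(0.90), "80-90%")
  expect_equal(mk(0.75), "65-80%")
  expect_equal(mk(0.10), "<10%")
  expect_equal(mk(0.101), "10-30%")
  expect_equal(mk(0.0), "<10%")
  # exhaustive, non-overlapping over a fine grid
  grid <- seq(0, 1, by = 0.001)
  labs <- participation_bin(grid)
  expect_false(any(is.na(labs)))
  expect_setequal(unique(labs), PARTICIPATION_BINS$label)
})

test_that("an atom on 3 of 4 optimal paths lands in the 65-80% bin", {
  s <- make_covalent_chain(2)
  g <- transfer_graph(s)
  full <- best_path(g, 1L, 3L)
  partial <- best_path(g, 2L, 3L)   # omits atom 1
  part <- participation_frequencies(list(full, full, full, partial),
                                    n_atoms = 3)
  expect_equal(part$fraction[1], 0.75)
  expect_equal(part$bin[1], "65-80%")
})

test_that("ensemble decay summarizes valid frames and excludes sentinels", {
  s <- make_covalent_chain(2)
  g <- transfer_graph(s)
  p1 <- best_path(g, 1L, 3L)
  p1$ln_k <- -10
  p2 <- p1; p2$ln_k <- -12
  lost <- best_path(make_random_graph(4, 0, seed = 1), 1, 4)
  summ <- ensemble_decay(list(p1, p2, lost))
  expect_equal(summ$mean_ln_k, -11)
  expect_equal(summ$best_frame$ln_k, -10)
  expect_equal(summ$best_frame$index, 1)
  expect_equal(summ$worst_frame$ln_k, -12)
  expect_equal(summ$frames_analyzed, 2)
  expect_equal(summ$frames_total, 3)
  single <- ensemble_decay(list(p1))
  expect_equal(single$sd_ln_k, 0)
  expect_error(ensemble_decay(list(lost)), "no frame")
})

test_that("summaries are invariant to frame order", {
  tg <- toggling_trajectory()
  res <- per_frame_paths(tg$traj, 1L, 6L)
  perm <- res[c(3, 1, 2)]
  a <- ensemble_decay(res); b <- ensemble_decay(perm)
  expect_equal(a$mean_ln_k, b$mean_ln_k)
  expect_equal(a$sd_ln_k, b$sd_ln_k)
  pa <- participation_frequencies(res, 6)
  pb <- participation_frequencies(perm, 6)
  expect_equal(pa$fraction, pb$fraction)
})
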