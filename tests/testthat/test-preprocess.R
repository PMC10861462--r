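test_that("volume dropping truncates signal and motion together", {
  s <- toy_scan(V = 10, Tn = 180)
  out <- drop_initial_volumes(s, 10)
  expect_equal(ncol(out$signal), 170)
  expect_equal(nrow(out$motion), 170)
  expect_identical(drop_initial_volumes(s, 0), s)
  s5 <- toy_scan(V = 4, Tn = 5)
  expect_error(drop_initial_volumes(s5, 5), "smaller")
})

test_that("framewise displacement follows the Power convention", {
  Tn <- 6
  m <- matrix(0, Tn, 6)
  tr0 <- compute_fd(m)
  expect_equal(tr0$fd, rep(0, Tn))
  expect_equal(tr0$mean_fd, 0)
  # one translation step of (0.3, 0, 0.4) mm
  m1 <- m; m1[3:Tn, 1] <- 0.3; m1[3:Tn, 3] <- 0.4
  expect_equal(compute_fd(m1)$fd[3], 0.7)
  expect_equal(compute_fd(m1)$fd[4], 0)
  # one rotation step of 0.01 rad at radius 50
  m2 <- m; m2[4:Tn, 5] <- 0.01
  expect_equal(compute_fd(m2, radius_mm = 50)$fd[4], 0.5)
  expect_equal(compute_fd(m2)$fd[1], 0)
  # translation invariance: constant offsets leave FD unchanged
  m3 <- matrix(rnorm(Tn * 6), Tn)
  expect_equal(compute_fd(m3)$fd, compute_fd(m3 + 5)$fd)
  expect_error(compute_fd(matrix(c(NA, rep(0, 11)), 2)), "non-finite")
})

test_that("Friston-24 expansion has the stated structure", {
  m <- matrix(rnorm(60), 10, 6)
  F24 <- friston24(m)
  expect_equal(ncol(F24), 24)
  expect_equal(friston24(matrix(0, 5, 6)), matrix(0, 5, 24))
  mc <- matrix(2, 8, 6)
  Fc <- friston24(mc)
  expect_true(all(Fc[, 1:6] == 2))
  expect_true(all(Fc[1, 13:24] == 0))
  expect_true(all(Fc[-1, 13:18] == 2))
  expect_true(all(Fc[-1, 19:24] == 4))
})

test_that("nuisance regression leaves residuals orthogonal to the design", {
  s <- toy_scan(V = 8, Tn = 50)
  reg <- matrix(rnorm(100), 50, 2)
  out <- regress_nuisance(s, reg)
  des <- cbind(1, seq_len(50) - 25.5, reg)
  ip <- t(out$signal %*% des)
  expect_lt(max(abs(ip)) / (max(abs(out$signal)) * max(abs(des)) * 50), 1e-8)
  # a voxel equal to a regressor is annihilated
  s2 <- s; s2$signal[1, ] <- reg[, 1]
  out2 <- regress_nuisance(s2, reg)
  expect_lt(max(abs(out2$signal[1, ])), 1e-10)
  # residual variance matches the explicit normal-equations solution
  x <- rnorm(50)
  y <- 2 * x + rnorm(50, sd = 0.1)
  s3 <- toy_scan(V = 1, Tn = 50); s3$signal[1, ] <- y
  out3 <- regress_nuisance(s3, cbind(x), include_trend = FALSE)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(as.numeric(out3$signal), as.numeric(y - X %*% beta),
               tolerance = 1e-10)
  expect_warning(regress_nuisance(s, cbind(reg, reg[, 1])), "collinear")
})

test_that("band-pass keeps the passband and kills stopband and DC", {
  Tn <- 200; tr <- 2
  t_sec <- (seq_len(Tn) - 1) * tr
  amp_ratio <- function(f) {
    s <- toy_scan(V = 1, Tn = Tn, tr = tr)
    s$signal[1, ] <- sin(2 * pi * f * t_sec)
    out <- bandpass(s)
    ft_in <- abs(fft(sin(2 * pi * f * t_sec)))
    ft_out <- abs(fft(out$signal[1, ]))
    bin <- which.max(ft_in[2:(Tn / 2)]) + 1
    ft_out[bin] / ft_in[bin]
  }
  expect_gte(amp_ratio(0.05), 0.95)
  expect_lte(amp_ratio(0.2), 0.10)
  s <- toy_scan(V = 1, Tn = Tn, tr = tr)
  s$signal[1, ] <- 7
  expect_lt(max(abs(bandpass(s)$signal)), 1e-6)
  expect_error(bandpass(toy_scan(Tn = 50), low_hz = 0.01, high_hz = 0.3),
               "Nyquist")
})

test_that("scrubbing interpolates flagged frames and respects boundaries", {
  s <- toy_scan(V = 3, Tn = 20)
  fd <- rep(0, 20)
  tr0 <- structure(list(fd = fd, mean_fd = 0), class = "motion_trace")
  expect_identical(scrub_interpolate(s, tr0), s)
  # linear ramp: interior interpolation is exact
  s$signal[1, ] <- seq_len(20)
  fd[10] <- 1
  tr1 <- structure(list(fd = fd, mean_fd = mean(fd)), class = "motion_trace")
  out <- scrub_interpolate(s, tr1)
  expect_equal(out$signal[1, 10], 10, tolerance = 1e-10)
  expect_equal(out$signal[1, -10], s$signal[1, -10])
  # flagged first and last frames take the nearest clean value
  fd2 <- rep(0, 20); fd2[c(1, 20)] <- 1
  tr2 <- structure(list(fd = fd2, mean_fd = mean(fd2)), class = "motion_trace")
  out2 <- scrub_interpolate(s, tr2)
  expect_equal(out2$signal[, 1], s$signal[, 2])
  expect_equal(out2$signal[, 20], s$signal[, 19])
  # too few clean frames errors
  fd3 <- rep(1, 20); fd3[1:3] <- 0
  tr3 <- structure(list(fd = fd3, mean_fd = mean(fd3)), class = "motion_trace")
  expect_error(scrub_interpolate(s, tr3), "clean frames")
})

test_that("preprocess_scan applies drop, regression, filtering, scrubbing in order", {
  co <- small_cohort(seed = 51, n_per_group = 2, V = 30, K = 3, T_raw = 50)
  s <- co$scans[[1]]
  out <- preprocess_scan(s, n_drop = 5)
  manual <- drop_initial_volumes(s, 5)
  manual <- regress_nuisance(manual, friston24(manual$motion))
  manual <- bandpass(manual)
  trace <- compute_fd(manual$motion)
  manual <- scrub_interpolate(manual, trace)
  expect_equal(out$signal, manual$signal, tolerance = 1e-12)
  expect_equal(out$mean_fd, trace$mean_fd)
  expect_equal(ncol(out$signal), 45)
  # the two linear stages do not commute, so the fixed order is material
  alt <- drop_initial_volumes(s, 5)
  alt <- bandpass(alt)
  alt <- regress_nuisance(alt, friston24(alt$motion))
  expect_gt(max(abs(alt$signal - manual$signal)), 0)
})

test_that("subject exclusion applies both motion rules", {
  mk <- function(id, fd_level, max_trans) {
    s <- toy_scan(V = 5, Tn = 30, seed = nchar(id))
    s$subject_id <- id
    s$motion[] <- 0
    s$motion[, 1] <- seq(0, max_trans, length.out = 30)
    # add FD via alternating jumps on translation y
    s$motion[seq(2, 30, 2), 2] <- fd_level
    s
  }
  ok1 <- mk("ok1", 0.05, 0.5); ok2 <- mk("ok2", 0.05, 0.5)
  high_fd <- mk("bad-fd", 0.6, 0.5)       # alternating 0.6 mm jumps
  big_move <- mk("bad-move", 0.05, 4)     # 4 mm > one 3 mm voxel
  res <- exclude_subjects(list(ok1, ok2, high_fd, big_move))
  expect_equal(vapply(res$scans, `[[`, "", "subject_id"), c("ok1", "ok2"))
  expect_setequal(res$report$subject_id, c("bad-fd", "bad-move"))
  expect_match(res$report$reason[res$report$subject_id == "bad-fd"], "FD")
  expect_match(res$report$reason[res$report$subject_id == "bad-move"],
               "translation")
  expect_error(exclude_subjects(list(high_fd)), "all subjects excluded")
})
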