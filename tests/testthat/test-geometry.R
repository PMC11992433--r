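# End-to-end distance, plane/circle fitting, curvature, flexibility,
# RMSD/RMSF, H-bonds, contacts, block errors and Daura clustering

make_two_point_chainB <- function(dist_nm, n_frames = 4) {
  # 6-residue chain B whose C-alpha 3 and 4 are dist_nm apart
  atoms <- data.frame(chain = "B", resno = 1:6, resid = "GLY",
                      elety = "CA", stringsAsFactors = FALSE)
  base <- cbind(c(0, 0, 0, 0, 0, 0), 0,
                c(-2, -1, 0, dist_nm, dist_nm + 1, dist_nm + 2))
  toy_traj(replicate(n_frames, base, simplify = FALSE), atoms)
}

test_that("end_to_end measures the third-to-third C-alpha distance", {
  tr <- make_two_point_chainB(10)
  ee <- end_to_end(tr)
  expect_equal(ee$mean, 10)
  expect_equal(ee$sd, 0)
  expect_equal(ee$series, rep(10, 4))

  # analytic value on a straight synthetic trimer
  st <- make_straight_trimer(generator_config(noise_sigma = 0,
                                              n_frames = 2, seed = 1))
  expect_equal(end_to_end(st)$mean, 0.286 * 34, tolerance = 1e-9)

  # jittered ensemble equals brute-force per-frame recomputation
  jt <- make_straight_trimer(generator_config(noise_sigma = 0.02,
                                              n_frames = 25, seed = 2))
  ca <- select_atoms(jt, chain = "B", elety = "CA")
  ca <- ca[order(jt$atoms$resno[ca])]
  brute <- vapply(seq_len(n_frames(jt)), function(f) {
    x <- frame_coords(jt, f, ca)
    sqrt(sum((x[3, ] - x[nrow(x) - 2, ])^2))
  }, numeric(1))
  expect_equal(end_to_end(jt)$series, brute, tolerance = 1e-12)

  too_short <- toy_traj(list(matrix(0, 3, 3)),
                        data.frame(chain = "B", resno = 1:3,
                                   resid = "GLY", elety = "CA"))
  expect_error(end_to_end(too_short), "6 C-alpha")
})

test_that("SVD plane fit recovers exact and noisy planes", {
  set.seed(31)
  # coplanar points: zero residual, projection preserves distances
  u <- matrix(rnorm(60), ncol = 3)
  u[, 3] <- 0.5 * u[, 1] - 2 * u[, 2] + 3
  pl <- fit_plane_svd(u)
  expect_lt(pl$rss, 1e-18)
  d3 <- dist(u); d2 <- dist(pl$projected)
  expect_equal(as.vector(d2), as.vector(d3), tolerance = 1e-9)

  # tilted circle: normal parallel to the constructed axis
  axis <- c(1, 2, 2) / 3
  b1 <- c(2, -1, 0) / sqrt(5); b2 <- c(axis[2] * b1[3] - axis[3] * b1[2],
                                       axis[3] * b1[1] - axis[1] * b1[3],
                                       axis[1] * b1[2] - axis[2] * b1[1])
  th <- seq(0, 2 * pi, length.out = 40)
  circ <- 5 * outer(cos(th), b1) + 5 * outer(sin(th), b2)
  pl2 <- fit_plane_svd(circ)
  expect_lt(min(sum((pl2$normal - axis)^2), sum((pl2$normal + axis)^2)),
            1e-18)

  # noisy plane: residual variance equals smallest covariance eigenvalue
  for (i in 1:20) {
    pts <- matrix(rnorm(90), ncol = 3) %*% diag(c(3, 1, 0.05))
    pl3 <- fit_plane_svd(pts)
    expect_equal(pl3$residual_var, min(eigen(cov(pts))$values),
                 tolerance = 1e-9)
  }

  # collinear input flags degeneracy instead of failing
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_true(fit_plane_svd(line)$degenerate)
})

test_that("circle fit is exact on circles and circumcircles", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  p <- cbind(3 + 50 * cos(th), -7 + 50 * sin(th))
  for (m in c("geometric", "kasa")) {
    fc <- fit_circle_2d(p, method = m)
    expect_equal(fc$r, 50, tolerance = 1e-9)
    expect_equal(fc$center, c(3, -7), tolerance = 1e-7, ignore_attr = TRUE)
    expect_lt(fc$rms_residual, 1e-9)
  }

  # three points: exact circumscribed circle (closed-form oracle)
  set.seed(17)
  for (i in 1:200) {
    tri <- random_triple()
    oracle <- circumcircle(tri)
    fc <- fit_circle_2d(tri)
    expect_equal(fc$r, oracle$r, tolerance = 1e-9)
    expect_equal(fc$center, oracle$center, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }

  expect_error(fit_circle_2d(matrix(1, 5, 2)), "coincident")
  expect_error(fit_circle_2d(matrix(1, 2, 2)), "at least 3")
})

test_that("circle fit recovers a noisy shallow arc within error bounds", {
  set.seed(23)
  r0 <- 40; span <- 20 * pi / 180
  th <- seq(-span / 2, span / 2, length.out = 60)
  errs <- replicate(40, {
    p <- cbind(r0 * sin(th), r0 * (1 - cos(th))) +
      matrix(rnorm(120, 0, 0.01), ncol = 2)
    fit_circle_2d(p)$r - r0
  })
  # Monte-Carlo oracle bound: mean error within 3 SD of the replicates
  expect_lt(abs(mean(errs)), 3 * sd(errs))
  expect_lt(sd(errs), 1.5)  # sanity: the fit is not wildly unstable
})

test_that("near-straight sets report the capped radius, not an error", {
  p <- cbind(seq(0, 10, length.out = 30), 0)
  p[, 2] <- p[, 2] + seq(-1e-10, 1e-10, length.out = 30)
  fc <- fit_circle_2d(p)
  expect_true(fc$degenerate)
  expect_equal(fc$r, 1e6)
  expect_equal(fc$curvature, 1e-6)
})

test_that("curvature recovers constructed bends and flags straight frames", {
  # bent on a 100 nm circle, no noise: curvature 0.0100 within 1e-6
  bt <- make_bent_trimer(generator_config(kappa0 = 0.01, noise_sigma = 0,
                                          n_frames = 3, seed = 4))
  cv <- curvature_per_frame(bt)
  expect_equal(cv$mean, 0.01, tolerance = 1e-4)
  expect_lt(abs(cv$series[1] - 0.01), 1e-6)
  expect_false(any(cv$degenerate))

  # straight, noiseless: degenerate-flagged, reported ~ 0
  st <- make_straight_trimer(generator_config(noise_sigma = 0,
                                              n_frames = 2, seed = 4))
  cs <- curvature_per_frame(st)
  expect_true(all(cs$degenerate))
  expect_lte(cs$mean, 1e-6)

  # selection errors
  expect_error(curvature_per_frame(make_two_point_chainB(10)),
               "no C-alpha atoms in chain A")
})

test_that("curvature and L are invariant under global rigid motion", {
  bt <- make_bent_trimer(generator_config(kappa0 = 0.0033,
                                          curvature_sd = 0.0018,
                                          n_frames = 6, seed = 8))
  set.seed(99)
  qr_ <- qr(matrix(rnorm(9), 3)); R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- c(5, -3, 11)
  xyz2 <- t(apply(bt$xyz, 1, function(v) {
    m <- matrix(v, ncol = 3, byrow = TRUE) %*% t(R)
    as.vector(t(sweep(m, 2, shift, "+")))
  }))
  bt2 <- helix_trajectory(xyz2, bt$atoms, bt$dt)
  expect_equal(curvature_per_frame(bt2)$series,
               curvature_per_frame(bt)$series, tolerance = 1e-9)
  expect_equal(end_to_end(bt2)$series, end_to_end(bt)$series,
               tolerance = 1e-9)
})

test_that("flexibility is the sample SD of the curvature series", {
  expect_equal(flexibility(rep(0.005, 10)), 0)
  expect_equal(flexibility(c(0.002, 0.004)), sd(c(0.002, 0.004)))
  expect_equal(flexibility(c(0.002, 0.004)),
               sqrt(2) * 0.001, tolerance = 1e-12)
  expect_error(flexibility(0.01), "insufficient")
})

test_that("RMSD/RMSF are zero for static or rigidly moved ensembles", {
  st <- make_straight_trimer(generator_config(noise_sigma = 0,
                                              n_frames = 4, seed = 3))
  expect_equal(rmsd_series(st), rep(0, 4), tolerance = 1e-6)
  expect_equal(rmsf_per_chain(st)$rmsf, rep(0, 39 * 3), tolerance = 1e-6)

  # a rigidly rotated copy of frame 1 superposes to RMSD 0
  atoms <- data.frame(chain = "A", resno = 1:4, resid = "GLY",
                      elety = rep(c("N", "CA", "C"), length.out = 4))
  f1 <- matrix(rnorm(12), 4, 3)
  rot90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  tr <- toy_traj(list(f1, f1 %*% rot90), atoms)
  expect_equal(rmsd_series(tr)[2], 0, tolerance = 1e-6)
})

test_that("two-frame toy RMSD matches a direct Kabsch oracle", {
  # generic 4-atom configuration (unique optimal superposition); frame 2
  # displaces one atom by d
  d <- 0.4
  atoms <- data.frame(chain = "A", resno = 1:4, resid = "GLY",
                      elety = rep(c("N", "CA", "C"), length.out = 4))
  set.seed(61)
  f1 <- matrix(rnorm(12), 4, 3)
  f2 <- f1; f2[4, 1] <- f2[4, 1] + d
  tr <- toy_traj(list(f1, f2), atoms)
  got <- rmsd_series(tr)[2]
  # oracle: Kabsch by SVD of the covariance of centered coordinates
  x <- scale(f1, scale = FALSE); y <- scale(f2, scale = FALSE)
  s <- svd(t(y) %*% x)
  flip <- diag(c(1, 1, sign(det(s$u %*% t(s$v)))))
  yrot <- y %*% s$u %*% flip %*% t(s$v)
  oracle <- sqrt(mean(rowSums((yrot - x)^2)))
  expect_equal(got, oracle, tolerance = 1e-4)
  # superposition can only reduce the naive displacement RMSD
  expect_lte(got, sqrt(d^2 / 4) + 1e-9)

  rf <- rmsf_per_chain(tr)
  expect_equal(nrow(rf), 1L)  # one C-alpha in the selection
})

test_that("hydrogen-bond counting follows the inclusive geometric rule", {
  expect_equal(hbond_count(make_hbond_fixture(1, "ideal"))$mean, 1)
  expect_equal(hbond_count(make_hbond_fixture(14, "ideal"))$mean, 14)
  # boundary at exactly 0.35 nm is counted
  expect_equal(hbond_count(make_hbond_fixture(5, "borderline"))$mean, 5)
  expect_equal(hbond_count(make_hbond_fixture(5, "broken"))$mean, 0)

  # proline/hydroxyproline backbone N never donates
  fx <- make_hbond_fixture(3, "ideal")
  fx$atoms$resid[fx$atoms$elety == "N"] <- "PRO"
  expect_warning(res_pro <- hbond_count(fx), "no donor")
  expect_equal(res_pro$mean, 0)

  # hyp-only donor mode ignores backbone donors
  expect_warning(res_hyp <- hbond_count(make_hbond_fixture(4, "ideal"),
                                        donors = "hyp"), "no donor")
  expect_equal(res_hyp$mean, 0)
})

test_that("contact and H-bond counts equal a brute-force pair scan", {
  set.seed(55)
  for (rep in 1:4) {
    n <- 8
    atoms <- data.frame(
      chain = rep(c("A", "B"), each = n),
      resno = rep(seq_len(n), 2),
      resid = "GLY",
      elety = rep(c("CA", "O"), n))
    co <- matrix(runif(3 * 2 * n, 0, 1.6), ncol = 3)
    tr <- toy_traj(list(co), atoms)
    got <- contact_count(tr, cutoff = 0.6)$series
    # O(n^2) brute force: residue pairs on different chains whose minimal
    # heavy-atom distance is within the cutoff, counted once
    cnt <- 0L
    for (ri in seq_len(n)) for (rj in seq_len(n)) {
      ai <- which(atoms$chain == "A" & atoms$resno == ri)
      bj <- which(atoms$chain == "B" & atoms$resno == rj)
      dmin <- min(outer(ai, bj, Vectorize(function(i, j)
        sqrt(sum((co[i, ] - co[j, ])^2)))))
      if (dmin <= 0.6) cnt <- cnt + 1L
    }
    expect_equal(got, cnt)
  }
})

test_that("block-shifted errors behave on constant and i.i.d. series", {
  st <- make_straight_trimer(generator_config(noise_sigma = 0,
                                              n_frames = 40, seed = 6))
  bs <- block_shifted_se(st, function(t) end_to_end(t)$mean)
  expect_equal(bs$se, 0, tolerance = 1e-12)
  expect_equal(bs$mean, 0.286 * 34, tolerance = 1e-9)

  # i.i.d. Gaussian statistic: SE within expected sampling bounds
  set.seed(77)
  atoms <- data.frame(chain = "B", resno = 1:6, resid = "GLY", elety = "CA")
  sigma <- 0.05; nf <- 500
  frames <- lapply(seq_len(nf), function(f) {
    m <- cbind(0, 0, c(-2, -1, 0, 10, 11, 12))
    m[4, 3] <- 10 + rnorm(1, 0, sigma)
    m
  })
  tr <- toy_traj(frames, atoms)
  bs2 <- block_shifted_se(tr, function(t) end_to_end(t)$mean)
  # each set holds 100 frames; SD of set means ~ sigma/10, SE ~ sigma/10/sqrt(5)
  expected_se <- sigma / sqrt(100) / sqrt(5)
  expect_gt(bs2$se, expected_se / 4)
  expect_lt(bs2$se, expected_se * 4)

  expect_error(block_shifted_se(st, function(t) 1, n_sets = 1),
               "n_sets < 2")
  expect_error(block_shifted_se(st, function(t) 1, shift = 33), "multiple")
  short <- make_straight_trimer(generator_config(n_frames = 3, seed = 1))
  expect_error(block_shifted_se(short, function(t) 1), "insufficient")
})

test_that("Daura clustering partitions conformer groups correctly", {
  st <- make_straight_trimer(generator_config(noise_sigma = 0,
                                              n_frames = 6, seed = 2))
  cl <- daura_cluster(st)
  expect_equal(cl$n_clusters, 1L)
  expect_equal(cl$sizes, 6L)

  # two well-separated conformer groups -> 2 clusters
  atoms <- data.frame(chain = "A", resno = 1:6, resid = "GLY",
                      elety = rep(c("N", "CA", "C"), 2))
  base <- matrix(rnorm(18, sd = 2), 6, 3)
  bent <- base; bent[1:3, ] <- bent[1:3, ] + 3  # internal deformation
  frames <- c(replicate(4, base + matrix(rnorm(18, 0, 0.01), 6, 3),
                        simplify = FALSE),
              replicate(3, bent + matrix(rnorm(18, 0, 0.01), 6, 3),
                        simplify = FALSE))
  tr <- toy_traj(frames, atoms)
  cl2 <- daura_cluster(tr, cutoff = 0.25)
  expect_equal(cl2$n_clusters, 2L)
  expect_equal(sort(cl2$sizes, decreasing = TRUE), c(4L, 3L))
  expect_equal(cl2$membership[1:4], rep(cl2$membership[1], 4))

  # random ensembles: identical partition to an O(n^2) oracle
  set.seed(41)
  frames3 <- replicate(12, matrix(rnorm(18, sd = 0.3), 6, 3),
                       simplify = FALSE)
  tr3 <- toy_traj(frames3, atoms)
  for (cut in c(0.3, 0.6, 1.0)) {
    got <- daura_cluster(tr3, cutoff = cut)
    # oracle: explicit greedy loop on a fresh pairwise matrix
    idx <- triplehelix:::backbone_idx(tr3)
    cols <- triplehelix:::xyz_cols(idx)
    dm <- matrix(0, 12, 12)
    for (i in 1:12) for (j in 1:12)
      dm[i, j] <- bio3d::rmsd(tr3$xyz[i, cols], tr3$xyz[j, cols],
                              fit = TRUE)
    left <- 1:12; mem <- integer(12); k <- 0L; reps <- integer(0)
    while (length(left)) {
      k <- k + 1L
      counts <- sapply(left, function(i) sum(dm[i, left] <= cut))
      ctr <- left[which.max(counts)]
      mm <- left[dm[ctr, left] <= cut]
      mem[mm] <- k; reps <- c(reps, ctr); left <- setdiff(left, mm)
    }
    expect_equal(got$membership, mem)
    expect_equal(got$representatives, reps)
  }
})

test_that("geometry_summary bundles the statistics coherently", {
  bt <- make_bent_trimer(generator_config(kappa0 = 0.005,
                                          curvature_sd = 0.001,
                                          n_frames = 25, seed = 13))
  gs <- geometry_summary(bt)
  expect_s3_class(gs, "geometry_summary")
  expect_gt(gs$L_mean, 9); expect_lt(gs$L_mean, 10.5)
  expect_gte(gs$L_sd, 0)
  expect_equal(gs$curvature_mean, 0.005, tolerance = 0.15)
  expect_gte(gs$flexibility, 0)
  expect_equal(gs$rmsd_series[1], 0, tolerance = 1e-9)
  expect_gte(gs$n_clusters, 1L)
  expect_output(print(gs), "nm")
})
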