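# Trajectory-geometry statistics for collagen trimer ensembles:
# end-to-end distance, curvature by SVD plane projection + least-squares
# circle fit, flexibility, RMSD/RMSF, hydrogen bonds, contacts, Daura
# clustering and block-shifted standard errors. All lengths in nm.

# radius cap for near-straight configurations (nm): curvature is reported
# as 1/r with r capped here and a degenerate flag set, never an exception
R_CAP <- 1e6
# condition-number threshold on the circle-fit normal equations beyond
# which the point set is treated as straight within noise
KAPPA_MAX <- 1e8

#' Per-frame end-to-end distance of the middle chain
#'
#' The distance between the C-alpha of the third residue and the C-alpha of
#' the third residue from the end of the middle (B) chain, a choice that
#' avoids the partially unfolding termini.
#'
#' @param traj A `helix_trajectory`.
#' @param chain Chain identifier of the middle chain (default `"B"`).
#' @return A list with `series` (nm per frame), `mean` and `sd` (the
#'   extension spread `s`).
#' @export
end_to_end <- function(traj, chain = "B") {
  ca <- select_atoms(traj, chain = chain, elety = "CA")
  if (length(ca) < 6L)
    stop("atom-selection error: middle chain needs >= 6 C-alpha atoms",
         call. = FALSE)
  resno <- traj$atoms$resno[ca]
  ca <- ca[order(resno)]
  i <- ca[3L]; j <- ca[length(ca) - 2L]
  di <- traj$xyz[, xyz_cols(i), drop = FALSE] -
    traj$xyz[, xyz_cols(j), drop = FALSE]
  series <- sqrt(rowSums(di^2))
  list(series = series, mean = mean(series),
       sd = if (length(series) > 1L) stats::sd(series) else 0)
}

#' Best-fit plane by singular value decomposition
#'
#' The plane passes through the centroid with normal along the singular
#' vector of the smallest singular value of the centered coordinates; the
#' projection onto the two leading singular vectors preserves in-plane
#' distances. Degenerate (collinear) sets are flagged, not rejected.
#'
#' @param points Numeric n x 3 matrix, n >= 3.
#' @return A list: `origin` (centroid), `normal` (unit), `projected`
#'   (n x 2, in-plane coordinates), `rss` (sum of squared out-of-plane
#'   distances), `residual_var` (`rss / (n - 1)`, the smallest eigenvalue of
#'   the coordinate covariance), `degenerate` (collinearity flag).
#' @export
fit_plane_svd <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  ctr <- colMeans(points)
  x <- sweep(points, 2L, ctr)
  sv <- svd(x)
  normal <- sv$v[, 3L]
  proj <- x %*% sv$v[, 1:2, drop = FALSE]
  degenerate <- sv$d[2L] <= 1e-12 * max(sv$d[1L], 1e-300)
  list(origin = ctr, normal = normal, projected = proj,
       rss = sv$d[3L]^2, residual_var = sv$d[3L]^2 / (n - 1),
       degenerate = degenerate)
}

#' Least-squares circle fit
#'
#' The default `"geometric"` method minimizes the orthogonal distances of
#' the points to the circle (Levenberg-Marquardt), started from the better
#' of two closed-form initializations: the Kasa algebraic fit (solving
#' `2*x*a + 2*y*b + c = x^2 + y^2`) and a parabolic-arc estimate (OLS
#' quadratic of the transverse on the longitudinal principal coordinate).
#' The geometric fit is required for shallow arcs sampled by points with a
#' transverse spread larger than the sagitta -- exactly the situation of a
#' gently curved collagen trimer, whose pooled C-alpha cloud is ~0.3 nm
#' wide while the sagitta of a 300 nm-radius bend over 10 nm is only
#' ~0.04 nm; the purely algebraic fit is attenuated by orders of magnitude
#' there, so `method = "kasa"` is kept only for comparison and for exact
#' interpolation problems. On three non-collinear points (and on points
#' lying exactly on a circle) both methods return the exact circle.
#'
#' Near-straight sets (curvature below `1 / r_cap`, or a rank-deficient
#' system) report a radius capped at `r_cap` with the `degenerate` flag
#' set, never an exception.
#'
#' @param points_2d Numeric n x 2 matrix, n >= 3.
#' @param method `"geometric"` (default) or `"kasa"`.
#' @param r_cap Radius cap for near-straight configurations (nm).
#' @return A list: `center`, `r`, `curvature` (= 1/r), `rms_residual`,
#'   `degenerate`.
#' @export
fit_circle_2d <- function(points_2d, method = c("geometric", "kasa"),
                          r_cap = R_CAP) {
  method <- match.arg(method)
  p <- as.matrix(points_2d)
  if (nrow(p) < 3L) stop("need at least 3 points", call. = FALSE)
  if (max(apply(p, 2L, function(v) diff(range(v)))) < 1e-12)
    stop("degenerate error: all points coincident", call. = FALSE)

  best <- if (method == "kasa") kasa_circle(p) else geometric_circle(p)
  degenerate <- is.null(best) || !all(is.finite(best$r)) ||
    best$r <= 0 || best$r > r_cap
  if (degenerate) {
    center <- c(NA_real_, NA_real_); r <- r_cap; rms <- NA_real_
  } else {
    center <- best$center; r <- best$r
    rms <- sqrt(mean((sqrt((p[, 1L] - center[1L])^2 +
                             (p[, 2L] - center[2L])^2) - r)^2))
  }
  list(center = center, r = r, curvature = 1 / r, rms_residual = rms,
       degenerate = degenerate)
}

# Geometric (orthogonal-distance) circle fit in the algebraic
# parametrization A(x^2+y^2) + B x + C y + D = 0 normalized to
# B^2 + C^2 - 4AD = 1, under which the exact point-to-circle distance is
# 2P / (1 + sqrt(1 + 4AP)) with P the normalized algebraic residual.
# Unlike the (center, radius) parametrization this stays perfectly
# conditioned through the straight-line limit A -> 0, so shallow arcs and
# near-straight clouds converge to a well-defined optimum.
geometric_circle <- function(p) {
  z <- p[, 1L]^2 + p[, 2L]^2
  resid <- function(u) {
    nrm <- u[2L]^2 + u[3L]^2 - 4 * u[1L] * u[4L]
    if (!is.finite(nrm) || nrm <= 0) return(rep(1e6, nrow(p)))
    u <- u / sqrt(nrm)
    P <- u[1L] * z + u[2L] * p[, 1L] + u[3L] * p[, 2L] + u[4L]
    E <- pmax(1 + 4 * u[1L] * P, 0)
    2 * P / (1 + sqrt(E))
  }
  # initializations: Kasa circle, parabolic arc, total-least-squares line
  inits <- list()
  to_u <- function(fit) {
    if (is.null(fit)) return(NULL)
    s <- 1 / (2 * fit$r)
    c(s, -2 * fit$center[1L] * s, -2 * fit$center[2L] * s,
      s * (sum(fit$center^2) - fit$r^2))
  }
  inits$kasa <- to_u(kasa_circle(p))
  inits$arc <- to_u(parabola_circle(p))
  ctr <- colMeans(p)
  nv <- svd(sweep(p, 2L, ctr))$v[, 2L]
  inits$line <- c(0, nv[1L], nv[2L], -sum(nv * ctr))
  best <- NULL; best_sse <- Inf
  for (u0 in inits) {
    if (is.null(u0) || !all(is.finite(u0))) next
    cand <- u0
    if (nrow(p) >= 4L) {  # LM needs at least as many residuals as params;
                          # on 3 points the Kasa init is already exact
      fit <- tryCatch(
        suppressWarnings(
          minpack.lm::nls.lm(par = u0, fn = resid,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 500, ftol = 1e-15, ptol = 1e-15,
                               gtol = 0))),
        error = function(e) NULL)
      if (!is.null(fit) && all(is.finite(fit$par))) cand <- fit$par
    }
    sse <- sum(resid(cand)^2)
    if (sse < best_sse) { best_sse <- sse; best <- cand }
  }
  if (is.null(best)) return(NULL)
  u <- best / sqrt(best[2L]^2 + best[3L]^2 - 4 * best[1L] * best[4L])
  if (abs(u[1L]) < 1 / (2 * R_CAP)) return(NULL)  # straight within cap
  r <- 1 / (2 * abs(u[1L]))
  list(center = c(-u[2L], -u[3L]) / (2 * u[1L]), r = r)
}

# Kasa algebraic circle fit; NULL when the system is rank-deficient or
# numerically straight (condition number beyond KAPPA_MAX)
kasa_circle <- function(p) {
  A <- cbind(2 * p[, 1L], 2 * p[, 2L], 1)
  b <- p[, 1L]^2 + p[, 2L]^2
  sol <- tryCatch({
    qrA <- qr(A)
    if (qrA$rank < 3L) NULL else qr.coef(qrA, b)
  }, error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol))) return(NULL)
  cond <- tryCatch(kappa(crossprod(A), exact = FALSE),
                   error = function(e) Inf)
  if (cond > KAPPA_MAX) return(NULL)
  center <- sol[1:2]
  r2 <- sol[3L] + sum(center^2)
  if (r2 <= 0) return(NULL)
  list(center = unname(center), r = sqrt(r2))
}

# osculating-circle estimate from an OLS parabola in the principal frame;
# suited to shallow arcs, useless for full circles (the SSE comparison in
# fit_circle_2d sorts that out)
parabola_circle <- function(p) {
  ctr <- colMeans(p)
  x <- sweep(p, 2L, ctr)
  sv <- svd(x)
  q <- x %*% sv$v                       # column 1 = longitudinal
  cf <- tryCatch(stats::lm.fit(cbind(1, q[, 1L], q[, 1L]^2),
                               q[, 2L])$coefficients,
                 error = function(e) NULL)
  if (is.null(cf) || anyNA(cf) || abs(cf[3L]) < 1 / (2 * R_CAP) / 1e3)
    return(NULL)
  c2 <- cf[3L]
  xv <- -cf[2L] / (2 * c2)
  yv <- cf[1L] + cf[2L] * xv + c2 * xv^2
  center_q <- c(xv, yv + 1 / (2 * c2))
  list(center = unname(as.vector(ctr + sv$v %*% center_q)),
       r = abs(1 / (2 * c2)))
}

# default chain-end omission scheme: residues dropped from each end before
# pooling C-alpha atoms for the curvature fit (leading A 3+3, middle B 2+2,
# trailing C 3+3)
default_omission <- function() {
  list(A = c(3L, 3L), B = c(2L, 2L), C = c(3L, 3L))
}

# pooled C-alpha atom indices after end omission
curvature_atom_set <- function(traj, omission = default_omission()) {
  idx <- integer(0)
  for (ch in names(omission)) {
    ca <- select_atoms(traj, chain = ch, elety = "CA")
    if (!length(ca)) stop("selection error: no C-alpha atoms in chain ", ch,
                          call. = FALSE)
    ca <- ca[order(traj$atoms$resno[ca])]
    om <- omission[[ch]]
    if (length(ca) <= sum(om))
      stop("selection error: chain ", ch, " too short after end omission",
           call. = FALSE)
    idx <- c(idx, ca[(om[1L] + 1L):(length(ca) - om[2L])])
  }
  idx
}

#' Per-frame curvature of a trimer ensemble
#'
#' For each frame the C-alpha atoms of the three chains are pooled after
#' dropping terminal residues (default: first/last 3 of chain A, 2 of chain
#' B, 3 of chain C), projected onto the bending plane, and a circle is
#' fitted; the curvature is 1/r. Near-straight frames are reported with the
#' capped radius and flagged.
#'
#' The projection plane contains the longitudinal axis (leading singular
#' vector of the centered cloud). Because the three chains wind with
#' near-perfect three-fold symmetry, the transverse second moments of a
#' trimer are almost isotropic and the remaining two singular vectors are
#' degenerate: a plain smallest-singular-vector plane would mix an
#' arbitrary part of the gentle bend (sagitta ~0.04 nm for a 300 nm bend
#' radius over a 10 nm helix) out of the plane. The second in-plane axis is
#' therefore taken as the transverse direction carrying the quadratic
#' (bowing) trend of the cloud along the axis, which isolates the bending
#' plane; frames with no detectable quadratic trend are flagged straight.
#'
#' @param traj A `helix_trajectory` with chains A, B and C.
#' @param omission Named list of `c(n_front, n_back)` residues to drop per
#'   chain; see Details for the default.
#' @param method Circle-fit method, passed to [fit_circle_2d()].
#' @return A list: `series` (nm^-1 per frame), `mean`, `degenerate`
#'   (logical per frame).
#' @export
curvature_per_frame <- function(traj, omission = default_omission(),
                                method = "geometric") {
  idx <- curvature_atom_set(traj, omission)
  nf <- n_frames(traj)
  series <- numeric(nf); degen <- logical(nf)
  for (f in seq_len(nf)) {
    pts <- frame_coords(traj, f, idx)
    bp <- bending_plane_points(pts, groups = traj$atoms$chain[idx])
    if (bp$degenerate) {
      series[f] <- 1 / R_CAP; degen[f] <- TRUE
    } else {
      fc <- fit_circle_2d(bp$points, method = method)
      series[f] <- fc$curvature
      degen[f] <- fc$degenerate
    }
  }
  list(series = series, mean = mean(series), degenerate = degen)
}

# project a pooled 3D cloud onto (longitudinal axis, bending direction):
# axis = leading principal direction; bending direction = the transverse
# direction of the quadratic bowing trend along the axis. Per-group
# (per-chain) intercepts absorb the constant transverse offset of each
# strand, so a chain protruding past the others at the ends (chain B keeps
# one more residue per end under the default omission) cannot masquerade
# as bowing.
bending_plane_points <- function(pts, groups = NULL) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2L, ctr)
  sv <- svd(x)
  q <- x %*% sv$v
  t <- q[, 1L]
  icpt <- if (is.null(groups) || length(unique(groups)) < 2L)
    matrix(1, length(t), 1L)
  else stats::model.matrix(~ 0 + factor(groups))
  cf <- tryCatch(
    stats::lm.fit(cbind(icpt, t, t^2), q[, 2:3, drop = FALSE])$coefficients,
    error = function(e) NULL)
  if (is.null(cf) || anyNA(cf))
    return(list(points = q[, 1:2, drop = FALSE], degenerate = TRUE))
  c2 <- cf[nrow(cf), ]
  nrm <- sqrt(sum(c2^2))
  if (!is.finite(nrm) || 2 * nrm < 1 / R_CAP)
    return(list(points = q[, 1:2, drop = FALSE], degenerate = TRUE))
  u <- c2 / nrm
  # remove each strand's constant transverse offset (the fitted per-chain
  # intercepts, which the regression separates from the shared bowing
  # trend), collapsing the three parallel chains onto the common axis: the
  # circle then fits the axis bend alone, and noise in the
  # bending-direction estimate cannot leak the strand-offset pattern into
  # the curvature
  ng <- ncol(icpt)
  w <- (q[, 2:3, drop = FALSE] -
          icpt %*% cf[seq_len(ng), , drop = FALSE]) %*% u
  # the projection is pose-independent in exact arithmetic; rounding the
  # canonical coordinates at 1e-9 nm (far below atomic precision) removes
  # the residual floating-point pose dependence so identical frames in
  # different global orientations give bit-identical fits
  pts2d <- round(cbind(t, w), 9L)
  list(points = pts2d, degenerate = FALSE)
}

#' Flexibility of a trimer: SD of the time-dependent curvature
#'
#' @param curvature_series Numeric vector of per-frame curvatures, or the
#'   list returned by [curvature_per_frame()].
#' @return Sample standard deviation (nm^-1).
#' @export
flexibility <- function(curvature_series) {
  if (is.list(curvature_series)) curvature_series <- curvature_series$series
  if (length(curvature_series) < 2L)
    stop("insufficient data: flexibility needs >= 2 frames", call. = FALSE)
  stats::sd(curvature_series)
}

# backbone atom indices (N, CA, C) ordered by chain then residue
backbone_idx <- function(traj, elety = c("N", "CA", "C")) {
  idx <- select_atoms(traj, elety = elety)
  if (!length(idx)) stop("selection error: no backbone atoms", call. = FALSE)
  idx[order(traj$atoms$chain[idx], traj$atoms$resno[idx])]
}

#' Backbone RMSD series after optimal superposition
#'
#' Every frame is rigid-body superposed (Kabsch) onto the reference frame
#' over the backbone atoms (N, C-alpha, C) of all chains before computing
#' the RMSD.
#'
#' @param traj A `helix_trajectory`.
#' @param reference_frame Reference frame index (default 1, so the first
#'   series entry is 0).
#' @return Numeric vector of per-frame RMSD values (nm).
#' @export
rmsd_series <- function(traj, reference_frame = 1L) {
  idx <- backbone_idx(traj)
  cols <- xyz_cols(idx)
  ref <- traj$xyz[reference_frame, cols]
  fitted <- suppressWarnings(
    bio3d::fit.xyz(ref, traj$xyz[, cols, drop = FALSE]))
  # rmsd computed directly from the superposed coordinates (bio3d's rmsd()
  # rounds to 3 decimals, too coarse on the nm scale)
  sqrt(rowMeans((sweep(fitted, 2L, ref))^2) * 3)
}

#' Per-residue RMSF by chain
#'
#' Frames are superposed on the first frame over all backbone atoms, then
#' the root mean square fluctuation of each C-alpha about its time-averaged
#' position is reported per chain.
#'
#' @param traj A `helix_trajectory`.
#' @return A data.frame with columns `chain`, `resno`, `rmsf` (nm).
#' @export
rmsf_per_chain <- function(traj) {
  idx <- backbone_idx(traj)
  cols <- xyz_cols(idx)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(traj$xyz[1L, cols], traj$xyz[, cols, drop = FALSE]))
  # per-atom RMSF about the mean structure, then keep the C-alpha entries
  mu <- colMeans(fitted)
  msf <- colMeans(sweep(fitted, 2L, mu)^2)      # per-coordinate
  per_atom <- sqrt(rowSums(matrix(msf, ncol = 3L, byrow = TRUE)))
  keep <- traj$atoms$elety[idx] == "CA"
  data.frame(chain = traj$atoms$chain[idx][keep],
             resno = traj$atoms$resno[idx][keep],
             rmsf = per_atom[keep], row.names = NULL)
}

#' Interchain hydrogen-bond count per frame
#'
#' Geometric criterion without explicit hydrogens: a donor heavy atom
#' (backbone N of non-imino residues, hydroxyproline hydroxyl OD1) and an
#' acceptor (backbone carbonyl O, hydroxyproline OD1) on *different* chains
#' within `cutoff` (inclusive). When the donor's antecedent atom is present
#' a C-N...O angle filter (>= `angle_min` degrees at the donor) suppresses
#' geometrically impossible pairs.
#'
#' @param traj A `helix_trajectory`.
#' @param cutoff Donor-acceptor distance cutoff in nm (default 0.35,
#'   inclusive).
#' @param angle_min Minimal donor angle in degrees (default 90).
#' @param donors `"all"` (backbone + Hyp hydroxyl) or `"hyp"` (hydroxyl
#'   donors only).
#' @return A list with `series` (count per frame) and `mean`.
#' @export
hbond_count <- function(traj, cutoff = 0.35, angle_min = 90,
                        donors = c("all", "hyp")) {
  donors <- match.arg(donors)
  a <- traj$atoms
  don_idx <- which((a$elety == "N" & !(a$resid %in% c("PRO", "HYP"))) |
                     a$elety == "OD1")
  if (donors == "hyp") don_idx <- which(a$elety == "OD1")
  acc_idx <- which(a$elety %in% c("O", "OD1"))
  if (!length(don_idx) || !length(acc_idx)) {
    warning("no donor/acceptor atoms found; returning zero counts")
    return(list(series = rep(0L, n_frames(traj)), mean = 0))
  }
  # antecedent C of each backbone N (same chain/resno) for the angle filter
  ante <- rep(NA_integer_, length(don_idx))
  for (k in seq_along(don_idx)) {
    d <- don_idx[k]
    if (a$elety[d] == "N") {
      hit <- which(a$chain == a$chain[d] & a$resno == a$resno[d] &
                     a$elety == "CA")
      if (length(hit)) ante[k] <- hit[1L]
    }
  }
  cos_max <- cos(angle_min * pi / 180)
  nf <- n_frames(traj)
  series <- integer(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    cnt <- 0L
    for (k in seq_along(don_idx)) {
      d <- don_idx[k]
      acc <- acc_idx[a$chain[acc_idx] != a$chain[d]]
      if (!length(acc)) next
      dv <- sweep(xyz[acc, , drop = FALSE], 2L, xyz[d, ])
      dist <- sqrt(rowSums(dv^2))
      ok <- dist <= cutoff
      if (any(ok) && !is.na(ante[k])) {
        u <- xyz[ante[k], ] - xyz[d, ]
        u <- u / sqrt(sum(u^2))
        # angle C(alpha)-N...O must open beyond angle_min
        cosang <- (dv[ok, , drop = FALSE] %*% u) / dist[ok]
        ok[ok] <- cosang <= cos_max
      }
      cnt <- cnt + sum(ok)
    }
    series[f] <- cnt
  }
  list(series = series, mean = mean(series))
}

#' Interchain contact count per frame
#'
#' Residue pairs on different chains with any heavy-atom pair within
#' `cutoff` (inclusive) count once per frame.
#'
#' @param traj A `helix_trajectory`.
#' @param cutoff Heavy-atom distance cutoff in nm (default 0.6).
#' @return A list with `series` (contacts per frame) and `mean`.
#' @export
contact_count <- function(traj, cutoff = 0.6) {
  a <- traj$atoms
  heavy <- which(!grepl("^H", a$elety))
  key <- paste(a$chain, a$resno, sep = ":")
  nf <- n_frames(traj)
  series <- integer(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f, heavy)
    d <- as.matrix(stats::dist(xyz))
    hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
    if (!nrow(hit)) { series[f] <- 0L; next }
    i <- heavy[hit[, 1L]]; j <- heavy[hit[, 2L]]
    inter <- a$chain[i] != a$chain[j]
    series[f] <- length(unique(paste(key[i[inter]], key[j[inter]])))
  }
  list(series = series, mean = mean(series))
}

#' Block-shifted standard error of a trajectory statistic
#'
#' The trajectory is split into `n_sets` interleaved frame grids, each
#' offset from the previous by `shift` ps (so each grid samples every
#' `n_sets * shift` ps). The statistic is evaluated on every grid; the
#' estimate is the mean of the per-set values and its standard error the SD
#' of the set values divided by `sqrt(n_sets)`.
#'
#' @param traj A `helix_trajectory` whose `dt` divides `shift`.
#' @param statistic Function mapping a `helix_trajectory` to a scalar, e.g.
#'   `function(t) end_to_end(t)$mean`.
#' @param n_sets Number of interleaved sets (default 5; must be >= 2).
#' @param shift Offset between consecutive sets in ps (default 100).
#' @return A list: `mean`, `se`, `set_values`.
#' @export
block_shifted_se <- function(traj, statistic, n_sets = 5L, shift = 100) {
  n_sets <- as.integer(n_sets)
  if (n_sets < 2L)
    stop("degenerate error: standard error undefined for n_sets < 2",
         call. = FALSE)
  off <- shift / traj$dt
  if (abs(off - round(off)) > 1e-9 || off < 1)
    stop("shift (", shift, " ps) must be a positive multiple of dt (",
         traj$dt, " ps)", call. = FALSE)
  off <- as.integer(round(off))
  stride <- n_sets * off
  if (n_frames(traj) < stride)
    stop("insufficient data: trajectory shorter than one sampling grid",
         call. = FALSE)
  vals <- vapply(seq_len(n_sets), function(k) {
    frames <- seq.int(1L + (k - 1L) * off, n_frames(traj), by = stride)
    statistic(subset_frames(traj, frames))
  }, numeric(1L))
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(n_sets),
       set_values = vals)
}

#' Daura conformational clustering
#'
#' Greedy neighbor-count clustering of frames under a pairwise backbone
#' RMSD cutoff: the frame with the most neighbors within the cutoff becomes
#' the representative of the first cluster, the cluster is removed, and the
#' procedure repeats on the remainder. Ties go to the earliest frame.
#'
#' @param traj A `helix_trajectory`.
#' @param cutoff Pairwise RMSD cutoff in nm (default 0.25, inclusive).
#' @param fit Superpose each frame pair before the RMSD (default TRUE).
#' @return A list: `membership` (cluster id per frame), `representatives`
#'   (frame index per cluster), `sizes`, `n_clusters`.
#' @export
daura_cluster <- function(traj, cutoff = 0.25, fit = TRUE) {
  nf <- n_frames(traj)
  if (nf < 1L) stop("empty trajectory", call. = FALSE)
  idx <- backbone_idx(traj)
  cols <- xyz_cols(idx)
  xyz <- traj$xyz[, cols, drop = FALSE]
  dmat <- matrix(0, nf, nf)
  for (i in seq_len(nf)) {
    if (i < nf) {
      rest <- xyz[(i + 1L):nf, , drop = FALSE]
      if (fit)
        rest <- suppressWarnings(bio3d::fit.xyz(xyz[i, ], rest))
      r <- sqrt(rowMeans(sweep(rest, 2L, xyz[i, ])^2) * 3)
      dmat[i, (i + 1L):nf] <- r
      dmat[(i + 1L):nf, i] <- r
    }
  }
  membership <- rep(NA_integer_, nf)
  reps <- integer(0)
  remaining <- seq_len(nf)
  cl <- 0L
  while (length(remaining)) {
    cl <- cl + 1L
    nb <- rowSums(dmat[remaining, remaining, drop = FALSE] <= cutoff)
    center <- remaining[which.max(nb)]  # which.max takes the earliest tie
    members <- remaining[dmat[center, remaining] <= cutoff]
    membership[members] <- cl
    reps <- c(reps, center)
    remaining <- setdiff(remaining, members)
  }
  list(membership = membership, representatives = reps,
       sizes = as.integer(table(membership)), n_clusters = cl)
}

#' Full geometry summary of a trimer ensemble
#'
#' Bundles the per-trajectory statistics: end-to-end distance L with its
#' spread s, mean curvature 1/r, flexibility f, RMSD/RMSF, interchain
#' hydrogen-bond and contact counts, and block-shifted standard errors for
#' L and the curvature.
#'
#' @param traj A `helix_trajectory`.
#' @param omission Chain-end omission scheme for the curvature fit.
#' @param n_sets,shift Block-shifted error parameters; the standard errors
#'   are skipped (NA) when the trajectory is too short for the grids.
#' @param cluster_cutoff Daura cutoff (nm); `NULL` skips clustering.
#' @return An object of class `geometry_summary`.
#' @export
geometry_summary <- function(traj, omission = default_omission(),
                             n_sets = 5L, shift = NULL,
                             cluster_cutoff = 0.25) {
  if (is.null(shift)) shift <- traj$dt
  ee <- end_to_end(traj)
  curv <- curvature_per_frame(traj, omission = omission)
  f <- if (length(curv$series) >= 2L) flexibility(curv$series) else NA_real_
  rmsd <- rmsd_series(traj)
  rmsf <- rmsf_per_chain(traj)
  hb <- hbond_count(traj)
  ct <- contact_count(traj)
  se_L <- se_curv <- NA_real_
  if (n_frames(traj) >= n_sets * round(shift / traj$dt)) {
    se_L <- block_shifted_se(traj, function(t) end_to_end(t)$mean,
                             n_sets = n_sets, shift = shift)$se
    se_curv <- block_shifted_se(
      traj, function(t) curvature_per_frame(t, omission = omission)$mean,
      n_sets = n_sets, shift = shift)$se
  }
  clus <- if (!is.null(cluster_cutoff) && n_frames(traj) > 1L)
    daura_cluster(traj, cutoff = cluster_cutoff) else NULL
  structure(list(
    L_mean = ee$mean, L_sd = ee$sd, L_se = se_L,
    curvature_mean = curv$mean, curvature_se = se_curv,
    flexibility = f,
    degenerate_fraction = mean(curv$degenerate),
    rmsd_series = rmsd, rmsf_per_chain = rmsf,
    hbond_mean = hb$mean, contact_mean = ct$mean,
    n_clusters = if (is.null(clus)) NA_integer_ else clus$n_clusters),
    class = "geometry_summary")
}

#' @export
print.geometry_summary <- function(x, ...) {
  cat("<geometry_summary>\n")
  cat(sprintf("  L       = %.4f nm (s = %.4f, SE = %s)\n", x$L_mean, x$L_sd,
              format(x$L_se, digits = 3)))
  cat(sprintf("  1/r     = %.5f nm^-1 (SE = %s%s)\n", x$curvature_mean,
              format(x$curvature_se, digits = 3),
              if (x$degenerate_fraction > 0)
                sprintf(", %.0f%% frames degenerate/straight",
                        100 * x$degenerate_fraction) else ""))
  cat(sprintf("  f       = %s nm^-1\n", format(x$flexibility, digits = 4)))
  cat(sprintf("  RMSD    = %.4f nm (max %.4f)\n", mean(x$rmsd_series),
              max(x$rmsd_series)))
  cat(sprintf("  H-bonds = %.2f, contacts = %.2f, clusters = %s\n",
              x$hbond_mean, x$contact_mean, format(x$n_clusters)))
  invisible(x)
}
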