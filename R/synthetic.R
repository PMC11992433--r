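# Synthetic coordinate ensembles and collagen-like sequences with analytic
# ground truth, so that every analysis stage is testable offline.
#
# The trimer generator emulates the coarse geometry of a collagen trimer
# ensemble: three parallel strands 120 degrees apart around a common axis
# that is laid along a circular arc whose radius is modulated frame by
# frame. Bending is modeled as modulation within a fixed principal bending
# plane (the simplest process whose curvature mean and SD are exactly
# controllable); a random rigid-body motion is applied to every frame, to
# which all the geometric statistics are invariant. The chain phase offsets
# (-30, 90, 210 degrees) put the middle chain exactly in the bending plane,
# so the pooled C-alpha cloud stays balanced about the central arc even
# after the asymmetric chain-end omission of the curvature fit.

#' Configuration for the synthetic trimer ensemble generator
#'
#' @param n_residues Residues per chain (default 39, i.e. 13 triplets).
#' @param rise Axial rise per residue (nm/residue, default 0.286).
#' @param radius Strand offset from the common axis (nm, default 0.28).
#' @param kappa0 Target mean curvature (nm^-1, >= 0; 0 = straight).
#' @param curvature_sd Target SD of the per-frame curvature (nm^-1, >= 0).
#'   Per-frame curvatures are drawn from a Gamma law with this mean/SD,
#'   which keeps them strictly positive with the exact requested moments.
#' @param length_sd Target SD of the per-frame end-to-end distance (nm,
#'   >= 0), produced by per-frame axial scaling.
#' @param noise_sigma Isotropic Gaussian positional noise per atom (nm,
#'   default 0.01, a small jitter standing in for fast local motion).
#' @param n_frames Number of stored frames.
#' @param dt Time between stored frames (ps, default 100).
#' @param seed Integer seed; identical configuration and seed reproduce the
#'   ensemble exactly.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_residues = 39L, rise = 0.286, radius = 0.28,
                             kappa0 = 0, curvature_sd = 0, length_sd = 0,
                             noise_sigma = 0.01, n_frames = 100L, dt = 100,
                             seed = 1L) {
  stopifnot(n_residues >= 6L, rise > 0, radius > 0, kappa0 >= 0,
            curvature_sd >= 0, length_sd >= 0, noise_sigma >= 0,
            n_frames >= 1L, dt > 0)
  structure(list(n_residues = as.integer(n_residues), rise = rise,
                 radius = radius, kappa0 = kappa0,
                 curvature_sd = curvature_sd, length_sd = length_sd,
                 noise_sigma = noise_sigma, n_frames = as.integer(n_frames),
                 dt = dt, seed = as.integer(seed)),
            class = "generator_config")
}

# reference (unbent) atom layout: three parallel strands, zero stagger,
# phases -30/90/210 degrees; minimal backbone N, CA, C, O per residue
straight_trimer_template <- function(n_residues, rise, radius) {
  phases <- c(-30, 90, 210) * pi / 180
  chains <- c("A", "B", "C")
  atoms <- list(); coords <- list()
  for (k in 1:3) {
    rad <- c(cos(phases[k]), sin(phases[k]), 0)
    base <- radius * rad
    for (i in seq_len(n_residues)) {
      z <- (i - 1) * rise
      ca <- base + c(0, 0, z)
      at <- rbind(ca + c(0, 0, -0.123) - 0.05 * rad,  # N
                  ca,                                  # CA
                  ca + c(0, 0, 0.123) - 0.05 * rad,    # C
                  ca + c(0, 0, 0.123) - 0.17 * rad)    # O
      atoms[[length(atoms) + 1L]] <- data.frame(
        chain = chains[k], resno = i, resid = "GLY",
        elety = c("N", "CA", "C", "O"), stringsAsFactors = FALSE)
      coords[[length(coords) + 1L]] <- at
    }
  }
  list(atoms = do.call(rbind, atoms), coords = do.call(rbind, coords))
}

# map coordinates built around a straight z axis onto a circular arc of
# curvature kappa in the x-z plane (arc length along z preserved)
bend_coords <- function(coords, kappa) {
  if (kappa < 1e-9) return(coords)
  R <- 1 / kappa
  phi <- coords[, 3L] / R
  cbind((R + coords[, 1L]) * cos(phi) - R,
        coords[, 2L],
        (R + coords[, 1L]) * sin(phi))
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qrm <- qr(matrix(stats::rnorm(9L), 3L))
  q <- qr.Q(qrm)
  q <- q %*% diag(sign(diag(qr.R(qrm))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# shared frame loop for straight and bent ensembles
generate_trimer <- function(config) {
  tmpl <- straight_trimer_template(config$n_residues, config$rise,
                                   config$radius)
  n_atoms <- nrow(tmpl$atoms)
  span <- config$n_residues - 5L          # residues 3 .. n-2 of chain B
  L_straight <- span * config$rise
  L0 <- if (config$kappa0 > 0)
    2 / config$kappa0 * sin(config$kappa0 * L_straight / 2) else L_straight
  if (config$kappa0 > 0 && 1 / config$kappa0 <= 2 * config$radius)
    stop("parameter error: curvature so large the trimer self-intersects",
         call. = FALSE)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  # stratified inverse-CDF draws, randomly permuted: the marginal law is
  # unchanged and frames are exchangeable, but the realized ensemble mean
  # and SD match the nominal ground truth to O(1/n) rather than O(1/sqrt(n)),
  # so even short ensembles carry their nominal moments
  strat <- function(n) (sample.int(n) - stats::runif(n)) / n
  if (config$curvature_sd > 0) {
    shape <- (config$kappa0 / config$curvature_sd)^2
    rate <- config$kappa0 / config$curvature_sd^2
    kappas <- stats::qgamma(strat(config$n_frames), shape = shape,
                            rate = rate)
  } else {
    kappas <- rep(config$kappa0, config$n_frames)
  }
  scales <- if (config$length_sd > 0)
    1 + stats::qnorm(strat(config$n_frames)) * config$length_sd / L0
  else rep(1, config$n_frames)

  xyz <- matrix(NA_real_, config$n_frames, 3L * n_atoms)
  for (f in seq_len(config$n_frames)) {
    co <- tmpl$coords
    co[, 3L] <- co[, 3L] * scales[f]
    co <- bend_coords(co, kappas[f])
    if (config$noise_sigma > 0)
      co <- co + matrix(stats::rnorm(3L * n_atoms, 0, config$noise_sigma),
                        ncol = 3L)
    co <- co %*% t(random_rotation())
    co <- sweep(co, 2L, stats::rnorm(3L, 0, 1), `+`)
    xyz[f, ] <- as.vector(t(co))
  }
  helix_trajectory(xyz, tmpl$atoms, dt = config$dt, metadata = list(
    config = config,
    truth = list(kappa = config$kappa0, flexibility = config$curvature_sd,
                 L = L0, L_sd = config$length_sd,
                 L_straight = L_straight)))
}

#' Generate a straight synthetic trimer ensemble
#'
#' Ground truth: curvature 0 (degenerate/straight for the circle fit),
#' end-to-end distance `(n_residues - 5) * rise` between the C-alpha atoms
#' used by [end_to_end()].
#'
#' @param config A [generator_config()] with `kappa0 = 0`.
#' @return A `helix_trajectory` whose `metadata$truth` records the ground
#'   truth.
#' @export
make_straight_trimer <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (config$kappa0 != 0)
    stop("straight ensemble requires kappa0 = 0; use make_bent_trimer",
         call. = FALSE)
  generate_trimer(config)
}

#' Generate a bent synthetic trimer ensemble with known curvature
#'
#' The trimer axis is laid along a circular arc of radius `1/kappa0`; when
#' `curvature_sd > 0` the per-frame curvature is drawn from a Gamma law
#' with mean `kappa0` and SD `curvature_sd`, so the flexibility statistic
#' (SD of the curvature series) has analytic ground truth.
#'
#' @param config A [generator_config()] with `kappa0 > 0`.
#' @return A `helix_trajectory`; `metadata$truth` holds `kappa`,
#'   `flexibility`, `L` and `L_sd`.
#' @export
make_bent_trimer <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$kappa0 <= 0)
    stop("bent ensemble requires kappa0 > 0; use make_straight_trimer",
         call. = FALSE)
  generate_trimer(config)
}

#' Single-frame hydrogen-bond fixture with known expected count
#'
#' Places `n_pairs` donor/acceptor pairs on two chains at exactly known
#' geometry: `"ideal"` pairs at 0.29 nm, `"borderline"` pairs exactly at
#' the 0.35 nm cutoff (counted, since the criterion is inclusive), and
#' `"broken"` pairs at 0.40 nm (not counted). Pairs are spaced 1 nm apart
#' so no cross-pairing occurs.
#'
#' @param n_pairs Number of donor/acceptor pairs.
#' @param geometry One of `"ideal"`, `"borderline"`, `"broken"`.
#' @return A single-frame `helix_trajectory`; `metadata$truth$hbonds` is
#'   the expected count.
#' @export
make_hbond_fixture <- function(n_pairs,
                               geometry = c("ideal", "borderline",
                                            "broken")) {
  geometry <- match.arg(geometry)
  d <- switch(geometry, ideal = 0.29, borderline = 0.35, broken = 0.40)
  atoms <- list(); coords <- list()
  for (j in seq_len(n_pairs)) {
    z <- j * 1.0
    atoms[[length(atoms) + 1L]] <- data.frame(
      chain = c("A", "A", "B"), resno = j, resid = "GLY",
      elety = c("CA", "N", "O"), stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <- rbind(c(-0.1, 0, z),  # CA behind N
                                           c(0, 0, z),     # donor N
                                           c(d, 0, z))     # acceptor O
  }
  co <- do.call(rbind, coords)
  helix_trajectory(matrix(as.vector(t(co)), nrow = 1L),
                   do.call(rbind, atoms), dt = 1,
                   metadata = list(truth = list(
                     hbonds = if (geometry == "broken") 0L else n_pairs)))
}

#' Generate a random collagen-like sequence pair with ground truth
#'
#' Random Gly-Xaa-Yaa triplets with configurable imino-acid density, an
#' optionally embedded canonical collagenase cleavage motif
#' (GAPGPL-GIA-GITGAR), and an optional in-frame duplication producing the
#' mutant sequence.
#'
#' @param n_triplets Number of triplets (>= 5).
#' @param dup_spec Optional list with `aa_start`, `aa_end` (1-based
#'   positions within the generated sequence) of the run to duplicate;
#'   length must be a multiple of 3.
#' @param seed Integer seed.
#' @param p_imino Probability that a Xaa (or Yaa) slot receives Pro
#'   (default 0.4).
#' @param embed_cleavage_at Optional triplet index (1-based) at which to
#'   embed the 5-triplet cleavage motif context.
#' @return A list: `wt`, `mut` (character scalars; `mut` is `NULL` without
#'   `dup_spec`), `dup` (a `protein_dup` or `NULL`), `registry`, and
#'   `truth` (per-class tallies and the embedded site position, if any).
#' @export
make_collagen_sequences <- function(n_triplets, dup_spec = NULL, seed = 1L,
                                    p_imino = 0.4,
                                    embed_cleavage_at = NULL) {
  stopifnot(n_triplets >= 5L)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  xaa_pool <- c("A", "L", "I", "S", "E", "Q", "V", "R")
  yaa_pool <- c("A", "R", "K", "Q", "T", "D", "S")
  draw <- function(pool) {
    n <- n_triplets
    out <- character(n)
    imino <- stats::runif(n) < p_imino
    out[imino] <- "P"
    out[!imino] <- sample(pool, sum(!imino), replace = TRUE)
    out
  }
  xaa <- draw(xaa_pool); yaa <- draw(yaa_pool)
  res <- as.vector(rbind("G", xaa, yaa))
  site_start <- NULL
  if (!is.null(embed_cleavage_at)) {
    t0 <- as.integer(embed_cleavage_at)
    if (t0 < 3L || t0 + 2L > n_triplets)
      stop("motif needs two triplets of context on each side", call. = FALSE)
    motif <- strsplit("GAPGPLGIAGITGAR", "")[[1L]]
    pos <- (3L * (t0 - 3L) + 1L):(3L * (t0 + 2L))
    res[pos] <- motif
    site_start <- 3L * (t0 - 1L) + 1L
    # neutralize accidental Gly-Ile/Leu triplets outside the motif so the
    # embedded site is the unique dual-flagged candidate
    gly_pos <- seq.int(1L, length(res), by = 3L)
    clash <- gly_pos[res[gly_pos + 1L] %in% c("I", "L") &
                       (gly_pos < min(pos) | gly_pos > max(pos))]
    res[clash + 1L] <- "A"
  }
  wt <- paste(res, collapse = "")
  registry <- triple_helix_registry(1L, n_triplets)
  mut <- NULL; dup <- NULL
  if (!is.null(dup_spec)) {
    a <- as.integer(dup_spec$aa_start); b <- as.integer(dup_spec$aa_end)
    if ((b - a + 1L) %% 3L != 0L)
      stop("parameter error: duplication length must be a multiple of 3",
           call. = FALSE)
    if (a < 1L || b > length(res))
      stop("parameter error: duplication outside the sequence", call. = FALSE)
    dup <- protein_dup(a, b, paste(res[a:b], collapse = ""))
    mut <- paste(append(res, res[a:b], after = b), collapse = "")
  }
  tally <- table(factor(c("Gly", "Xaa", "Yaa")[(seq_along(res) - 1L) %% 3L
                                               + 1L], c("Gly", "Xaa", "Yaa")),
                 res)
  list(wt = wt, mut = mut, dup = dup, registry = registry,
       truth = list(site_start = site_start, class_tally = tally))
}

#' Synthetic coding sequence emulating the collagen alpha-1(III) context
#'
#' A deterministically constructed stand-in coding sequence (980 codons; it
#' is *not* the real transcript) that reproduces the local protein context
#' of the alpha-1(III) chain around the canonical collagenase cleavage
#' site: the Gly948|Ile949 scissile bond with its imino-rich upstream and
#' imino-free downstream triplets, and the Leu958-Gly963 run whose 18-nt
#' tandem duplication (c.2868_2885dupGGGTCTTGCAGGACCACC) yields
#' p.(Leu958_Gly963dup). Everywhere else the triple-helical domain is a
#' Gly-Pro-Pro repeat.
#'
#' @return A list: `cds` (character scalar), `registry` (a
#'   `helix_registry` over the synthetic helical domain), `hgvs` (the
#'   duplication descriptor placed on this sequence).
#' @export
synthetic_col3a1_cds <- function() {
  n_codons <- 980L
  domain_start <- 3L
  codon_for <- c(Gly = "GGT", Xaa = "CCT", Yaa = "CCC")
  codons <- character(n_codons)
  codons[1L] <- "ATG"; codons[2L] <- "GCT"
  p <- 3:n_codons
  cls <- c("Gly", "Xaa", "Yaa")[(p - domain_start) %% 3L + 1L]
  codons[p] <- codon_for[cls]
  context <- c(`942` = "GGA", `943` = "GCC", `944` = "CCT", `945` = "GGC",
               `946` = "CCA", `947` = "CTG", `948` = "GGT", `949` = "ATC",
               `950` = "GCT", `951` = "GGC", `952` = "ATT", `953` = "ACA",
               `954` = "GGA", `955` = "GCC", `956` = "AGG", `957` = "GGT",
               `958` = "CTT", `959` = "GCA", `960` = "GGA", `961` = "CCA",
               `962` = "CCG", `963` = "GGT")
  codons[as.integer(names(context))] <- context
  list(cds = paste(codons, collapse = ""),
       registry = triple_helix_registry(domain_start, 323L),
       hgvs = "SYNTH_COL3A1:c.2868_2885dupGGGTCTTGCAGGACCACC")
}
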