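# shared fixtures, built in code

# the synthetic alpha-1(III)-context CDS and its derived objects
col3 <- synthetic_col3a1_cds()
col3_prot <- triplehelix:::cds_to_protein(col3$cds)
col3_dup <- project_to_protein(parse_dup(col3$hgvs), col3$cds)

# a small random CDS with in-frame codons only (no stops)
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  codons <- c("GCT", "TGT", "GAT", "GAA", "TTT", "GGT", "CAT", "ATT",
              "AAA", "CTG", "ATG", "AAT", "CCT", "CAA", "CGT", "AGT",
              "ACT", "GTT", "TGG", "TAT")
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# three-point circumcircle closed form (independent oracle)
circumcircle <- function(p) {
  ax <- p[1, 1]; ay <- p[1, 2]; bx <- p[2, 1]; by <- p[2, 2]
  cx <- p[3, 1]; cy <- p[3, 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), r = sqrt((ax - ux)^2 + (ay - uy)^2))
}

# a well-separated random triple (regenerates until non-degenerate)
random_triple <- function() {
  repeat {
    p <- matrix(stats::runif(6, 0, 10), 3, 2)
    area <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                  (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
    if (area > 1) return(p)
  }
}

# minimal hand-made trajectory: given list of n_atoms x 3 frames
toy_traj <- function(frames, atoms, dt = 100) {
  xyz <- do.call(rbind, lapply(frames, function(m) as.vector(t(m))))
  helix_trajectory(xyz, atoms, dt = dt)
}

gpp_chain <- function(n_triplets)
  paste(rep(c("G", "P", "P"), n_triplets), collapse = "")
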