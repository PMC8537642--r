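# Independent oracles and fixture builders used across the suite.  These
# deliberately avoid the package's own code paths (quaternion instead of SVD
# superposition, explicit loops instead of vectorised set logic).

# Optimal-superposition RMSD by the Horn/Kearsley quaternion method: the
# largest eigenvalue of the 4x4 key matrix gives the residual directly.
quaternion_rmsd <- function(mobile, target) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(target, 2, colMeans(target))
  S <- t(A) %*% B
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(A^2) + sum(B^2) - 2 * lambda) / nrow(A)))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
    2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
    2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Brute-force cross-chain residue contact pairs by explicit atom-pair loops.
brute_contact_pairs <- function(cs, cutoff) {
  ag <- cs$atoms[cs$atoms$chain == cs$antigen_chain, ]
  nb <- cs$atoms[cs$atoms$chain == cs$nanobody_chain, ]
  akey <- paste0(ag$chain, ":", ag$resno, ifelse(ag$ins == "", "", ag$ins))
  hkey <- paste0(nb$chain, ":", nb$resno, ifelse(nb$ins == "", "", nb$ins))
  pairs <- character(0)
  for (i in seq_len(nrow(ag))) {
    for (j in seq_len(nrow(nb))) {
      d <- sqrt((ag$x[i]-nb$x[j])^2 + (ag$y[i]-nb$y[j])^2 + (ag$z[i]-nb$z[j])^2)
      if (d <= cutoff) pairs <- c(pairs, paste0(akey[i], "||", hkey[j]))
    }
  }
  sort(unique(pairs))
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the absolute differences.
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.numeric(signs %*% r)
  p_le <- mean(Vs <= V)
  p_ge <- mean(Vs >= V)
  min(1, 2 * min(p_le, p_ge))
}

# Average precision by an explicit loop over every distinct threshold.
brute_pr_auc <- function(labels, scores) {
  npos <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0; area <- 0
  for (t in th) {
    sel <- scores >= t
    precision <- sum(labels[sel] == 1) / sum(sel)
    recall <- sum(labels[sel] == 1) / npos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Minimal hand-rolled PDB writer for fixtures (wwPDB fixed columns).
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     element = substr(trimws(name), 1, 1), record = "ATOM",
                     ins = " ", altloc = " ") {
  nm <- if (nchar(trimws(name)) < 4) sprintf(" %-3s", trimws(name)) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altloc, resname, chain, resno, ins, x, y, z,
          1.00, 0.00, element)
}

# A small 2-chain fixture: 3 antigen residues (chain A, incl. one MSE
# HETATM), 3 nanobody residues (chain H), with hydrogens, a water and a
# second altloc that readers must drop.
write_fixture_pdb <- function(path) {
  lines <- c(
    pdb_line(1, "N",  "ALA", "A", 1, 0.0, 0.0, 0.0),
    pdb_line(2, "CA", "ALA", "A", 1, 1.5, 0.0, 0.0, element = "C"),
    pdb_line(3, "C",  "ALA", "A", 1, 2.2, 1.3, 0.0),
    pdb_line(4, "O",  "ALA", "A", 1, 1.7, 2.4, 0.0),
    pdb_line(5, "HA", "ALA", "A", 1, 1.6, -1.0, 0.0, element = "H"),
    pdb_line(6, "N",  "GLY", "A", 2, 3.5, 1.2, 0.0),
    pdb_line(7, "CA", "GLY", "A", 2, 4.4, 2.3, 0.0, element = "C"),
    pdb_line(8, "CA", "GLY", "A", 2, 4.9, 2.9, 0.4, element = "C", altloc = "B"),
    pdb_line(9, "C",  "GLY", "A", 2, 5.8, 1.8, 0.0),
    pdb_line(10, "N",  "MSE", "A", 3, 6.8, 2.7, 0.0, record = "HETATM"),
    pdb_line(11, "CA", "MSE", "A", 3, 8.2, 2.4, 0.0, element = "C", record = "HETATM"),
    pdb_line(12, "SE", "MSE", "A", 3, 9.1, 3.9, 0.2, element = "SE", record = "HETATM"),
    pdb_line(13, "N",  "CYS", "H", 1, 0.0, 6.0, 0.0),
    pdb_line(14, "CA", "CYS", "H", 1, 1.4, 6.2, 0.0, element = "C"),
    pdb_line(15, "SG", "CYS", "H", 1, 2.2, 7.6, 0.6, element = "S"),
    pdb_line(16, "H",  "CYS", "H", 1, -0.5, 6.8, 0.0, element = "H"),
    pdb_line(17, "N",  "TRP", "H", 2, 2.9, 5.1, 0.0),
    pdb_line(18, "CA", "TRP", "H", 2, 4.3, 5.3, 0.0, element = "C"),
    pdb_line(19, "CB", "TRP", "H", 2, 5.0, 4.0, 0.3, element = "C"),
    pdb_line(20, "N",  "TYR", "H", 3, 6.4, 6.1, 0.0),
    pdb_line(21, "CA", "TYR", "H", 3, 7.8, 6.3, 0.0, element = "C"),
    pdb_line(22, "OH", "TYR", "H", 3, 8.6, 7.5, 0.4, element = "O"),
    pdb_line(23, "O",  "HOH", "A", 90, 20.0, 20.0, 20.0, record = "HETATM"),
    "END"
  )
  writeLines(lines, path)
  invisible(path)
}

# Build a bare complex_structure from per-residue CA-style atom tables.
toy_complex <- function(ag_xyz, nb_xyz, ag_resid = NULL, nb_resid = NULL) {
  mk <- function(xyz, chain, resid) {
    n <- nrow(xyz)
    if (is.null(resid)) resid <- rep("ALA", n)
    data.frame(chain = chain, resno = seq_len(n), ins = "", resid = resid,
               elety = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }
  nbrank:::new_complex_structure(rbind(mk(ag_xyz, "A", ag_resid),
                                       mk(nb_xyz, "H", nb_resid)), "A", "H")
}

# Toy labelled dataset on the contact-only schema: one informative column
# (n_paratope) separates the classes; everything else is noise.
toy_dataset <- function(n_complexes = 6, poses_per_complex = 8, seed = 42,
                        separation = 4) {
  set.seed(seed)
  schema <- feature_schema("contact")
  n <- n_complexes * poses_per_complex
  label <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * length(schema$columns), sd = 0.3), n,
              dimnames = list(NULL, schema$columns))
  X[, "n_paratope"] <- X[, "n_paratope"] + separation * label
  meta <- data.frame(
    complex_id = rep(sprintf("C%02d", seq_len(n_complexes)), each = poses_per_complex),
    docking_mode = "default",
    parent_id = rep(sprintf("P%02d", seq_len(poses_per_complex)), n_complexes),
    refined_id = sprintf("R%03d", seq_len(n)),
    dockq = ifelse(label == 1, 0.6, 0.05),
    label = label,
    stringsAsFactors = FALSE
  )
  pose_dataset(meta, X, schema)
}
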