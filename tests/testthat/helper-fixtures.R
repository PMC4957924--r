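## Shared fixture builders and independent oracles.

AA20 <- ptpscreen:::AA20

## Random 11-mer windows with central Y, flanks uniform over the 20 AA.
rand_windows <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    fl <- sample(AA20, 10, replace = TRUE)
    paste0(paste(fl[1:5], collapse = ""), "Y", paste(fl[6:10], collapse = ""))
  }, character(1))
}

## Windows enriched for a simple planted motif (acidic N-terminal flank).
motif_windows <- function(n, strength = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    left <- ifelse(runif(5) < strength, sample(c("D", "E"), 5, replace = TRUE),
                   sample(AA20, 5, replace = TRUE))
    right <- ifelse(runif(5) < strength / 2,
                    sample(c("E", "V"), 5, replace = TRUE),
                    sample(AA20, 5, replace = TRUE))
    paste0(paste(left, collapse = ""), "Y", paste(right, collapse = ""))
  }, character(1))
}

## Brute-force method-1 score: explicit loop over the 10 height lookups.
brute_logo_score <- function(peptide, logo) {
  chars <- strsplit(peptide, "")[[1]]
  pos <- c(-5:-1, 1:5)
  idx <- c(1:5, 7:11)
  s <- 0
  for (k in seq_along(idx)) {
    a <- chars[idx[k]]
    if (a != "-") s <- s + logo[a, as.character(pos[k])]
  }
  s
}

## Brute-force method-2 score from the raw frequency matrices.
brute_pssm_score <- function(peptide, pssm, alpha) {
  chars <- strsplit(peptide, "")[[1]]
  pos <- c(-5:-1, 1:5)
  idx <- c(1:5, 7:11)
  s <- 0
  for (k in seq_along(idx)) {
    a <- chars[idx[k]]
    j <- as.character(pos[k])
    ft <- pssm$total[a, j]
    if (ft == 0) next
    s <- s + log2((pssm$positive[a, j] + alpha * ft) /
                  (pssm$negative[a, j] + alpha * ft))
  }
  s
}

## Independent rigid-body superposition oracle: Horn's closed-form
## quaternion method.  Returns the rotation R (fitted = P0 %*% t(R)) and
## the least-squares RMSD of P onto Q.
quaternion_superpose <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(P0, Q0)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2
  ), 3, 3, byrow = TRUE)
  fitted <- P0 %*% t(R)
  list(rotation = R, rmsd = sqrt(mean(rowSums((fitted - Q0)^2))))
}

## Rotation about the z axis by `deg` degrees.
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

## Apply a rigid motion to every atom of a pose.
transform_pose <- function(pose, R, t) {
  xyz <- as.matrix(pose$atoms[, c("x", "y", "z")])
  pose$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, t, `+`)
  pose
}

## Write a small synthetic world (proteome + positives TSV) and return a
## run_config for it.
synthetic_run_config <- function(dir, spec = ptpscreen::motif_spec(seed = 11),
                                 q = 0.25, seed = 11) {
  pr <- ptpscreen::generate_proteome(spec, dir = dir)
  pos <- pr$truth[pr$truth$planted, c("protein_id", "position")]
  pos$residue <- "Y"
  write.table(pos, file.path(dir, "positives.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(
    proteome = pr,
    config = ptpscreen::run_config(
      fasta = file.path(dir, "proteome.fasta"),
      sites = file.path(dir, "sites.tsv"),
      positive_sites = file.path(dir, "positives.tsv"),
      out_dir = file.path(dir, "out"), q = q, seed = seed
    )
  )
}
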