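## Geometric acceptance criteria for docked phosphatase-peptide poses:
## (i) the phosphotyrosine inserts into the catalytic pocket, (ii) the
## peptide N-to-C orientation matches the reference complex, and (iii) at
## least two of the three key hydrogen bonds are formed (Asp-48 side-chain
## oxygens to the backbone N of pY and of pY+1; Arg-47 backbone N to the
## backbone O of pY-2).

#' Residue names recognised as phosphotyrosine
#' @export
PY_RESNAMES <- c("PTR", "PTY", "YPO", "TPO", "PY")

#' Construct a phosphatase-peptide complex pose
#'
#' @param atoms Data frame with columns \code{elety} (atom name),
#'   \code{resid} (residue name), \code{resno}, \code{chain}, \code{x},
#'   \code{y}, \code{z} (angstrom).
#' @param phos_chain,pep_chain Chain identifiers of the phosphatase and of
#'   the peptide.
#' @param py_resno Residue number of the phosphotyrosine on the peptide
#'   chain; inferred from residue names in [PY_RESNAMES] when NULL.
#' @return An object of class \code{complex_pose}.
#' @export
complex_pose <- function(atoms, phos_chain, pep_chain, py_resno = NULL) {
  need <- c("elety", "resid", "resno", "chain", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  }
  if (!phos_chain %in% atoms$chain) stop("phosphatase chain absent: ", phos_chain)
  if (!pep_chain %in% atoms$chain) stop("peptide chain absent: ", pep_chain)
  pep <- atoms[atoms$chain == pep_chain, , drop = FALSE]
  if (is.null(py_resno)) {
    hit <- unique(pep$resno[pep$resid %in% PY_RESNAMES])
    if (length(hit) != 1L) {
      stop("could not infer a unique phosphotyrosine residue on chain ",
           pep_chain, "; pass py_resno")
    }
    py_resno <- hit
  }
  has_p <- any(pep$resno == py_resno & pep$elety == "P")
  if (!has_p) stop("phosphotyrosine residue ", py_resno,
                   " has no phosphorus atom")
  structure(list(atoms = atoms, phos_chain = phos_chain,
                 pep_chain = pep_chain, py_resno = as.integer(py_resno)),
            class = "complex_pose")
}

#' Read a docked complex pose from a PDB file
#'
#' Single-model PDB; ATOM and HETATM records are kept (phosphotyrosine is
#' often a HETATM residue).
#'
#' @inheritParams complex_pose
#' @param path PDB file path.
#' @return A \code{complex_pose}.
#' @export
read_pose_pdb <- function(path, phos_chain = "A", pep_chain = "B",
                          py_resno = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(elety = at$elety, resid = at$resid,
                      resno = at$resno, chain = at$chain,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  complex_pose(atoms, phos_chain, pep_chain, py_resno)
}

#' Designate a pose as the reference complex
#'
#' @param pose A \code{complex_pose} (e.g. a crystallographic
#'   phosphatase-peptide complex).
#' @param pocket_resnos Residue numbers of the catalytic pocket on the
#'   phosphatase chain; default 214:221, the phosphate-binding P-loop of
#'   PTP1B.
#' @param asp_resno,arg_resno Residue numbers of the aspartate whose
#'   side-chain carboxylate accepts H-bonds 1-2 and of the arginine whose
#'   backbone N donates H-bond 3 (PTP1B: Asp-48, Arg-47).
#' @return An object of class \code{reference_complex}.
#' @export
reference_complex <- function(pose, pocket_resnos = 214:221,
                              asp_resno = 48, arg_resno = 47) {
  stopifnot(inherits(pose, "complex_pose"))
  phos <- pose$atoms[pose$atoms$chain == pose$phos_chain, , drop = FALSE]
  missing_res <- setdiff(c(asp_resno, arg_resno), phos$resno)
  if (length(missing_res) > 0L) {
    stop("reference lacks phosphatase residue(s): ",
         paste(missing_res, collapse = ", "))
  }
  if (!any(phos$resno %in% pocket_resnos & phos$elety == "CA")) {
    stop("reference has no CA atoms in the catalytic pocket residues")
  }
  structure(c(pose, list(pocket_resnos = as.integer(pocket_resnos),
                         asp_resno = as.integer(asp_resno),
                         arg_resno = as.integer(arg_resno))),
            class = c("reference_complex", "complex_pose"))
}

## Kabsch least-squares superposition: returns the proper rotation R and
## translation t minimising || P R^T + t - Q ||.
kabsch <- function(P, Q) {
  cP <- unname(colMeans(P))
  cQ <- unname(colMeans(Q))
  P0 <- sweep(P, 2, cP)
  Q0 <- sweep(Q, 2, cQ)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cQ - as.numeric(R %*% cP)
  list(rotation = R, translation = t)
}

pose_xyz <- function(pose, sel) {
  as.matrix(pose$atoms[sel, c("x", "y", "z"), drop = FALSE])
}

## Matched phosphatase CA coordinates of pose and reference, by residue
## number.
shared_ca <- function(pose, reference) {
  pa <- pose$atoms
  ra <- reference$atoms
  p_ca <- pa$chain == pose$phos_chain & pa$elety == "CA"
  r_ca <- ra$chain == reference$phos_chain & ra$elety == "CA"
  shared <- intersect(pa$resno[p_ca], ra$resno[r_ca])
  list(
    resnos = shared,
    P = pose_xyz(pose, which(p_ca)[match(shared, pa$resno[p_ca])]),
    Q = pose_xyz(reference, which(r_ca)[match(shared, ra$resno[r_ca])])
  )
}

#' Superpose a pose onto the reference by phosphatase C-alpha atoms
#'
#' Least-squares rigid-body fit (Kabsch) over phosphatase CA atoms shared
#' by residue number; the whole pose is transformed.
#'
#' @param mobile A \code{complex_pose}.
#' @param reference A \code{reference_complex}.
#' @return List with the transformed \code{pose}, \code{rotation} (proper,
#'   det +1), \code{translation} and the CA \code{rmsd} (angstrom).
#' @export
superpose_pose <- function(mobile, reference) {
  sh <- shared_ca(mobile, reference)
  if (length(sh$resnos) < 3L) {
    stop("need at least 3 shared phosphatase CA atoms; found ",
         length(sh$resnos))
  }
  fit <- kabsch(sh$P, sh$Q)
  xyz <- as.matrix(mobile$atoms[, c("x", "y", "z")])
  moved <- sweep(xyz %*% t(fit$rotation), 2, fit$translation, `+`)
  out <- mobile
  out$atoms[, c("x", "y", "z")] <- moved
  fitted <- sweep(sh$P %*% t(fit$rotation), 2, fit$translation, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - sh$Q)^2)))
  list(pose = out, rotation = fit$rotation, translation = fit$translation,
       rmsd = rmsd)
}

atom_xyz <- function(pose, chain, resno, elety) {
  a <- pose$atoms
  sel <- a$chain == chain & a$resno == resno & a$elety == elety
  if (!any(sel)) return(NULL)
  as.numeric(a[which(sel)[1L], c("x", "y", "z")])
}

#' Criterion (i): does the phosphotyrosine point into the catalytic site?
#'
#' Measured as the distance from the phosphorus atom of the pY residue to
#' the centroid of the reference catalytic-pocket CA atoms; the pose must
#' already be superposed onto the reference.
#'
#' @param pose A superposed \code{complex_pose}.
#' @param reference A \code{reference_complex}.
#' @param cutoff Acceptance distance in angstrom, inclusive; default 7.
#' @return List: \code{ok} (logical) and \code{distance} (angstrom).
#' @export
check_py_in_site <- function(pose, reference, cutoff = 7) {
  p <- atom_xyz(pose, pose$pep_chain, pose$py_resno, "P")
  if (is.null(p)) stop("pY residue has no phosphorus atom")
  ra <- reference$atoms
  sel <- ra$chain == reference$phos_chain & ra$elety == "CA" &
    ra$resno %in% reference$pocket_resnos
  centroid <- colMeans(pose_xyz(reference, sel))
  d <- sqrt(sum((p - centroid)^2))
  list(ok = d <= cutoff, distance = d)
}

## CA->CA vector across the pY, at +/-2 with fallback to +/-1.
peptide_vector <- function(pose, py_resno = NULL) {
  if (is.null(py_resno)) py_resno <- pose$py_resno
  for (off in c(2L, 1L)) {
    a <- atom_xyz(pose, pose$pep_chain, py_resno - off, "CA")
    b <- atom_xyz(pose, pose$pep_chain, py_resno + off, "CA")
    if (!is.null(a) && !is.null(b)) return(b - a)
  }
  stop("peptide too short: no CA pair at pY+/-2 or pY+/-1")
}

#' Criterion (ii): does the peptide N-to-C orientation match the reference?
#'
#' Compares the CA(pY-2) to CA(pY+2) vector of the superposed pose with the
#' corresponding vector of the reference peptide; accepted when the angle
#' between them is strictly below 90 degrees.
#'
#' @inheritParams check_py_in_site
#' @return List: \code{ok} (logical) and \code{angle} (degrees).
#' @export
check_orientation <- function(pose, reference) {
  v <- peptide_vector(pose)
  w <- peptide_vector(reference)
  cosang <- sum(v * w) / (sqrt(sum(v^2)) * sqrt(sum(w^2)))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  list(ok = ang < 90, angle = ang)
}

#' Criterion (iii): detect the three key hydrogen bonds
#'
#' Heavy-atom donor-acceptor distances only (docked poses usually carry no
#' hydrogens):
#' \itemize{
#'   \item bond 1: nearest Asp side-chain oxygen (OD1/OD2) to the backbone
#'     N of the pY residue;
#'   \item bond 2: nearest Asp side-chain oxygen to the backbone N of
#'     residue pY+1;
#'   \item bond 3: Arg backbone N to the backbone O of residue pY-2.
#' }
#' A bond whose atoms are missing is reported absent with a reason rather
#' than raising an error.
#'
#' @inheritParams check_py_in_site
#' @param dmax Donor-acceptor distance cutoff in angstrom, inclusive;
#'   default 3.5.
#' @return Data frame with one row per bond: \code{bond}, \code{present},
#'   \code{distance}, \code{reason}.
#' @export
detect_hbonds <- function(pose, reference, dmax = 3.5) {
  asp <- reference$asp_resno
  arg <- reference$arg_resno
  od1 <- atom_xyz(pose, pose$phos_chain, asp, "OD1")
  od2 <- atom_xyz(pose, pose$phos_chain, asp, "OD2")
  ods <- Filter(Negate(is.null), list(od1, od2))

  min_od_dist <- function(n_xyz) {
    if (is.null(n_xyz) || length(ods) == 0L) return(NA_real_)
    min(vapply(ods, function(o) sqrt(sum((o - n_xyz)^2)), numeric(1)))
  }

  n_py <- atom_xyz(pose, pose$pep_chain, pose$py_resno, "N")
  n_p1 <- atom_xyz(pose, pose$pep_chain, pose$py_resno + 1L, "N")
  o_m2 <- atom_xyz(pose, pose$pep_chain, pose$py_resno - 2L, "O")
  n_arg <- atom_xyz(pose, pose$phos_chain, arg, "N")

  d1 <- min_od_dist(n_py)
  d2 <- min_od_dist(n_p1)
  d3 <- if (is.null(n_arg) || is.null(o_m2)) NA_real_ else
    sqrt(sum((n_arg - o_m2)^2))

  reason <- function(d, what) {
    if (is.na(d)) paste0("missing atom(s) for ", what) else ""
  }
  data.frame(
    bond = c("asp_to_pY_N", "asp_to_pYplus1_N", "arg_N_to_pYminus2_O"),
    present = c(!is.na(d1) && d1 <= dmax,
                !is.na(d2) && d2 <= dmax,
                !is.na(d3) && d3 <= dmax),
    distance = c(d1, d2, d3),
    reason = c(reason(d1, "bond 1"), reason(d2, "bond 2"),
               reason(d3, "bond 3")),
    stringsAsFactors = FALSE
  )
}

#' Evaluate a docked pose against all three acceptance criteria
#'
#' Superposes the pose on the reference by the phosphatase CA atoms, then
#' applies: (i) pY phosphorus within \code{cutoff} of the catalytic-pocket
#' centroid; (ii) peptide orientation angle below 90 degrees; (iii) at
#' least two of the three key hydrogen bonds within \code{dmax}.  The pose
#' is accepted iff (i) and (ii) hold and at least two bonds are present.
#'
#' @param pose A \code{complex_pose} (any frame; superposition is applied).
#' @param reference A \code{reference_complex}.
#' @param cutoff Pocket distance cutoff (angstrom); default 7.
#' @param dmax Hydrogen-bond distance cutoff (angstrom); default 3.5.
#' @return An object of class \code{pose_evaluation}: a list with
#'   \code{py_in_site}, \code{py_distance}, \code{orientation_ok},
#'   \code{orientation_angle}, \code{hbonds} (data frame),
#'   \code{n_hbonds}, \code{superposition_rmsd} and \code{accepted}.
#' @export
evaluate_pose <- function(pose, reference, cutoff = 7, dmax = 3.5) {
  sup <- superpose_pose(pose, reference)
  moved <- sup$pose
  site <- check_py_in_site(moved, reference, cutoff)
  ori <- check_orientation(moved, reference)
  hb <- detect_hbonds(moved, reference, dmax)
  n_hb <- sum(hb$present)
  structure(list(
    py_in_site = site$ok, py_distance = site$distance,
    orientation_ok = ori$ok, orientation_angle = ori$angle,
    hbonds = hb, n_hbonds = n_hb,
    superposition_rmsd = sup$rmsd,
    accepted = site$ok && ori$ok && n_hb >= 2L
  ), class = "pose_evaluation")
}

#' Print a pose evaluation
#' @param x A \code{pose_evaluation}.
#' @param ... Ignored.
#' @return \code{x}, invisibly.
#' @method print pose_evaluation
#' @export
print.pose_evaluation <- function(x, ...) {
  cat(sprintf(
    "pose evaluation: %s\n  pY-pocket distance %.2f A (in site: %s)\n  orientation angle %.1f deg (ok: %s)\n  hydrogen bonds: %d of 3\n",
    if (x$accepted) "ACCEPTED" else "rejected",
    x$py_distance, x$py_in_site, x$orientation_angle, x$orientation_ok,
    x$n_hbonds))
  invisible(x)
}

#' Evaluate a directory or list of pose PDB files
#'
#' Unreadable files are skipped with a warning; an error is raised only if
#' every file fails.
#'
#' @param paths Character vector of PDB paths, or a directory.
#' @param reference A \code{reference_complex}.
#' @param ... Passed to [evaluate_pose()] and [read_pose_pdb()].
#' @param phos_chain,pep_chain Chain ids used when reading each pose.
#' @return Data frame, one row per readable pose, sorted by accepted status
#'   then pocket distance.
#' @export
evaluate_pose_files <- function(paths, reference, phos_chain = "A",
                                pep_chain = "B", ...) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.pdb$", full.names = TRUE)
  }
  rows <- lapply(paths, function(p) {
    ev <- tryCatch({
      pose <- read_pose_pdb(p, phos_chain = phos_chain,
                            pep_chain = pep_chain)
      evaluate_pose(pose, reference, ...)
    }, error = function(e) {
      warning("skipping pose ", p, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(ev)) return(NULL)
    data.frame(pose = basename(p),
               py_distance = ev$py_distance,
               orientation_angle = ev$orientation_angle,
               n_hbonds = ev$n_hbonds,
               py_in_site = ev$py_in_site,
               orientation_ok = ev$orientation_ok,
               accepted = ev$accepted,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stop("no readable poses among ", length(paths),
                               " file(s)")
  out <- do.call(rbind, rows)
  out <- out[order(-out$accepted, out$py_distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
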