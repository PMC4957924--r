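## Synthetic fixtures: motif-planted proteomes with pY annotations for the
## scoring pipeline, and idealised phosphatase-peptide poses for the
## geometric criteria.  The generator emulates the statistical structure
## the scoring assumes -- a positive motif class around the central pY
## (acidic residues N-terminal to the site, as in known PTP1B substrate
## peptides such as EEEDIpYEVLPD) against a tyrosine background class.

#' Human-proteome-like amino-acid background frequencies
#'
#' Approximate relative frequencies of the 20 amino acids in the human
#' proteome (UniProt proteome-wide statistics, rounded); available as an
#' alternative to the uniform default of [motif_spec()].
#' @export
HUMAN_AA_FREQS <- c(
  A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.037, G = 0.066,
  H = 0.026, I = 0.043, K = 0.057, L = 0.100, M = 0.021, N = 0.036,
  P = 0.063, Q = 0.048, R = 0.056, S = 0.083, T = 0.054, V = 0.060,
  W = 0.012, Y = 0.027
)

#' Specification of a synthetic motif-planted proteome
#'
#' Positive (planted) pY sites draw each flank residue from a per-position
#' mixture: with probability equal to the position's enrichment weight, a
#' residue uniform over the preferred set; otherwise a residue from the
#' background distribution.  Decoy pY sites are annotated but have
#' background flanks; background proteins carry no annotation and supply
#' the negative class.  The default motif is strongly acidic N-terminal to
#' the pY with a milder preference C-terminal, echoing known substrate
#' peptides of tyrosine phosphatases.
#'
#' @param motif Named list over flank positions (\code{"-5"..."-1"},
#'   \code{"1"..."5"}); each element a list with \code{residues}
#'   (character) and \code{weight} in [0,1].  Positions absent from the
#'   list use the background distribution.
#' @param background Named numeric over the 20 amino acids, summing to 1;
#'   default uniform.
#' @param n_positive_sites,n_decoy_sites Numbers of annotated planted and
#'   decoy pY sites (one per protein).
#' @param n_background_proteins Number of unannotated proteins.
#' @param protein_length Length-2 integer range of protein lengths.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class \code{motif_spec}.
#' @export
motif_spec <- function(motif = NULL,
                       background = NULL,
                       n_positive_sites = 60L,
                       n_decoy_sites = 240L,
                       n_background_proteins = 120L,
                       protein_length = c(150L, 250L),
                       seed = 1L) {
  if (is.null(motif)) {
    acidic <- list(residues = c("D", "E"), weight = 0.7)
    mild <- list(residues = c("E", "V", "L"), weight = 0.5)
    motif <- list(`-5` = acidic, `-4` = acidic, `-3` = acidic,
                  `-2` = acidic, `-1` = acidic, `1` = mild, `2` = mild)
  }
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA20)
  }
  background <- background[AA20]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-6 ||
      any(background < 0)) {
    stop("background must be a non-negative distribution over the 20 amino acids")
  }
  bad_pos <- setdiff(names(motif), as.character(FLANK_POSITIONS))
  if (length(bad_pos) > 0L) {
    stop("motif positions must be -5..-1 or 1..5; got: ",
         paste(bad_pos, collapse = ", "))
  }
  for (m in motif) {
    if (!all(m$residues %in% AA20) || m$weight < 0 || m$weight > 1) {
      stop("motif entries need residues in the 20-letter alphabet and weight in [0,1]")
    }
  }
  protein_length <- as.integer(protein_length)
  if (length(protein_length) != 2L || any(protein_length < WINDOW_WIDTH)) {
    stop("protein_length must be a range with minimum >= ", WINDOW_WIDTH)
  }
  structure(list(motif = motif, background = background,
                 n_positive_sites = as.integer(n_positive_sites),
                 n_decoy_sites = as.integer(n_decoy_sites),
                 n_background_proteins = as.integer(n_background_proteins),
                 protein_length = protein_length,
                 seed = as.integer(seed)),
            class = "motif_spec")
}

sample_background <- function(n, spec) {
  sample(AA20, n, replace = TRUE, prob = spec$background)
}

## Draw the 10 flank residues of one site from the motif mixture.
sample_flanks <- function(spec, planted) {
  vapply(as.character(FLANK_POSITIONS), function(pos) {
    m <- spec$motif[[pos]]
    if (planted && !is.null(m) && stats::runif(1) < m$weight) {
      sample(m$residues, 1L)
    } else {
      sample_background(1L, spec)
    }
  }, character(1))
}

#' Generate a synthetic proteome with planted and decoy pY sites
#'
#' Deterministic given the spec (including its seed).  Each annotated site
#' sits on its own protein at an interior position, so every annotated
#' window is a full 11-mer; background proteins contribute unannotated
#' tyrosines for the negative class.
#'
#' @param spec A [motif_spec()].
#' @param dir Optional output directory; when given, writes
#'   \code{proteome.fasta}, \code{sites.tsv} and \code{truth.tsv}.
#' @return List of class \code{synthetic_proteome}: \code{proteins}
#'   (\code{protein_set}), \code{sites} (annotation data frame), and
#'   \code{truth} (one row per annotated site with its 11-mer
#'   \code{peptide} and logical \code{planted} label).
#' @export
generate_proteome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "motif_spec"))
  set.seed(spec$seed)
  n_ann <- spec$n_positive_sites + spec$n_decoy_sites
  planted <- rep(c(TRUE, FALSE), c(spec$n_positive_sites, spec$n_decoy_sites))

  make_protein <- function(len) {
    paste(sample_background(len, spec), collapse = "")
  }
  lens <- sample(seq(spec$protein_length[1], spec$protein_length[2]),
                 n_ann + spec$n_background_proteins, replace = TRUE)

  ids <- sprintf("SP%04d", seq_len(n_ann + spec$n_background_proteins))
  genes <- sprintf("GENE%04d", seq_len(n_ann + spec$n_background_proteins))
  seqs <- character(n_ann + spec$n_background_proteins)
  positions <- integer(n_ann)

  for (k in seq_len(n_ann)) {
    base <- make_protein(lens[k])
    pos <- sample(seq(CENTER_OFFSET, lens[k] - 5L), 1L)
    fl <- sample_flanks(spec, planted[k])
    window <- paste0(paste(fl[1:5], collapse = ""), "Y",
                     paste(fl[6:10], collapse = ""))
    substr(base, pos - 5L, pos + 5L) <- window
    seqs[k] <- base
    positions[k] <- pos
  }
  for (k in seq_len(spec$n_background_proteins)) {
    seqs[n_ann + k] <- make_protein(lens[n_ann + k])
  }

  proteins <- as_protein_set(ids, genes, seqs)
  sites <- data.frame(protein_id = ids[seq_len(n_ann)],
                      position = positions, residue = "Y",
                      stringsAsFactors = FALSE)
  truth <- data.frame(
    protein_id = sites$protein_id, position = sites$position,
    gene = genes[seq_len(n_ann)],
    peptide = vapply(seq_len(n_ann), function(k) {
      window_at(seqs[k], positions[k])
    }, character(1)),
    planted = planted, stringsAsFactors = FALSE
  )

  out <- structure(list(proteins = proteins, sites = sites, truth = truth),
                   class = "synthetic_proteome")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(proteins, file.path(dir, "proteome.fasta"))
    utils::write.table(sites, file.path(dir, "sites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

#' Generate synthetic substrate and pathway tables for the filters
#'
#' Builds a small phosphatase-substrate world around an anchor phosphatase
#' and GMT-style pathway collections in which a chosen fraction of genes
#' co-occur with the anchor gene.  Intended for exercising
#' [passes_filters()] end to end.
#'
#' @param genes Character vector of candidate gene ids.
#' @param anchor,anchor_gene Anchor phosphatase and its gene id.
#' @param substrate_fraction Fraction of genes made substrates of the
#'   anchor or of a related phosphatase.
#' @param pathway_fraction Fraction of genes placed in a pathway with the
#'   anchor gene.
#' @param seed Integer seed.
#' @return List with \code{substrates} (a \code{substrate_table}) and
#'   \code{pathways} (named list of \code{pathway_sets}).
#' @export
generate_filter_tables <- function(genes, anchor = "PTP1B",
                                   anchor_gene = "PTPN1",
                                   substrate_fraction = 0.2,
                                   pathway_fraction = 0.2, seed = 1L) {
  set.seed(as.integer(seed))
  genes <- toupper(genes)
  n <- length(genes)
  sub_genes <- sample(genes, max(1L, round(substrate_fraction * n)))
  half <- seq_len(ceiling(length(sub_genes) / 2))
  tab <- data.frame(
    phosphatase = c(rep(anchor, length(half)),
                    rep("PTPRX", length(sub_genes) - length(half)),
                    "PTPRX"),
    substrate_gene = c(sub_genes[half], sub_genes[-half], sub_genes[1L]),
    stringsAsFactors = FALSE
  )
  path_genes <- sample(genes, max(1L, round(pathway_fraction * n)))
  kegg <- structure(list(hsa0001 = sort(unique(c(path_genes, anchor_gene)))),
                    class = "pathway_sets")
  pid <- structure(list(pid_insulin = sort(unique(
    c(sample(genes, max(1L, round(pathway_fraction * n / 2))), anchor_gene)
  ))), class = "pathway_sets")
  list(substrates = read_substrate_table(tab),
       pathways = list(KEGG = kegg, PID = pid))
}

#' Write a substrate table and pathway sets to disk
#'
#' @param tables Output of [generate_filter_tables()].
#' @param dir Output directory; writes \code{substrates.tsv} and one
#'   \code{<collection>.gmt} per pathway collection.
#' @return \code{dir}, invisibly.
#' @export
write_filter_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sub <- do.call(rbind, lapply(names(tables$substrates), function(p) {
    data.frame(phosphatase = p, substrate_gene = tables$substrates[[p]],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(sub, file.path(dir, "substrates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (cn in names(tables$pathways)) {
    lines <- vapply(names(tables$pathways[[cn]]), function(pw) {
      paste(c(pw, "synthetic pathway", tables$pathways[[cn]][[pw]]),
            collapse = "\t")
    }, character(1))
    writeLines(lines, file.path(dir, paste0(cn, ".gmt")))
  }
  invisible(dir)
}

## ---- toy poses --------------------------------------------------------

toy_atom <- function(elety, resid, resno, chain, xyz) {
  data.frame(elety = elety, resid = resid, resno = resno, chain = chain,
             x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
}

#' Generate an idealised phosphatase-peptide pose
#'
#' Constructs a minimal phosphatase fragment (catalytic-loop residues
#' 214-221, the H-bond arginine 47 and aspartate 48 with its side-chain
#' oxygens) and a 5-residue peptide whose central residue is a
#' phosphotyrosine, placed so that each requested criterion holds with at
#' least 0.5 angstrom (or 90 degree) margin and each unrequested one fails
#' with at least the same margin, at the default thresholds of
#' [evaluate_pose()].  Geometry is schematic: only the criteria-relevant
#' atoms are meaningful.
#'
#' @param py_in_site Place the pY phosphorus inside the pocket (criterion
#'   i).
#' @param orientation Peptide N-to-C direction matching the reference
#'   (criterion ii).
#' @param hb1,hb2,hb3 Form hydrogen bonds 1-3 (criterion iii).
#' @return A \code{complex_pose} (phosphatase chain A, peptide chain B,
#'   pY residue 3).
#' @export
generate_toy_pose <- function(py_in_site = TRUE, orientation = TRUE,
                              hb1 = TRUE, hb2 = TRUE, hb3 = TRUE) {
  rows <- list()
  ## catalytic loop 214-221 along x, centroid at the origin
  for (k in 214:221) {
    ca <- c((k - 217.5) * 1.5, 0, 0)
    rows <- c(rows, list(
      toy_atom("N", "GLY", k, "A", ca + c(0.3, 0.8, 0)),
      toy_atom("CA", "GLY", k, "A", ca),
      toy_atom("C", "GLY", k, "A", ca + c(0.8, -0.5, 0.3)),
      toy_atom("O", "GLY", k, "A", ca + c(1.0, -1.2, 0.5))
    ))
  }
  ## Arg-47 (backbone N is the H-bond 3 donor)
  rows <- c(rows, list(
    toy_atom("N", "ARG", 47, "A", c(0, 9, 0)),
    toy_atom("CA", "ARG", 47, "A", c(1.2, 9.5, 0)),
    toy_atom("C", "ARG", 47, "A", c(2.2, 8.8, 0.4)),
    toy_atom("O", "ARG", 47, "A", c(2.4, 9.0, 1.6))
  ))
  ## Asp-48 (side-chain OD1/OD2 accept H-bonds 1 and 2)
  od1 <- c(3.0, 5.5, 2.8)
  od2 <- c(5.0, 6.0, 2.5)
  rows <- c(rows, list(
    toy_atom("N", "ASP", 48, "A", c(2.6, 8.4, 0)),
    toy_atom("CA", "ASP", 48, "A", c(3.0, 7.5, 0)),
    toy_atom("C", "ASP", 48, "A", c(4.2, 7.8, 0.6)),
    toy_atom("O", "ASP", 48, "A", c(4.6, 8.9, 0.6)),
    toy_atom("CB", "ASP", 48, "A", c(3.5, 6.5, 1.0)),
    toy_atom("CG", "ASP", 48, "A", c(3.8, 6.0, 2.0)),
    toy_atom("OD1", "ASP", 48, "A", od1),
    toy_atom("OD2", "ASP", 48, "A", od2)
  ))

  ## peptide chain B: residues 1..5, pY at 3; CA positions define N->C
  ca_x <- c(-4, -2, 0, 2, 4)
  if (!orientation) ca_x <- rev(ca_x)
  resnames <- c("ALA", "ALA", "PTR", "ALA", "ALA")
  hb_dist <- function(flag) if (flag) 2.9 else 5.5
  for (r in 1:5) {
    ca <- c(ca_x[r], 5, 0)
    rows <- c(rows, list(toy_atom("CA", resnames[r], r, "B", ca)))
    rows <- c(rows, list(toy_atom("C", resnames[r], r, "B",
                                  ca + c(0.5, -0.5, -0.5))))
  }
  ## criteria-relevant peptide atoms, placed absolutely
  rows <- c(rows, list(
    toy_atom("P", "PTR", 3, "B",
             if (py_in_site) c(0, 1, 0) else c(0, 15, 0)),
    toy_atom("N", "PTR", 3, "B", od1 + c(0, 0, hb_dist(hb1))),
    toy_atom("N", "ALA", 4, "B", od2 + c(0, 0, hb_dist(hb2))),
    toy_atom("O", "ALA", 1, "B", c(0, 9 + hb_dist(hb3), 0)),
    ## inert backbone completion, far from any donor/acceptor pairing
    toy_atom("N", "ALA", 1, "B", c(ca_x[1] + 0.5, 4.2, -1.0)),
    toy_atom("N", "ALA", 2, "B", c(ca_x[2] + 0.5, 4.2, -1.0)),
    toy_atom("N", "ALA", 5, "B", c(ca_x[5] + 0.5, 4.2, -1.0)),
    toy_atom("O", "ALA", 2, "B", c(ca_x[2] - 0.5, 4.0, -1.2)),
    toy_atom("O", "PTR", 3, "B", c(0.5, 4.0, -1.2)),
    toy_atom("O", "ALA", 4, "B", c(ca_x[4] - 0.5, 4.0, -1.2)),
    toy_atom("O", "ALA", 5, "B", c(ca_x[5] - 0.5, 4.0, -1.2))
  ))
  atoms <- do.call(rbind, rows)
  complex_pose(atoms, phos_chain = "A", pep_chain = "B", py_resno = 3L)
}

#' Reference complex for toy poses
#'
#' The all-criteria-satisfying toy pose promoted to a
#' \code{reference_complex}; evaluating it against itself passes every
#' criterion.
#'
#' @return A \code{reference_complex}.
#' @export
toy_reference <- function() {
  reference_complex(generate_toy_pose(), pocket_resnos = 214:221,
                    asp_resno = 48, arg_resno = 47)
}

#' Write a pose as PDB text
#'
#' Minimal fixed-width ATOM-record writer for synthetic poses.
#'
#' @param pose A \code{complex_pose}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_pose_pdb <- function(pose, path) {
  a <- pose$atoms
  element <- substr(gsub("[0-9]", "", a$elety), 1L, 1L)
  lines <- sprintf(
    "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), a$elety, a$resid, a$chain, a$resno,
    a$x, a$y, a$z, 1.00, 0.00, element
  )
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
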