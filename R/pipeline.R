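## Orchestration: run the scoring stage, the biological filter stage and
## the pose-evaluation stage from a single configuration, writing TSV
## outputs plus a JSON manifest sufficient to reproduce the run.

#' Build a validated run configuration
#'
#' @param fasta Path to the protein FASTA library.
#' @param sites Path to the pY site annotation TSV (the peptide library).
#' @param positive_sites Path to the known-dephosphorylation-site TSV (the
#'   positive training class); may equal a subset of \code{sites}.
#' @param substrates,pathway_gmts Paths for the filter stage: substrate
#'   table TSV and a named character vector of GMT files.
#' @param reference_pdb Path to the reference complex PDB for pose
#'   evaluation (optional).
#' @param out_dir Output directory.
#' @param q Consensus top fraction, in (0,1]; default 0.1.
#' @param alpha PSSM pseudocount weight; default 0.05.
#' @param target_specificity Classifier specificity target; default 0.95.
#' @param pocket_cutoff,hbond_dmax Pose criteria cutoffs (angstrom).
#' @param anchor,anchor_gene Anchor phosphatase id and gene id.
#' @param phos_chain,pep_chain Chain ids in pose PDB files.
#' @param pocket_resnos,asp_resno,arg_resno Catalytic geometry residue
#'   numbers.
#' @param seed Integer seed for the classifier split.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(fasta = NULL, sites = NULL, positive_sites = NULL,
                       substrates = NULL, pathway_gmts = NULL,
                       reference_pdb = NULL, out_dir = tempfile("ptpscreen_"),
                       q = 0.1, alpha = 0.05, target_specificity = 0.95,
                       pocket_cutoff = 7, hbond_dmax = 3.5,
                       anchor = "PTP1B", anchor_gene = "PTPN1",
                       phos_chain = "A", pep_chain = "B",
                       pocket_resnos = 214:221, asp_resno = 48,
                       arg_resno = 47, seed = 1L) {
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  if (alpha <= 0) stop("alpha must be > 0")
  if (target_specificity <= 0 || target_specificity >= 1) {
    stop("target_specificity must be in (0, 1)")
  }
  for (p in c(fasta, sites, positive_sites, substrates, pathway_gmts,
              reference_pdb)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  structure(list(fasta = fasta, sites = sites,
                 positive_sites = positive_sites, substrates = substrates,
                 pathway_gmts = pathway_gmts, reference_pdb = reference_pdb,
                 out_dir = out_dir, q = q, alpha = alpha,
                 target_specificity = target_specificity,
                 pocket_cutoff = pocket_cutoff, hbond_dmax = hbond_dmax,
                 anchor = anchor, anchor_gene = anchor_gene,
                 phos_chain = phos_chain, pep_chain = pep_chain,
                 pocket_resnos = pocket_resnos, asp_resno = asp_resno,
                 arg_resno = arg_resno, seed = as.integer(seed)),
            class = "run_config")
}

write_manifest <- function(config, stage, extra = list()) {
  inputs <- Filter(Negate(is.null),
                   config[c("fasta", "sites", "positive_sites", "substrates",
                            "pathway_gmts", "reference_pdb")])
  checksums <- lapply(inputs, function(p) unname(tools::md5sum(p)))
  manifest <- c(
    list(stage = stage,
         package_version = as.character(utils::packageVersion("ptpscreen")),
         parameters = config[c("q", "alpha", "target_specificity",
                               "pocket_cutoff", "hbond_dmax", "anchor",
                               "anchor_gene", "seed")],
         score_formula = "logodds_total_pseudocount",
         input_md5 = checksums),
    extra
  )
  path <- file.path(config$out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the sequence-based prediction stage
#'
#' Reads the protein library and its pY annotations, extracts the
#' deduplicated 11-mer window library, builds the three scoring models
#' (logo heights and PSSM from the positive class against the background
#' tyrosine windows; the calibrated classifier with the configured seed),
#' scores every library window, and marks the top-\code{q} consensus.
#' Writes \code{candidates.tsv} and a manifest to \code{out_dir}.
#'
#' @param config A [run_config()] with \code{fasta}, \code{sites} and
#'   \code{positive_sites} set.
#' @return The \code{candidate_records} data frame, invisibly also written
#'   to disk.
#' @export
run_predict <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("fasta", "sites", "positive_sites")) {
    if (is.null(config[[f]])) stop("run_predict needs config$", f)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  proteins <- read_fasta(config$fasta)
  sites <- read_site_annotations(config$sites, proteins)
  library_windows <- extract_windows(sites, proteins)

  pos_sites <- read_site_annotations(config$positive_sites, proteins)
  positives <- extract_windows(pos_sites, proteins)
  negatives <- enumerate_background_windows(proteins, sites)
  if (nrow(negatives) == 0L) stop("no background windows available")

  logo <- build_logo(positives)
  pssm <- build_pssm(positives, negatives)
  clf <- train_site_classifier(positives, negatives,
                               target_specificity = config$target_specificity,
                               seed = config$seed)

  records <- candidate_table(
    library_windows,
    score_logo(library_windows, logo),
    score_pssm(library_windows, pssm, alpha = config$alpha),
    score_classifier(library_windows, clf)
  )
  records <- consensus(records, q = config$q)
  records$classifier_pass <- records$score3 >= clf$threshold

  utils::write.table(records, file.path(config$out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, "predict",
                 list(n_library = nrow(records),
                      n_positive = nrow(positives),
                      n_background = nrow(negatives),
                      classifier_threshold = clf$threshold))
  invisible(records)
}

## Map candidate windows to gene symbols via their source proteins.
candidate_genes <- function(records, proteins) {
  idx <- protein_id_index(proteins)
  genes <- lapply(strsplit(records$sources, ";", fixed = TRUE), function(s) {
    pid <- sub(":\\d+$", "", s)
    g <- proteins$gene[idx[sub(";.*", "", pid)]]
    unique(g[!is.na(g)])
  })
  genes
}

#' Run the biological filter stage on consensus candidates
#'
#' Maps consensus windows to their source genes and applies the
#' substrate-sharing / pathway co-membership filter.
#'
#' @param config A [run_config()] with \code{fasta}, \code{substrates} and
#'   \code{pathway_gmts} set.
#' @param candidates A \code{candidate_records} table from [run_predict()].
#' @return Data frame with one row per consensus window: peptide, genes,
#'   filter verdict and reasons; written to \code{filter_report.tsv}.
#' @export
run_filter <- function(config, candidates) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("fasta", "substrates", "pathway_gmts")) {
    if (is.null(config[[f]])) stop("run_filter needs config$", f)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  proteins <- read_fasta(config$fasta)
  table <- read_substrate_table(config$substrates)
  gmt_names <- names(config$pathway_gmts)
  if (is.null(gmt_names)) {
    gmt_names <- tools::file_path_sans_ext(basename(config$pathway_gmts))
  }
  pathways <- stats::setNames(lapply(config$pathway_gmts, read_gmt),
                              gmt_names)

  cons <- candidates[isTRUE_vec(candidates$in_consensus), , drop = FALSE]
  gene_sets <- candidate_genes(cons, proteins)
  rows <- lapply(seq_len(nrow(cons)), function(k) {
    genes <- gene_sets[[k]]
    if (length(genes) == 0L) {
      return(data.frame(peptide = cons$peptide[k], genes = "",
                        pass = FALSE, reasons = "no gene annotation",
                        stringsAsFactors = FALSE))
    }
    verdicts <- passes_filters(genes, table, pathways, config$anchor,
                               config$anchor_gene)
    data.frame(peptide = cons$peptide[k],
               genes = paste(genes, collapse = ";"),
               pass = any(verdicts$pass),
               reasons = paste(verdicts$reasons[verdicts$pass | nzchar(verdicts$reasons)],
                               collapse = "|"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, file.path(config$out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, "filter", list(n_candidates = nrow(out),
                                        n_pass = sum(out$pass)))
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Run the pose-evaluation stage on a directory of docked poses
#'
#' @param config A [run_config()] with \code{reference_pdb} set.
#' @param pose_dir Directory of pose PDB files (or a character vector of
#'   paths).
#' @return Pose report data frame (see [evaluate_pose_files()]); written to
#'   \code{pose_report.tsv}.
#' @export
run_pose_eval <- function(config, pose_dir) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$reference_pdb)) stop("run_pose_eval needs config$reference_pdb")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ref_pose <- read_pose_pdb(config$reference_pdb,
                            phos_chain = config$phos_chain,
                            pep_chain = config$pep_chain)
  reference <- reference_complex(ref_pose,
                                 pocket_resnos = config$pocket_resnos,
                                 asp_resno = config$asp_resno,
                                 arg_resno = config$arg_resno)
  report <- evaluate_pose_files(pose_dir, reference,
                                phos_chain = config$phos_chain,
                                pep_chain = config$pep_chain,
                                cutoff = config$pocket_cutoff,
                                dmax = config$hbond_dmax)
  utils::write.table(report, file.path(config$out_dir, "pose_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, "pose_eval",
                 list(n_poses = nrow(report), n_accepted = sum(report$accepted)))
  report
}
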