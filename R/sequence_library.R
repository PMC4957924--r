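#' Read a protein FASTA file into a non-redundant protein set
#'
#' Reads amino-acid FASTA, uppercases sequences, validates the alphabet
#' (20 standard residues plus \code{X} for unknown), and collapses entries
#' with identical sequences into a single record whose \code{id} is the
#' semicolon-joined list of original identifiers.  A gene symbol is parsed
#' from a \code{GN=<gene>} token in the description line when present.
#'
#' @param path Path to a FASTA file.
#' @return A data frame of class \code{protein_set} with columns \code{id},
#'   \code{gene} and \code{sequence}, one row per distinct sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) return(empty_protein_set())
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  genes <- ifelse(grepl("GN=", headers, fixed = TRUE),
                  sub("^.*GN=([^ \t]+).*$", "\\1", headers),
                  NA_character_)
  seqs <- toupper(as.character(set))
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "X]"), seqs)
  if (any(bad)) {
    stop("non-amino-acid characters in FASTA entries: ",
         paste(ids[bad], collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for FASTA entries: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  as_protein_set(ids, genes, seqs)
}

empty_protein_set <- function() {
  structure(
    data.frame(id = character(), gene = character(),
               sequence = character(), stringsAsFactors = FALSE),
    class = c("protein_set", "data.frame")
  )
}

## Collapse duplicate sequences; merge ids (and genes) with ";".
as_protein_set <- function(ids, genes, seqs) {
  key <- factor(seqs, levels = unique(seqs))
  merged_id <- tapply(ids, key, function(x) paste(unique(x), collapse = ";"))
  merged_gene <- tapply(genes, key, function(x) {
    g <- unique(x[!is.na(x)])
    if (length(g) == 0L) NA_character_ else paste(g, collapse = ";")
  })
  out <- data.frame(id = as.character(merged_id),
                    gene = as.character(merged_gene),
                    sequence = levels(key),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Write a protein set to FASTA
#'
#' @param proteins A \code{protein_set} data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  seqs <- Biostrings::AAStringSet(proteins$sequence)
  names(seqs) <- ifelse(is.na(proteins$gene), proteins$id,
                        paste0(proteins$id, " GN=", proteins$gene))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read and validate phosphotyrosine site annotations
#'
#' Reads a tab-separated table with columns \code{protein_id},
#' \code{position} (1-based) and \code{residue}, keeps rows that identify a
#' tyrosine actually present at that position of a known protein, and
#' attaches the remaining rows, each with a reason, as the
#' \code{"rejected"} attribute.  A position outside the protein sequence is
#' treated as a hard validation error because it usually signals a
#' mismatched sequence version.
#'
#' @param path Path to the TSV file, or a data frame with the same columns.
#' @param proteins A \code{protein_set} from [read_fasta()].  A site matches
#'   a protein when its \code{protein_id} equals any of the semicolon-joined
#'   identifiers of a record.
#' @return A data frame of class \code{phospho_sites} with columns
#'   \code{protein_id} (the merged record id), \code{position},
#'   \code{residue}; duplicated sites are collapsed.  Rejected rows (absent
#'   protein, non-Y residue claim, residue mismatch) are in
#'   \code{attr(, "rejected")}.
#' @export
read_site_annotations <- function(path, proteins) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "residue")
  if (!all(need %in% names(tab))) {
    stop("site annotation table must have columns: ",
         paste(need, collapse = ", "))
  }
  tab$protein_id <- as.character(tab$protein_id)
  tab$position <- as.integer(tab$position)
  tab$residue <- toupper(as.character(tab$residue))

  lookup <- protein_id_index(proteins)
  row_idx <- lookup[tab$protein_id]
  reason <- rep(NA_character_, nrow(tab))
  reason[is.na(row_idx)] <- "protein not found"
  reason[is.na(reason) & tab$residue != "Y"] <- "annotated residue is not Y"

  ok <- is.na(reason)
  if (any(ok)) {
    plen <- nchar(proteins$sequence[row_idx[ok]])
    out_of_range <- tab$position[ok] < 1L | tab$position[ok] > plen
    if (any(out_of_range)) {
      bad <- tab[ok, ][out_of_range, , drop = FALSE]
      stop("site position out of range for protein sequence: ",
           paste(sprintf("%s:%d", bad$protein_id, bad$position),
                 collapse = ", "))
    }
    at <- substr(proteins$sequence[row_idx[ok]], tab$position[ok],
                 tab$position[ok])
    mism <- at != "Y"
    reason[which(ok)[mism]] <- sprintf("residue at position is %s, not Y",
                                       at[mism])
  }

  rejected <- cbind(tab[!is.na(reason), need, drop = FALSE],
                    reason = reason[!is.na(reason)])
  rownames(rejected) <- NULL
  if (nrow(rejected) > 0L) {
    warning(nrow(rejected), " site annotation(s) rejected; see attr(x, 'rejected')")
  }

  keep <- tab[is.na(reason), , drop = FALSE]
  sites <- data.frame(
    protein_id = proteins$id[row_idx[is.na(reason)]],
    position = keep$position,
    residue = "Y",
    stringsAsFactors = FALSE
  )
  sites <- unique(sites)
  sites <- sites[order(sites$protein_id, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  structure(sites, rejected = rejected,
            class = c("phospho_sites", "data.frame"))
}

## Map every individual identifier (components of merged "A;B" ids) to the
## row index of its protein record.
protein_id_index <- function(proteins) {
  parts <- strsplit(proteins$id, ";", fixed = TRUE)
  idx <- rep(seq_along(parts), lengths(parts))
  stats::setNames(idx, unlist(parts))
}

## Substring with '-' padding beyond the termini.
window_at <- function(sequence, position, flank = 5L) {
  n <- nchar(sequence)
  left <- max(1L, position - flank)
  right <- min(n, position + flank)
  core <- substr(sequence, left, right)
  paste0(strrep("-", left - (position - flank)),
         core,
         strrep("-", (position + flank) - right))
}

#' Extract centred 11-mer peptide windows around phosphosites
#'
#' Each site yields the window \code{sequence[position-5 .. position+5]},
#' padded with \code{-} where the window runs past a terminus.  Identical
#' peptides are collapsed into one window whose \code{sources} merge all
#' contributing (protein, position) pairs.  Windows containing \code{X}
#' carry no usable frequency information and are dropped with a warning.
#'
#' @param sites A \code{phospho_sites} data frame (or any data frame with
#'   \code{protein_id} and \code{position}).
#' @param proteins A \code{protein_set}.
#' @return A data frame of class \code{peptide_windows} with columns
#'   \code{peptide} (11 characters, centre \code{Y}), \code{n_sources} and
#'   \code{sources} (semicolon-joined \code{protein_id:position} pairs),
#'   sorted by peptide.
#' @export
extract_windows <- function(sites, proteins) {
  if (nrow(sites) == 0L) return(empty_windows())
  lookup <- protein_id_index(proteins)
  first_id <- sub(";.*$", "", sites$protein_id)
  row_idx <- lookup[first_id]
  if (anyNA(row_idx)) {
    stop("sites refer to unknown proteins: ",
         paste(unique(sites$protein_id[is.na(row_idx)]), collapse = ", "))
  }
  peptides <- vapply(seq_len(nrow(sites)), function(k) {
    window_at(proteins$sequence[row_idx[k]], sites$position[k])
  }, character(1))
  src <- paste0(sites$protein_id, ":", sites$position)

  has_x <- grepl("X", peptides, fixed = TRUE)
  if (any(has_x)) {
    warning(sum(has_x), " window(s) containing X dropped: ",
            paste(utils::head(src[has_x], 5L), collapse = ", "))
    peptides <- peptides[!has_x]
    src <- src[!has_x]
  }
  if (length(peptides) == 0L) return(empty_windows())
  stopifnot(all(substr(peptides, CENTER_OFFSET, CENTER_OFFSET) == "Y"))

  by_pep <- split(src, peptides)
  srcs <- vapply(by_pep, function(s) paste(sort(unique(s)), collapse = ";"),
                 character(1))
  out <- data.frame(
    peptide = names(by_pep),
    n_sources = lengths(lapply(strsplit(srcs, ";", fixed = TRUE), unique)),
    sources = unname(srcs),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peptide_windows", "data.frame")
  out
}

empty_windows <- function() {
  structure(
    data.frame(peptide = character(), n_sources = integer(),
               sources = character(), stringsAsFactors = FALSE),
    class = c("peptide_windows", "data.frame")
  )
}

#' Enumerate background tyrosine windows
#'
#' Builds the negative-class alignment: 11-mer windows around tyrosines that
#' carry no phosphotyrosine annotation.  By default the exclusion is at the
#' protein level — every tyrosine of a protein that has at least one
#' annotated pY site is excluded, so background windows come only from
#' proteins without any pY annotation.  \code{exclusion = "site"} instead
#' keeps unannotated tyrosines on annotated proteins, for users with densely
#' annotated inputs.
#'
#' @param proteins A \code{protein_set}.
#' @param annotated A \code{phospho_sites} data frame of known pY sites.
#' @param exclusion \code{"protein"} (default) or \code{"site"}.
#' @return A \code{peptide_windows} data frame, deduplicated as in
#'   [extract_windows()].
#' @export
enumerate_background_windows <- function(proteins, annotated,
                                         exclusion = c("protein", "site")) {
  exclusion <- match.arg(exclusion)
  annotated_ids <- unique(as.character(annotated$protein_id))
  sites <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(k) {
    id <- proteins$id[k]
    if (exclusion == "protein" && id %in% annotated_ids) return(NULL)
    pos <- which(strsplit(proteins$sequence[k], "", fixed = TRUE)[[1]] == "Y")
    if (exclusion == "site") {
      ann_pos <- annotated$position[annotated$protein_id == id]
      pos <- setdiff(pos, ann_pos)
    }
    if (length(pos) == 0L) return(NULL)
    data.frame(protein_id = id, position = as.integer(pos),
               residue = "Y", stringsAsFactors = FALSE)
  }))
  if (is.null(sites)) return(empty_windows())
  extract_windows(sites, proteins)
}

#' Write peptide windows to a TSV file
#'
#' @param windows A \code{peptide_windows} data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_windows <- function(windows, path) {
  utils::write.table(windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
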