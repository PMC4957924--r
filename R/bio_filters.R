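## Biologically meaningful filters: candidate genes must be substrates of
## the anchor phosphatase or of a phosphatase sharing substrates with it,
## or co-members of a pathway with the anchor gene.

#' Read a phosphatase-substrate table
#'
#' Two-column TSV (\code{phosphatase}, \code{substrate_gene}), DEPOD-style.
#' Identifiers are uppercased.
#'
#' @param path TSV path, or a data frame with the same columns.
#' @return A named list of class \code{substrate_table}: phosphatase id ->
#'   character vector of substrate gene ids.
#' @export
read_substrate_table <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("phosphatase", "substrate_gene") %in% names(tab))) {
    stop("substrate table must have columns phosphatase, substrate_gene")
  }
  by <- split(toupper(tab$substrate_gene), toupper(tab$phosphatase))
  tab <- lapply(by, function(g) sort(unique(g)))
  if (any(lengths(tab) == 0L)) stop("empty substrate set in table")
  structure(tab, class = "substrate_table")
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return A named list of class \code{pathway_sets}: pathway id ->
#'   uppercase gene vector.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop("GMT line with fewer than 3 fields: ", f[1])
    sort(unique(toupper(f[-(1:2)])))
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  structure(sets, class = "pathway_sets")
}

#' Phosphatases sharing at least one substrate with an anchor phosphatase
#'
#' @param table A \code{substrate_table}.
#' @param anchor Phosphatase id present in the table.
#' @return Character vector of phosphatase ids (anchor excluded) whose
#'   substrate set intersects the anchor's.
#' @export
related_phosphatases <- function(table, anchor) {
  anchor <- toupper(anchor)
  if (!anchor %in% names(table)) {
    stop("anchor phosphatase not in table: ", anchor)
  }
  others <- setdiff(names(table), anchor)
  others[vapply(others, function(p) {
    length(intersect(table[[p]], table[[anchor]])) > 0L
  }, logical(1))]
}

#' Apply the substrate/pathway filters to candidate genes
#'
#' A gene passes when it is a known substrate of the anchor phosphatase or
#' of a phosphatase that shares substrates with the anchor, or when it
#' co-occurs with the anchor gene in at least one pathway.  With
#' \code{pathway_mode = "any"} (default) co-membership in one pathway of
#' any collection suffices; \code{"all"} requires co-membership in at least
#' one pathway of every collection supplied.
#'
#' @param genes Character vector of candidate gene ids.
#' @param table A \code{substrate_table}.
#' @param pathways A named list of \code{pathway_sets} collections (e.g.
#'   \code{list(KEGG = ..., PID = ...)}), or a single \code{pathway_sets}.
#' @param anchor Anchor phosphatase id (e.g. the PTP1B entry of the table).
#' @param anchor_gene Gene id of the anchor phosphatase (e.g. PTPN1).
#' @param pathway_mode \code{"any"} or \code{"all"}.
#' @return Data frame with columns \code{gene}, \code{pass} and
#'   \code{reasons} (semicolon-joined satisfied clauses, or "not found").
#' @export
passes_filters <- function(genes, table, pathways, anchor, anchor_gene,
                           pathway_mode = c("any", "all")) {
  pathway_mode <- match.arg(pathway_mode)
  if (inherits(pathways, "pathway_sets")) pathways <- list(pathways = pathways)
  genes_uc <- toupper(genes)
  anchor <- toupper(anchor)
  anchor_gene <- toupper(anchor_gene)
  related <- related_phosphatases(table, anchor)

  known <- unique(unlist(table, use.names = FALSE))
  in_pathways <- unique(unlist(pathways, use.names = FALSE))

  res <- lapply(genes_uc, function(g) {
    reasons <- character()
    if (g %in% table[[anchor]]) {
      reasons <- c(reasons, paste0("substrate_of_anchor:", anchor))
    }
    for (p in related) {
      if (g %in% table[[p]]) reasons <- c(reasons, paste0("substrate_of:", p))
    }
    per_collection <- vapply(names(pathways), function(cn) {
      hits <- names(pathways[[cn]])[vapply(pathways[[cn]], function(s) {
        g %in% s && anchor_gene %in% s
      }, logical(1))]
      if (length(hits) > 0L) {
        reasons <<- c(reasons, paste0("pathway:", cn, ":", hits))
      }
      length(hits) > 0L
    }, logical(1))
    pathway_ok <- if (pathway_mode == "any") any(per_collection)
                  else all(per_collection)
    substrate_ok <- any(startsWith(reasons, "substrate_of"))
    pass <- substrate_ok || pathway_ok
    if (!pass && !(g %in% known) && !(g %in% in_pathways)) {
      reasons <- "not found"
    }
    list(pass = pass,
         reasons = if (length(reasons) == 0L) "" else
           paste(reasons, collapse = ";"))
  })
  data.frame(gene = genes,
             pass = vapply(res, `[[`, logical(1), "pass"),
             reasons = vapply(res, `[[`, character(1), "reasons"),
             stringsAsFactors = FALSE)
}
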